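prefix,condition,weight,malignancy
I21,mi,1,0
I22,mi,1,0
I252,mi,1,0
I099,chf,1,0
I110,chf,1,0
I130,chf,1,0
I132,chf,1,0
I255,chf,1,0
I420,chf,1,0
I425,chf,1,0
I426,chf,1,0
I427,chf,1,0
I428,chf,1,0
I429,chf,1,0
I43,chf,1,0
I50,chf,1,0
P290,chf,1,0
I70,pvd,1,0
I71,pvd,1,0
I731,pvd,1,0
I738,pvd,1,0
I739,pvd,1,0
I771,pvd,1,0
I790,pvd,1,0
I792,pvd,1,0
K551,pvd,1,0
K558,pvd,1,0
K559,pvd,1,0
Z958,pvd,1,0
Z959,pvd,1,0
G45,cvd,1,0
G46,cvd,1,0
H340,cvd,1,0
I60,cvd,1,0
I61,cvd,1,0
I62,cvd,1,0
I63,cvd,1,0
I64,cvd,1,0
I65,cvd,1,0
I66,cvd,1,0
I67,cvd,1,0
I68,cvd,1,0
I69,cvd,1,0
F00,dementia,1,0
F01,dementia,1,0
F02,dementia,1,0
F03,dementia,1,0
F051,dementia,1,0
G30,dementia,1,0
G311,dementia,1,0
I278,copd,1,0
I279,copd,1,0
J40,copd,1,0
J41,copd,1,0
J42,copd,1,0
J43,copd,1,0
J44,copd,1,0
J45,copd,1,0
J46,copd,1,0
J47,copd,1,0
J60,copd,1,0
J61,copd,1,0
J62,copd,1,0
J63,copd,1,0
J64,copd,1,0
J65,copd,1,0
J66,copd,1,0
J67,copd,1,0
J684,copd,1,0
J701,copd,1,0
J703,copd,1,0
M05,rheum,1,0
M06,rheum,1,0
M315,rheum,1,0
M32,rheum,1,0
M33,rheum,1,0
M34,rheum,1,0
M351,rheum,1,0
M353,rheum,1,0
M360,rheum,1,0
K25,pud,1,0
K26,pud,1,0
K27,pud,1,0
K28,pud,1,0
B18,liver_mild,1,0
K700,liver_mild,1,0
K701,liver_mild,1,0
K702,liver_mild,1,0
K703,liver_mild,1,0
K709,liver_mild,1,0
K713,liver_mild,1,0
K714,liver_mild,1,0
K715,liver_mild,1,0
K717,liver_mild,1,0
K73,liver_mild,1,0
K74,liver_mild,1,0
K760,liver_mild,1,0
K762,liver_mild,1,0
K763,liver_mild,1,0
K764,liver_mild,1,0
K768,liver_mild,1,0
K769,liver_mild,1,0
Z944,liver_mild,1,0
E100,diab,1,0
E101,diab,1,0
E106,diab,1,0
E108,diab,1,0
E109,diab,1,0
E110,diab,1,0
E111,diab,1,0
E116,diab,1,0
E118,diab,1,0
E119,diab,1,0
E120,diab,1,0
E121,diab,1,0
E126,diab,1,0
E128,diab,1,0
E129,diab,1,0
E130,diab,1,0
E131,diab,1,0
E136,diab,1,0
E138,diab,1,0
E139,diab,1,0
E140,diab,1,0
E141,diab,1,0
E146,diab,1,0
E148,diab,1,0
E149,diab,1,0
E10,diab,1,0
E11,diab,1,0
E12,diab,1,0
E13,diab,1,0
E14,diab,1,0
E102,diab_comp,2,0
E103,diab_comp,2,0
E104,diab_comp,2,0
E105,diab_comp,2,0
E107,diab_comp,2,0
E112,diab_comp,2,0
E113,diab_comp,2,0
E114,diab_comp,2,0
E115,diab_comp,2,0
E117,diab_comp,2,0
E122,diab_comp,2,0
E123,diab_comp,2,0
E124,diab_comp,2,0
E125,diab_comp,2,0
E127,diab_comp,2,0
E132,diab_comp,2,0
E133,diab_comp,2,0
E134,diab_comp,2,0
E135,diab_comp,2,0
E137,diab_comp,2,0
E142,diab_comp,2,0
E143,diab_comp,2,0
E144,diab_comp,2,0
E145,diab_comp,2,0
E147,diab_comp,2,0
G041,plegia,2,0
G114,plegia,2,0
G801,plegia,2,0
G802,plegia,2,0
G81,plegia,2,0
G82,plegia,2,0
G830,plegia,2,0
G831,plegia,2,0
G832,plegia,2,0
G833,plegia,2,0
G834,plegia,2,0
G839,plegia,2,0
I120,renal,2,0
I131,renal,2,0
N032,renal,2,0
N033,renal,2,0
N034,renal,2,0
N035,renal,2,0
N036,renal,2,0
N037,renal,2,0
N052,renal,2,0
N053,renal,2,0
N054,renal,2,0
N055,renal,2,0
N056,renal,2,0
N057,renal,2,0
N18,renal,2,0
N19,renal,2,0
N250,renal,2,0
Z490,renal,2,0
Z491,renal,2,0
Z492,renal,2,0
Z940,renal,2,0
Z992,renal,2,0
C77,metastasis,6,1
C78,metastasis,6,1
C79,metastasis,6,1
C80,metastasis,6,1
C,malignancy,2,1
I850,liver_severe,3,0
I859,liver_severe,3,0
I864,liver_severe,3,0
I982,liver_severe,3,0
K704,liver_severe,3,0
K711,liver_severe,3,0
K721,liver_severe,3,0
K729,liver_severe,3,0
K765,liver_severe,3,0
K766,liver_severe,3,0
K767,liver_severe,3,0
B20,hiv,6,0
B21,hiv,6,0
B22,hiv,6,0
B24,hiv,6,0
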