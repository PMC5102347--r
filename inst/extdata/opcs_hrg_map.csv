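opcs,hrg
Q07,M05
Q23,M05
Q18,M04
T30,M07
X72,OPCH
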