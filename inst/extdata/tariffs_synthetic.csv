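hrg,description,setting,base_tariff,trim_point,excess_rate
M05,major open pelvic surgery (hysterectomy/BSO),inpatient,3700,8,225
M04,diagnostic/staging gynaecological procedure,inpatient,3000,3,180
M07,gynaecological readmission or complication,inpatient,1400,5,200
OPCH,outpatient chemotherapy delivery,outpatient,380,1,0
OPRT,radiotherapy fraction,outpatient,120,1,0
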