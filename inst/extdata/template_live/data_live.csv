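condition,time,rep_1,rep_2,rep_3
control,0,1000,1050,980
control,24,2060,2110,1975
control,48,4120,4300,4010
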