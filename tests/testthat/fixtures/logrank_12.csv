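patient_id,months,event,group
s01,6,1,a
s02,10,0,a
s03,14,1,a
s04,18,1,a
s05,22,0,a
s06,30,1,a
s07,8,1,b
s08,12,1,b
s09,16,0,b
s10,20,1,b
s11,24,1,b
s12,28,1,b
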