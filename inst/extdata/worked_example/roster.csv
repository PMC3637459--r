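shift_id,date,shift,person_id,role
W08_day,2009-06-24,day,A,SRN
W08_day,2009-06-24,day,B,PCT
W08_day,2009-06-24,day,C,CRN
W08_day,2009-06-24,day,D,RMD
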