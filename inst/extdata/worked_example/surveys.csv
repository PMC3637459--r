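shift_id,respondent,relation,target,frequency
W08_day,A,problem_solving,B,0
W08_day,A,problem_solving,C,0
W08_day,A,problem_solving,D,0
W08_day,B,problem_solving,A,0
W08_day,B,problem_solving,C,0
W08_day,B,problem_solving,D,0
W08_day,C,problem_solving,A,2
W08_day,C,problem_solving,B,1
W08_day,C,problem_solving,D,3
W08_day,D,problem_solving,A,1
W08_day,D,problem_solving,B,2
W08_day,D,problem_solving,C,0
W08_day,A,medication_advice,B,0
W08_day,A,medication_advice,C,0
W08_day,A,medication_advice,D,0
W08_day,B,medication_advice,A,0
W08_day,B,medication_advice,C,0
W08_day,B,medication_advice,D,0
W08_day,C,medication_advice,A,2
W08_day,C,medication_advice,B,1
W08_day,C,medication_advice,D,3
W08_day,D,medication_advice,A,1
W08_day,D,medication_advice,B,2
W08_day,D,medication_advice,C,0
W08_day,A,socializing,B,0
W08_day,A,socializing,C,0
W08_day,A,socializing,D,0
W08_day,B,socializing,A,0
W08_day,B,socializing,C,0
W08_day,B,socializing,D,0
W08_day,C,socializing,A,2
W08_day,C,socializing,B,1
W08_day,C,socializing,D,3
W08_day,D,socializing,A,1
W08_day,D,socializing,B,2
W08_day,D,socializing,C,0
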