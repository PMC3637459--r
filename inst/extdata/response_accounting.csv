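shift_id,completed,refused,not_located
May 6 AM,10,1,3
May 6 PM,17,1,2
May 13 AM,8,1,0
May 13 PM,11,4,3
May 20 AM,11,2,0
May 20 PM,7,9,0
May 27 AM,13,0,0
May 27 PM,14,5,1
June 3 AM,10,1,0
June 3 PM,13,4,2
June 10 AM,14,1,0
June 10 PM,19,3,0
June 17 AM,14,0,0
June 17 PM,18,3,0
June 24 AM,14,1,0
June 24 PM,18,3,0
July 1 AM,14,1,0
July 1 PM,15,5,2
July 8 AM,14,1,0
July 8 PM,20,4,0
July 15 AM,15,2,0
July 15 PM,19,3,0
July 22 AM,14,0,0
July 22 PM,14,6,0
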