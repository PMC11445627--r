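signal,low,high,score
HR,-Inf,41,2
HR,41,51,1
HR,51,101,0
HR,101,111,1
HR,111,130,2
HR,130,Inf,3
RR,-Inf,9,2
RR,9,15,0
RR,15,21,1
RR,21,30,2
RR,30,Inf,3
SBP,-Inf,71,3
SBP,71,81,2
SBP,81,101,1
SBP,101,200,0
SBP,200,Inf,2
TEMP,-Inf,35,2
TEMP,35,38.5,0
TEMP,38.5,Inf,2
SPO2,-Inf,92,3
SPO2,92,94,2
SPO2,94,96,1
SPO2,96,Inf,0
DBP,-Inf,40,3
DBP,40,50,1
DBP,50,110,0
DBP,110,130,1
DBP,130,Inf,2
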