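channel,row,col
FP1-F7,1,1
F7-T7,2,1
T7-P7,3,1
P7-O1,4,1
FP1-F3,1,2
F3-C3,2,2
C3-P3,3,2
P3-O1,4,2
FZ-CZ,2,3
CZ-PZ,3,3
FP2-F4,1,4
F4-C4,2,4
C4-P4,3,4
P4-O2,4,4
FP2-F8,1,5
F8-T8,2,5
T8-P8,3,5
P8-O2,4,5
T7-FT9,5,1
FT9-FT10,5,3
FT10-T8,5,5
P7-T7,5,2
T8-P8-2,5,4
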