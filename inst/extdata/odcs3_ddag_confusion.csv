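correct,R,I,L
R,1896,116,608
I,51,5043,146
L,454,128,2038
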