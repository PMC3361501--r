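id,x,y,population,positives
A,0,0,2,1
B,10,0,4,4
C,20,0,2,0
D,30,0,6,3
E,40,0,3,0
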