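location,males_adult,females_adult,males_young,females_young,pups,wounded_males_adult,wounded_females_adult
A,22,12,3,3,1,0,0
B,1,7,3,2,25,0,0
C,14,17,4,4,2,0,0
D,10,12,4,4,15,1,0
E,25,12,1,1,2,2,0
F,2,14,5,0,27,0,2
G,12,9,1,3,0,0,0
H,13,9,4,2,3,0,1
I,5,2,0,0,0,1,0
J,2,5,0,2,24,1,0
Z,39,15,0,0,4,22,2
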