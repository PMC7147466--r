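patient_id,total,class1,class0
P12,104,24,80
P18,61,11,50
P23,78,15,63
P29,78,34,44
P34,73,13,60
P40,34,7,27
P45,34,21,13
P51,14,3,11
P56,55,20,35
P62,91,51,40
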