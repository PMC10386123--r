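subject_id,before_load,after_load,after_eating
1,10,14,10
2,12,13,12
3,17,13,11
4,10,12,10
5,10,10,10
6,13,21,11
7,12,18,12
8,21,19,17
9,10,15,10
10,16,16,11
11,18,21,14
12,11,12,10
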