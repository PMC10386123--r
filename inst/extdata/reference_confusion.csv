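subject_id,tp,fn,fp,tn,precision,f1,recall,accuracy
1,35,22,1,46,82.43,77.63,79.64,77.88
2,61,8,0,48,92.86,93.08,94.20,93.16
3,39,12,6,41,82.01,81.62,81.85,81.63
4,38,8,0,47,92.73,91.32,91.30,91.40
5,31,0,20,27,80.39,74.29,78.72,74.36
6,42,16,2,45,84.61,82.84,84.08,82.86
7,31,1,4,49,93.29,93.84,94.66,94.12
8,47,1,25,22,80.46,70.60,72.36,72.63
9,44,2,3,44,94.63,94.62,94.63,94.62
10,37,7,0,48,93.64,92.28,92.05,92.39
11,31,3,0,47,97.00,96.15,95.59,96.30
12,37,3,23,24,75.28,69.43,71.78,70.11
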