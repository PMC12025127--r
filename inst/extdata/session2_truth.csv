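period,start,end
1,2 min 17 s,2 min 18 s
2,5 min 47 s,6 min 26 s
3,7 min 32 s,7 min 33 s
4,11 min 49 s,11 min 50 s
5,15 min 42 s,16 min 8 s
6,22 min 20 s,22 min 22 s
7,24 min 20 s,24 min 21 s
8,26 min 6 s,26 min 7 s
9,31 min 10 s,31 min 17 s
10,35 min 34 s,35 min 35 s
11,40 min 4 s,40 min 11 s
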