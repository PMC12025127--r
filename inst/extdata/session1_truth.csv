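period,start,end
1,5 min 37 s,5 min 38 s
2,8 min 19 s,8 min 20 s
3,12 min 10 s,12 min 11 s
4,16 min 15 s,16 min 16 s
5,20 min 44 s,20 min 45 s
6,23 min 9 s,23 min 10 s
7,31 min 36 s,31 min 38 s
8,33 min 0 s,33 min 1 s
9,36 min 12 s,36 min 13 s
10,45 min 18 s,45 min 20 s
11,47 min 46 s,47 min 47 s
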