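period,start,end
1,05:37,05:38
2,08:19,08:20
3,12:10,12:11
4,16:15,16:16
5,20:44,21:12
6,22:23,23:10
7,30:33,30:34
8,31:36,31:38
9,33:00,33:01
10,36:12,37:34
11,45:17,45:19
12,47:46,47:47
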