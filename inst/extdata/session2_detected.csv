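period,start,end
1,02:17,02:18
2,05:47,06:26
3,07:32,07:39
4,11:08,11:50
5,15:42,16:08
6,18:20,18:29
7,20:05,20:06
8,22:20,23:02
9,24:20,24:21
10,26:06,26:07
11,31:10,31:17
12,35:34,35:35
13,40:04,41:06
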