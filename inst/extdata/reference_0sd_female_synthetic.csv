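age,height
3,95.6
4,103.1
5,110.2
6,116.6
7,122.5
8,128.5
9,134.1
10,140.1
11,146.6
12,152.4
13,156.3
14,158.6
15,159.8
16,160.1
17,160.3
18,160.6
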