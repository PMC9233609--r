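age,height
3,96.8
4,104.1
5,111.3
6,117.7
7,124.0
8,130.0
9,135.4
10,140.2
11,145.3
12,151.9
13,159.5
14,165.9
15,169.8
16,171.6
17,172.3
18,172.7
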