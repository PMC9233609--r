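sex,age,bmi
M,3,15.6
M,4,15.3
M,5,15.2
M,6,15.3
M,7,15.5
M,8,15.7
M,9,16.0
M,10,16.4
M,11,16.9
M,12,17.5
M,13,18.2
M,14,19.0
M,15,19.8
M,16,20.5
M,17,21.1
M,18,21.7
F,3,15.4
F,4,15.1
F,5,15.0
F,6,15.2
F,7,15.4
F,8,15.7
F,9,16.1
F,10,16.6
F,11,17.2
F,12,18.0
F,13,18.8
F,14,19.6
F,15,20.2
F,16,20.7
F,17,21.0
F,18,21.3
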