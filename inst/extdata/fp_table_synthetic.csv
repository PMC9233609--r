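sex,category,bone_age,fp
M,normal,6,0.680
M,normal,7,0.700
M,normal,8,0.722
M,normal,9,0.748
M,normal,10,0.776
M,normal,11,0.806
M,normal,12,0.840
M,normal,13,0.876
M,normal,14,0.920
M,normal,15,0.958
M,normal,16,0.982
M,normal,17,0.995
M,normal,18,1.000
M,early,6,0.700
M,early,8,0.745
M,early,10,0.800
M,early,12,0.865
M,early,14,0.940
M,early,16,0.990
M,early,18,1.000
M,late,6,0.660
M,late,8,0.700
M,late,10,0.752
M,late,12,0.815
M,late,14,0.895
M,late,16,0.970
M,late,18,1.000
F,normal,6,0.720
F,normal,7,0.745
F,normal,8,0.772
F,normal,9,0.802
F,normal,10,0.835
F,normal,11,0.872
F,normal,12,0.912
F,normal,13,0.950
F,normal,14,0.978
F,normal,15,0.992
F,normal,16,1.000
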