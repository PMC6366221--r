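model,strain,w1,w2,w3,w4,ws,rc_l,rc_m,rc_h,corr,t_test,q_l,q_m,q_h
whole_spectrum,Fp84,0,0,0,0,1,21.61,56.09,97.24,0.99,1.00,1,2,4
whole_spectrum,DSM70449,0,0,0,0,1,15.54,60.00,95.01,0.97,0.97,1,2,4
whole_spectrum,Fm17,0,0,0,0,1,17.40,72.86,80.84,0.83,0.97,1,3,4
weighted_regions,Fp84,0,0,1,0,0,29.48,44.07,100.00,0.99,0.99,1,2,4
weighted_regions,DSM70449,0.1,0,0.1,0.8,0,24.30,49.59,99.75,1.00,0.99,1,2,4
weighted_regions,Fm17,1,0,0,0,0,14.55,60.33,94.72,0.96,0.96,1,2,4
expected,expected,NA,NA,NA,NA,NA,25.00,50.00,100.00,NA,NA,1,2,4
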