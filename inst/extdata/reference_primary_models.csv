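strain,window,a,b,c,r2
Fp84,W1,0.997,13.056,0.142,0.498
Fp84,W2,0.895,1.553,0.078,0.938
Fp84,W3,2.544,-10.997,-0.134,0.990
Fp84,W4,-0.989,15.862,-1.344,0.502
Fp84,WS,43.077,-96.031,0.063,0.990
DSM70449,W1,3.198,9.209,7.156,0.960
DSM70449,W2,0.679,1.147,5.264,0.906
DSM70449,W3,1.592,2.410,7.418,0.941
DSM70449,W4,14.301,-17.229,-0.122,0.998
DSM70449,WS,9.412,8.529,4.426,0.957
Fm17,W1,2.093,3.819,5.399,0.950
Fm17,W2,-0.005,5.776,5.083,0.785
Fm17,W3,-2.405,31.267,-9.201,0.846
Fm17,W4,-2.658,25.816,-1.647,0.503
Fm17,WS,2.990,10.959,3.898,0.824
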