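tip,angle_deg,a,b,r2
flat,0,2.685,7.782,0.837
flat,30,3.036,3.465,0.845
flat,45,3.689,2.952,0.867
flat,60,2.807,3.137,0.984
flat,90,2.693,0.892,0.893
round,0,2.837,4.251,0.974
round,30,3.903,2.890,0.961
round,45,3.429,0.012,0.926
round,60,3.062,1.363,0.936
round,90,2.341,2.709,0.953
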