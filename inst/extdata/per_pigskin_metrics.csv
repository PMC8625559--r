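code,cd_mg_ml,cd_corrected_mg_ml,j_mean,j_sd,q16h_mean,q16h_sd,logkp_mean,logkp_sd
S1,1,1,25,9.6,261,100,-1.71,0.32
S2,368,368,20,15,98,67,-4.26,0.51
S4,60,60,0.08,0.024,1.09,0.39,-5.88,0.19
S5,8,8,61,18,515,203,-1.97,0.34
S6,1,1,7.5,3,100,37,-2.16,0.26
S7,350,350,20,17.6,147,120,-4.24,0.81
S8,51,5.1,98,50,516,109,-1.72,0.34
S9,373,373,40,15,320,149,-3.97,0.24
S10,75,75,8,3.5,54,34,-3.97,0.29
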