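code,cd_mg_ml,j_mean,j_sd,lag_min,q6h_mean,q6h_sd,auc_norm,logpm_mean,logpm_sd
S1,1,72.4,7.8,1.4,169,4,647,-1.12,0.06
S2,500,12033,252,0.0,13575,1710,105,-1.62,0.01
S3,5,137,22,5.5,869,112,491,-1.57,0.07
S4,70,209,53,3.6,1342,298,55.2,-2.54,0.13
S5,10,589,25,0.9,1662,169,569,-1.23,0.03
S6,1,76.4,15.2,0.0,175,22,551,-1.13,0.07
S7,500,2118,502,3.8,11142,729,69.1,-2.38,0.11
S8,10,570,5,1.1,1772,98,595,-1.24,0.01
S9,500,10846,326,1.4,14926,2431,114,-1.66,0.01
S10,70,377,36,3.0,749,92,38.2,-2.27,0.04
S11,1,7.18,1.6,3.9,19,0.4,64.5,-2.16,0.08
S12,1,2.45,0.57,3.3,13,1.9,36.7,-2.63,0.07
S13,1,3.26,0.41,1.4,13,1.3,38.6,-2.48,0.06
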