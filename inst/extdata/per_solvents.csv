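code,solvent_class,solvent,mw,approx_solubility,equilibrium_solubility,equilibrium_solubility_sd
S1,low-MW polar,Water,18.0,1,1.3,0.2
S2,low-MW polar,Ethanol,46.1,>1000,368,52
S3,low-MW polar,Glycerol,92.1,5,NA,NA
S4,low-MW polar,Dimethylisosorbide,174.2,75,60,5.7
S5,low-MW polar,Water/ethanol 80:20 (w/w),NA,10,8.1,4.3
S6,low-MW polar,Water/dimethylisosorbide 90:10 (w/w),NA,1,1.1,0.1
S7,low-MW polar glycol,Propylene glycol,76.1,500,350,21
S8,low-MW polar glycol,Water/propylene glycol 80:20 (w/w),NA,10,5.1,0.8
S9,low-MW polar glycol,Water/propylene glycol/ethanol 10:30:60 (w/w/w),NA,>1000,373,49
S10,high-MW non-polar,Capric/caprylic triglycerides,554.8/470.7,75,74,5.1
S11,high-MW non-polar,Octyl dodecanol,298.6,1,NA,NA
S12,high-MW non-polar,Apricot kernel oil,NA,1,NA,NA
S13,high-MW non-polar,Corn oil,NA,1,NA,NA
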