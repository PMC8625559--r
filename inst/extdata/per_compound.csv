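property,value,units
chemical_name,4-phenylethyl-resorcinol,
cas_number,94-77-9,
molecular_weight,214.3,g/mol
logp,2.98,log10
pka,9.77-10.77,AH/A-
solubility_prisma_buffer,3.45,mg/mL
water_solubility,3.85,mg/mL
calibration_slope,117.95,absorbance per mg/mL
calibration_intercept,0.01,absorbance
calibration_range_low,9,ug/mL
calibration_range_high,90,ug/mL
calibration_n,9,
calibration_r_squared,0.9997,
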