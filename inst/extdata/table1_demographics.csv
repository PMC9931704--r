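id,study,population,dose,dose_unit,age_years,weight_kg,sex,serum_creatinine_mg_dl,egfr,regimen
S1,study1,renal_failure,2.3,mg_per_kg,5.5,NA,M,0.61,61,steady_state
S2,study1,renal_failure,0.8,mg_per_kg,3.5,NA,M,1.8,59,steady_state
S3,study1,renal_failure,1.6,mg_per_kg,9,NA,M,3.2,20,steady_state
S4,study1,renal_failure,1.6,mg_per_kg,12.5,NA,M,3.4,26,steady_state
S5,study1,renal_failure,1.2,mg_per_kg,11.5,NA,M,1.3,83,steady_state
S6,study1,renal_failure,2,mg_per_kg,20,NA,M,4.2,20,steady_state
L1,study2,renal_scarring,12.5,mg,5,18,F,0.28,187,single
L2,study2,renal_scarring,20,mg,12,29.6,F,0.56,142,single
L3,study2,renal_scarring,16.5,mg,6,24,F,0.35,173,single
L4,study2,renal_scarring,23.5,mg,10,34,F,0.67,135,single
L5,study2,renal_scarring,46,mg,18,66,M,1.25,83,single
L6,study2,renal_scarring,37.5,mg,14,52.8,F,0.58,138,single
L7,study2,renal_scarring,37.5,mg,11,53.7,F,0.56,148,single
L8,study2,renal_scarring,20,mg,7,29.7,M,0.34,200,single
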