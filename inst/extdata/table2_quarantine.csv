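id,column,printed,recomputed,check,note
S6,clf_obs,0.09,0.93,dose_over_auc,printed observed CL/F inconsistent with dose/AUC (2 mg/kg / 2153.50); likely decimal-place typo
S6,clf_pred,0.07,0.67,dose_over_auc,printed predicted CL/F inconsistent with dose/AUC (2 mg/kg / 2978.25)
L1,clf_pred,28.65,28.67,dose_over_auc,predicted AUC printed without decimals (436); dose/AUC differs in the last digit
L2,clf_pred,55.36,55.40,dose_over_auc,predicted AUC printed without decimals (361); dose/AUC differs in the last digit
L5,auc_ratio,0.60,0.59,pred_over_obs,635.37/1082.10 = 0.587 rounds to 0.59
S2,clf_ratio,2.29,2.31,pred_over_obs,1.64/0.71 = 2.31
S5,clf_ratio,0.82,0.92,pred_over_obs,1.44/1.56 = 0.92
S3,clf_ratio,0.72,0.88,pred_over_obs,1.02/1.16 = 0.88
S4,clf_ratio,0.81,1.05,pred_over_obs,0.98/0.93 = 1.05
S6,clf_ratio,0.47,0.78,pred_over_obs,0.07/0.09 = 0.78 (both cells themselves quarantined)
S1,clf_ratio,1.82,1.83,pred_over_obs,1.83/1.00 = 1.83
L7,clf_ratio,1.09,1.10,pred_over_obs,49.79/45.27 = 1.10
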