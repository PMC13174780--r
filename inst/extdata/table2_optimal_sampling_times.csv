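analyte,age_band,tod_cut_h,mean_ln_early,mean_ln_late,printed_diff,printed_fold,p_value
IA,14-19,14,-1.39,-2.35,0.97,2.64,0.0097
IA,>=44,9,-2.48,-1.65,-0.82,0.44,0.0459
IA-2A,<=16,8,5.28,4.03,1.25,3.49,0.0051
IA-2A,17-42,8,3.86,3.15,0.71,2.03,0.0369
ZnT8A,<=15,9,-2.38,-3.05,0.70,2.01,0.0243
ZnT8A,26-57,14,-4.24,-3.07,-1.17,0.31,0.0433
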