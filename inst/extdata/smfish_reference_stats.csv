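rna,genotype,mean_spots,mean_sem,variance,variance_sem,pct_gt0,pct_gt0_sem,pct_gt1,pct_gt1_sem,mean_is_upper_bound
cre,sir4,12,2,53,9,98,1,95,2,FALSE
cre,sir1,5,1,58,13,46,7,41,7,FALSE
cre,wild_type,0.005,NA,NA,NA,0.42,0.07,0.04,0.01,TRUE
cre,no_cre,0.003,NA,NA,NA,0.3,0.1,0,NA,TRUE
KAP104,sir4,7.3,0.4,11,1,99.0,0.3,97.2,0.8,FALSE
KAP104,sir1,7.1,0.2,10.8,0.9,99.28,0.04,97.5,0.1,FALSE
KAP104,wild_type,6.1,0.2,7.8,0.3,99.1,0.2,96.5,0.8,FALSE
KAP104,no_cre,5.9,0.5,7.1,0.5,99.0,0.7,96,2,FALSE
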