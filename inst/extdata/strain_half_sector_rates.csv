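strain,genotype,ploidy,rate_mean,rate_sd
JRY9628,HMLalpha::cre,haploid,0.00158,0.00007
JRY9629,HMRalpha::cre,haploid,0.0007,0.0002
JRY9739,HMLalpha::cre sir1,haploid,0.055,0.007
JRY9740,HMRalpha::cre sir1,haploid,0.061,0.002
JRY9731,HMLalpha/HMLalpha::cre,diploid,0.00037,0.00004
JRY9732,HMLalpha/HMLalpha::cre sir1/SIR1,diploid,0.0007,0.0002
JRY9734,HMLalpha/HMLalpha::cre sir3/SIR3,diploid,0.0016,0.0005
JRY9735,HMLalpha/HMLalpha::cre sir4/SIR4,diploid,0.0013,0.0003
JRY9636,HMLalpha::cre hst3,haploid,0.0111,0.0005
JRY9639,HMLalpha::cre single-histone HHT2-HHF2,haploid,0.0033,0.0004
JRY9640,HMLalpha::cre single-histone hht2K56R,haploid,0.0111,0.0008
JRY9641,HMLalpha::cre single-histone hht2K56Q,haploid,0.009,0.002
JRY9736,HMLalpha::cre hst3 single-histone HHT2-HHF2,haploid,0.0096,0.0008
JRY9737,HMLalpha::cre hst3 single-histone hht2K56R,haploid,0.009,0.001
JRY9738,HMLalpha::cre hst3 single-histone hht2K56Q,haploid,0.0105,0.0004
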