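# Reference strain panel: per-division silencing-loss rates as generative
# parameters, simple timing model. Rates are the published half-sector
# frequencies for the reporter strain panel (see strain_half_sector_rates.csv).
experiment: sector-panel
seed: 1
n_colonies: 200000
n_replicates: 3
strains:
  wt_hml:
    switch:
      p_div: 0.00158
  wt_hmr:
    switch:
      p_div: 0.0007
  sir1_hml:
    switch:
      p_div: 0.055
  hst3:
    switch:
      p_div: 0.0111
  wt_diploid:
    switch:
      p_div: 0.00037
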