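# Two-channel FISH synthesis + spot calling. Channel A: silenced reporter
# transcript; channel B: constitutive control transcript.
experiment: fish-panel
seed: 1
fish:
  n_stacks: 4
  stack:
    dim: [24, 360, 360]
    n_cells: 30
    min_separation: 6
  strains:
    sir4:
      model_a: {family: negbin, mean: 12, variance: 53}
      model_b: {family: poisson, mean: 7.3}
    sir1:
      model_a: {family: mixture, mean: 5, pi_expressed: 0.46}
      model_b: {family: poisson, mean: 7.1}
    wild_type:
      model_a: {family: poisson, mean: 0}
      model_b: {family: poisson, mean: 6.1}
caller:
  threshold_a: auto
  threshold_b: auto
  size_range: [4, 200]
  match_radius: 3
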