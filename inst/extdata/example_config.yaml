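# Example run configuration for the carepathways pipeline.
# Top-level keys mirror run_config(); the sim block mirrors sim_config().
normalization: mean
linkage: average
k_range: [2, 3, 4, 5, 6, 7, 8]
minsup: 0.10
max_len: 5
ppd_codes: ["DX:PPD"]
seed: 1
sim:
  n_patients: 2000
  mixing_proportions: [0.22, 0.46, 0.32]
  length_mean: 18
  region_side: 12000
  tract_size: 2000
  outcome_or: [6.3, 2.43]
  baseline_ppd: 0.0114
  seed: 1
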