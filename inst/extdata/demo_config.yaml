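# Demo pipeline configuration: a small two-stratum cohort on one
# synthetic chromosome. Maps 1:1 onto run_config() / sim_config().
seed: 7
platform: SIM450
sim:
  n_samples:
    NLW: 60
    LAT: 80
  n_variants: 400
  n_cpgs: 60
  chrom_length: 20000000
scan:
  window_bp: 2000000
  n_perm: 200
thresholds:
  adjusted_p: 0.05
  r2: 0.5
  change: 0.20
  bonferroni_alpha: 0.05
deconvolve: true
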