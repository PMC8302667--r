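# Small demonstration configuration for `run_pipeline()` / `qrs.R simulate`.
cohort:
  "n": 800    # quoted: bare n/y are YAML 1.1 booleans
  j_relevant: 15
  j_noise: 40
  n_case_codes: 2
  b_relevant: 1.5
phenorm:
  r: 0.3
  B: 20000
  alpha_grid: {from: 0.0, to: 2.0, by: 0.05}
genotypes:
  n_genes: 5
  variants_per_gene: 15
  causal: {GENE001: 0.5}
n_bins: 60
preselect_threshold: 1.0e-5
family: inverse-gaussian
seed: 1
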