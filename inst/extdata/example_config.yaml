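# Example experiment configuration for run_experiment() /
# read_run_config(). Small sizes for illustration; defaults fill in any
# omitted block (see ?validate_run_config).
seed: 1
stages: [imputation, prediction]
out_dir: lcgblup_example_run
sim:
  K: 4
  n_sites: 100
  n_ind: 120
  mean_depth: 3.5
impute:
  K: 4
  n_iter: 20
depths: [0.5, 1.0, 2.0]
sample_sizes: [120]
g_types: [dosage]
models: [single, two]
traits:
  var_a: [10.0, 80.0]
  var_e: [8.0, 120.0]
  rg: 0.8
  re: 0.3
  n_qtl: 50
n_folds: 6
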