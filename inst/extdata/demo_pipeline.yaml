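# Demo configuration for run_pipeline(); unset keys fall back to
# default_pipeline_config().
scenario:
  n_runs: 2
  n_grid: 2
  years: [1951, 2100]
bias_correct: true
obs_model: 2
fit_models: [2, 6]
project_models: [2, 6]
betas: [0.0, 2.0]
reference: [1971, 2000]
target: [2070, 2099]
lambdas: [0.674, 1.0, 1.645]
sa_control:
  iters: 800
  n_chains: 1
seeds:
  scenario: 101
  reference: 202
  obs: 303
  fit: 404
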