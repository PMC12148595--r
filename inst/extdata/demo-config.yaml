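# Demo configuration for aesthsim::run_pipeline().
# Omitted entries fall back to the package defaults (default_config()).
seed: 7
out_dir: demo-run
design:
  n_subjects: 34
  n_stimuli_per_type: 20
  n_runs: 4
effects:
  beta_modality: -0.29
  beta_type: -0.56
geometry:
  w_mod: 1
  w_exp: 0
  w_type: 0
  n_channels: 200
  noise_sd: 1
analysis:
  dimensions: [moving]
  # map further region labels to NIfTI mask files to add levels of
  # resolution (e.g. a reward-network mask); "all" means every channel
  rois:
    wholebrain: all
  subset_high_vividness: true
  include_partial: false
  whitening: distance-covariance
  n_boot: 2000
  chains: 2
  iter: 1500
  warmup: 1500
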