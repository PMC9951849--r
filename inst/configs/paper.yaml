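# Full-scale profile: 128^3 at 1 mm isotropic, full network widths,
# 6000 hybrid samples split 5400/300/300, Adam with learning rate 1e-4 and
# batch size 8. Intended for workstation-scale runs.
phantom:
  grid_shape: [128, 128, 128]
  spacing: [1, 1, 1]
  n_phases: 10
  seed: 7
geometry:
  beam_model: parallel
  detector_shape: [128, 128]
  detector_spacing: [1, 1]
  step_mm: 0.5
demons:
  n_levels: 3
  iters_per_level: [50, 30, 20]
  smoothing_sigma_mm: 2.0
  max_step_mm: 2.0
train:
  lr: 1.0e-4
  batch_size: 8
  n_samples: 6000
  split: [5400, 300, 300]
  epochs: 100
  patience: 10
  loss_weights: {lambda_dice: 0.5, lambda_mi: 0.5, lambda_reg: 0.1}
  net:
    proj_size: [128, 128]
    vol_size: [128, 128, 128]
    unet_levels: 3
    scale_factor: 1.0
    seed: 11
  seed: 5
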