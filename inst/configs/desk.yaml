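# Desk-scale profile: 32^3 grid at 4 mm spacing (same physical anatomy as
# the full-scale profile), quarter-width network, 200 hybrid samples.
# Runs end to end on a single CPU.
phantom:
  grid_shape: [32, 32, 32]
  spacing: [4, 4, 4]
  n_phases: 10
  seed: 7
geometry:
  beam_model: parallel
  detector_shape: [32, 32]
  detector_spacing: [4, 4]
  step_mm: 2.0
demons:
  n_levels: 3
  iters_per_level: [30, 20, 10]
  smoothing_sigma_mm: 3.0
  max_step_mm: 4.0
train:
  lr: 1.0e-3
  batch_size: 8
  n_samples: 200
  split: [160, 20, 20]
  epochs: 20
  patience: 20
  loss_weights: {lambda_dice: 0.5, lambda_mi: 0.5, lambda_reg: 0.1}
  net:
    proj_size: [32, 32]
    vol_size: [32, 32, 32]
    unet_levels: 3
    scale_factor: 0.25
    seed: 11
  seed: 5
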