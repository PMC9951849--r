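# orthoreg

Non-rigid 2D/3D image registration from two orthogonal X-ray-like
projections, for lung and lung-tumour tracking.

## The problem

3D imaging (CT) carries the anatomical detail needed for radiotherapy and
interventional guidance, but is too slow and dose-heavy to acquire
continuously; planar X-rays are fast and cheap but lack depth. `orthoreg`
addresses the gap with a patient-specific deep-learning model: given a
previously acquired 3D *moving* volume `M_CT` and a pair of projections at
orthogonal angles (0° = anterior–posterior, 90° = lateral) taken at some
breathing moment, a convolutional network predicts the dense 3D deformation
field `φ_p` that warps `M_CT` onto the unseen anatomy at that moment:

    P_CT = M_CT ∘ φ_p,   φ_p = Net(DRR₀₀, DRR₉₀, M_CT)

The network is a residual 2D encoder over the channel-stacked projections,
a channel-to-depth lifting into a 3D feature map, and a 3D attention U-Net
regressing `φ_p`. It is trained per subject on synthetically deformed
copies of `M_CT`: nine demons inter-phase fields (from a 4D breathing
series) are superimposed pairwise with random weights and perturbed by
random thin-plate-spline fields (20–60 control points, 0–20 mm), each
hybrid field yielding a synthetic fixed anatomy and its ray-cast DRR pair
(`I = I₀·e^(−∫μ dl)`). The loss is

    L = λ₁(1 − Dice(F_seg, P_seg)) + λ₂(−MI(F_CT, P_CT)) + λ₃ Reg(φ_p),
    (λ₁, λ₂, λ₃) = (0.5, 0.5, 0.1)

optimised with Adam. Everything — the phantom 4D generator, DRR ray
casting, TPS/warping field algebra, multi-resolution demons, the network
with hand-derived backward passes, and the evaluation suite (Dice, 95%
Hausdorff, NCC, normalized MI, landmark mTRE, tumour centre-of-mass error)
— is implemented in this package and runs on a single CPU. See the methods
vignette (`vignettes/orthoreg-methods.Rmd`) for the model, conventions and
design decisions.

Because the original clinical 4D CT inputs cannot be shipped, the package
includes a synthetic breathing-lung phantom (lung ellipsoid, vessel
texture, embedded tumour, 75 landmarks) with an analytic, invertible
breathing law, so the entire pipeline builds, trains and evaluates itself
with no external data.

## Worked example

Desk-scale profile (32³ voxels at 4 mm, quarter-width network, 200 hybrid
samples, 20 epochs — `configs/desk.yaml`):

```r
library(orthoreg)
cfgs <- load_run_config(config_path("desk"))

ref   <- make_reference(cfgs$phantom)            # end-expiration anatomy
ser   <- make_phase_series(cfgs$phantom)         # 10-phase breathing 4D series
inter <- make_interphase_fields(ser, cfgs$demons)     # 9 demons fields
ds    <- build_dataset(ser, inter, cfgs$geometry,
                       n_samples = cfgs$train$n_samples,
                       seed = cfgs$train$seed)         # 200 DRR-pair samples
tr    <- train_regnet(ds, cfgs$train, verbose = TRUE)

ev <- evaluate_phases(tr$model, cfgs$phantom, ref,
                      seq(0.025, 0.975, length.out = 20), cfgs$geometry)
round(colMeans(ev), 4)
```

Output of this run (20 held-out breathing phases, ~11 min on one CPU):

```
phase_fraction    dice_before     dice_after  com_before_mm   com_after_mm
        0.5000         0.9543         0.9592         3.8000         0.8000
mtre_before_mm  mtre_after_mm
        3.7744         2.6494
```

Reading the numbers: without registration the moving lung overlaps the
per-phase truth at Dice 0.954 and the tumour centre of mass is off by
3.8 mm on average; after a single forward pass of the trained network the
lung Dice rises to 0.959, the tumour centre-of-mass error drops to 0.8 mm
and the mean landmark target registration error falls from 3.77 mm to
2.65 mm. The per-epoch training loss is in `tr$history`; it decreases from
−0.063 to −0.109 over the 20 epochs.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/orthoreg.R synth   --config inst/configs/desk.yaml --out out/phases
Rscript inst/cli/orthoreg.R train   --config inst/configs/desk.yaml --out out/run
Rscript inst/cli/orthoreg.R register --model out/run/model.rds \
    --drr0 a.tif --drr90 b.tif --moving m.nii.gz --seg s.nii.gz --out out/reg
```

`configs/paper.yaml` holds the full-scale recipe (128³ at 1 mm, full
widths, 6000 samples split 5400/300/300, learning rate 1e-4, batch 8) for
workstation runs.

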