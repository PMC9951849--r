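---
title: "Methods: non-rigid 2D/3D registration from orthogonal projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-rigid 2D/3D registration from orthogonal projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

In image-guided radiotherapy the full 3D anatomy at treatment time is not
available: acquiring CT continuously is slow and adds dose, while planar
X-rays are fast and cheap. `orthoreg` implements a patient-specific
deep-learning approach to this 2D/3D problem: given a previously acquired 3D
"moving" volume $M_{CT}$ (one breathing extreme) and **two orthogonal
projections** of the patient at some later breathing moment, a convolutional
network predicts the dense displacement field $\varphi_p$ such that warping
$M_{CT}$ by $\varphi_p$ reproduces the (unseen) 3D anatomy at that moment.
Inference is a single forward pass, so tracking an organ or tumour through
the breathing cycle requires only planar imaging at runtime.

The network has three parts:

1. **Residual 2D encoder.** The two projections are stacked as a 2-channel
   image and passed through a stem convolution, max pooling and two residual
   stages (widths 64 and 128 at full scale, two blocks per stage, the second
   stage strided).
2. **Channel-to-depth lifting.** The final 2D activation's channel axis is
   reinterpreted as a third spatial dimension and the resulting block is
   trilinearly resampled onto the moving volume's grid, giving a
   single-channel 3D feature map. How a stack of 2D channels becomes a
   3D-aligned feature volume is genuinely underdetermined by the
   architecture sketch this design follows; channels-as-depth followed by a
   resample is the simplest reading and is shape-validated at construction.
3. **3D attention U-Net.** The feature map is concatenated with the moving
   volume and passed through an encoder-decoder with skip connections;
   additive attention gates (1-voxel convolutions, internal width half the
   skip width) modulate each skip with the coarser decoder signal. The final
   1-voxel convolution emits 3 channels: the displacement field in voxel
   units, converted to mm by the grid spacing.

The head is initialised with near-zero weights so the untrained network
starts at (almost exactly) the identity transform — standard practice for
field-regression networks, which keeps early training stable. It is *near*
zero rather than exactly zero so that every upstream parameter receives a
nonzero gradient from the first step.

All layers (2D/3D convolution, pooling, trilinear resizing, attention
gates, the spatial-transformer warp) are implemented in this package with
hand-derived backward passes over C++ kernels; training runs on a single
CPU. The convolutions use a shift-and-add scheme over zero-padded buffers
with BLAS `daxpy`/`ddot` inner loops, which keeps the working set cache
resident at the volume sizes used here.

## Training data synthesis

Paired "projection + simultaneous CT" data do not exist, so training data
are synthesised from a 4D (breathing-resolved) series:

* **Inter-phase fields.** The reference phase (end expiration) is registered
  to each of the nine remaining phases with multi-resolution Thirion demons
  (below), giving nine displacement fields that span the observed breathing.
* **Intra-phase perturbations.** Small phase-specific shape changes are
  simulated by thin-plate splines: $N \sim U\{20..60\}$ control points
  placed uniformly in the volume, displacement directions uniform on the
  sphere, magnitudes uniform on $[0, 20]$ mm.
* **Hybrid superposition.** Two distinct inter-phase fields are blended
  convexly with $w \sim U(0,1)$ and the TPS field is added with an
  independent weight $v \sim U(0,1)$:
  $\varphi_{hybrid} = w\,\varphi_a + (1-w)\,\varphi_b + v\,\varphi_{intra}$.
  The blend is voxel-wise addition, not composition: the fields are being
  weighted and superimposed as vectors. The weight distributions are a
  design choice (the procedure is otherwise stated without them); the convex
  pair keeps the breathing component inside the hull of observed motion.

Each sample warps $M_{CT}$ and its segmentations by a fresh hybrid field to
create a synthetic fixed anatomy $F_{CT}, F_{seg}$, then renders its
orthogonal DRR pair. The full-scale recipe uses 6000 samples split
5400/300/300 into train/validation/test; every sample records the field that
produced it, so ground-truth correspondences (including landmark positions)
are known exactly.

## DRR generation

A digitally reconstructed radiograph follows the Beer–Lambert law
$I_n = I_0 e^{-\int \mu\, dl}$. `line_integral_image()` ray-marches with
trilinear sampling at a fixed step (at most one voxel) and accumulates
$\sum \mu \cdot \Delta l$; `to_intensity()` applies the exponential. The
network consumes min–max-normalized **line integrals** rather than
exponentiated intensities: the two are monotone equivalents, and the linear
domain is better conditioned as network input. The intensity conversion is
provided for completeness.

Angle 0° projects along the anterior–posterior axis, 90° along left–right,
with the detector v-axis superior–inferior; the source geometry never
states these axes, so they are fixed here by convention. The default beam is
parallel — source–detector distances are likewise unstated, and a parallel
beam admits exact axis-summation oracles — with a cone beam available
behind the same interface. The volume is treated as occupying its full
voxel extent (half a voxel beyond the boundary centres, edge-clamped), which
makes an axis-aligned parallel integral equal the column sum times spacing
exactly; the ray-march reproduces closed forms to well under 1%.

## Deformation-field algebra

All resampling uses **backward** fields (the output voxel at $x$ samples the
input at $x + u(x)$), the convention under which trilinear interpolation is
well posed. Forward fields are used only to transport points (landmarks,
ground truth); `invert_field()` bridges the two with the fixed-point
iteration $u_{k+1}(x) = -\varphi(x + u_k(x))$, which converges for
non-folding fields (positive Jacobian determinant, checked by central
differences). Out-of-bounds samples take the boundary value, avoiding
artificial air borders inside the field of view.

The 3D TPS uses the polyharmonic kernel $U(r) = r$ with an affine term —
the standard 3D choice when the method is named without a kernel. The
linear system is solved densely with one step of iterative refinement, and
kernel distances at evaluation time are computed by explicit differencing;
both are needed to reproduce control displacements to $10^{-6}$ mm (the
naive $\|a\|^2 + \|b\|^2 - 2ab$ expansion loses six digits near control
points). Affine displacement patterns, including pure translations, are
reproduced exactly.

The smoothness penalty is the diffusion regulariser: the sum over the nine
entries of the displacement Jacobian (per-mm forward differences) of the
mean squared value. With this normalisation a unit shear ($u_x = x$) scores
exactly 1, constants score 0, and scaling the field by $c$ scales the
penalty by $c^2$.

## Demons registration

The "conventional intensity-based" inter-phase registration and the 3D/3D
baseline are one implementation: Thirion demons with the update
$\delta = (f - m\circ\varphi)\,\nabla f / (\|\nabla f\|^2 + (f - m\circ\varphi)^2)$,
the denominator guarded to zero, steps capped at `max_step_mm`. The update
field is Gaussian-smoothed (`smoothing_sigma_mm`, fluid-like regularisation)
before being added, and the accumulated field receives a light half-voxel
diffusion per iteration; smoothing the *total* field with the full sigma
each iteration was measured to dissipate genuine displacement (a translation
of a smooth blob was recovered at only ~70%), which motivated the split.
A 3-level pyramid with a fixed iteration budget per level and early exit on
the mean update norm keeps runtimes reproducible. Defaults
(40/30/20 iterations, sigma 2 mm, 2 mm cap) recover a 2-voxel translation
of a smooth blob to within half a voxel and strictly reduce landmark error
on phantom phase pairs; they are deliberately not tuned to any external
benchmark.

## Loss

Training minimises

$$L = \lambda_1\,(1 - \mathrm{Dice}(F_{seg}, P_{seg}))
    + \lambda_2\,(-\mathrm{MI}(F_{CT}, P_{CT}))
    + \lambda_3\,\mathrm{Reg}(\varphi_p),\qquad
  (\lambda_1, \lambda_2, \lambda_3) = (0.5, 0.5, 0.1).$$

The similarity terms enter negated: the written objective combines
similarities, which cannot be minimised as printed, and the surrounding
procedure explicitly maximises similarity. Dice is the soft multi-category
form with $\varepsilon = 10^{-6}$, the masks warped with *linear*
interpolation during training so the term stays differentiable (nearest
mode is used for reported labels). MI is a Parzen-window estimate on a
32-bin joint histogram over $[0,1]$.

**MI kernel bandwidth.** The Gaussian window width trades gradient support
against estimator bias: mass from intensities near a bin edge is split
across adjacent bins, which inflates the joint entropy, and this bias grows
roughly linearly with the bandwidth (measured: ~60% of the self-MI at one
bin width, 1.5% at 0.03 bin widths on the phantom volume). The default is
0.03 bin widths: the estimate then matches a hard-histogram entropy oracle
to within 2% while intensities within a few sigma of a bin boundary (about
a fifth of the voxels of a typical volume) still carry gradients. The
evaluation-side `mi_score()` is a separate, non-differentiable
hard-histogram estimator whose headline value is the *normalized* MI
$2I/(H_a+H_b)$ — the variant whose range matches how such scores are
conventionally reported near 1 — with plain nats alongside.

## Evaluation suite

Dice, 95% Hausdorff surface distance (boundaries by 6-connectivity erosion
difference; the 95th linear-interpolation percentile of the *pooled*
symmetric distance set — the common medical-segmentation convention),
global Pearson NCC, normalized MI, mean target registration error over
matched landmarks (reported mean and SD in mm), and tumour centre-of-mass
error (unweighted mask centroids, per-axis LR/AP/SI and Euclidean total).
The Hausdorff implementation is tested against an $O(N^2)$ brute-force
oracle.

## The synthetic phantom

Because the original experiments used clinical 4D CT series that cannot be
redistributed, the package ships a breathing-lung phantom with the same
*structure*: a soft-tissue block (intensity 0.35), a low-intensity lung
ellipsoid (semi-axes 30/38/42 mm), vessel-like bright strands for texture,
a tumour sphere (radius 7 mm) strictly inside the lung, and 75 landmarks —
a typical 4D-CT landmark density. Intensities are normalised to $[0,1]$
(no CT-to-attenuation calibration is assumed anywhere). Breathing is an
analytic field: superior–inferior compression with a small
anterior–posterior term, constant inside the lung core, tapered smoothly to
zero outside a margin around the lung, and **linear in the phase fraction**
with peak displacement 8 mm — monotone, invertible, and with analytic
landmark ground truth. Every phase field is checked for a positive
Jacobian determinant when the phantom is constructed. The tumour sits in the rigid core, so its voxel
count is conserved across phases up to nearest-neighbour resampling.

What the phantom does *not* emulate: hysteresis (inhale/exhale path
asymmetry), sliding motion at the pleura, airway trees, CT noise texture
and beam artefacts, or the grayscale gap between DRRs and real X-rays.
Passing the end-to-end tests therefore demonstrates that the pipeline —
synthesis, projection, network, training, evaluation — is internally
correct and that the network can learn the mapping on data of this
structure; it does not certify clinical accuracy on real patients, for
which the original study's external data and full-scale training would be
required.

## Problem sizes and profiles

Two bundled profiles define the study conditions:

* `configs/paper.yaml` — 128³ voxels at 1 mm, full channel widths,
  6000 samples split 5400/300/300, Adam with learning rate $10^{-4}$,
  batch 8. This mirrors the full-scale recipe and is intended for
  workstation runs.
* `configs/desk.yaml` — the same physical anatomy on a 32³ grid at 4 mm,
  quarter-width network (`scale_factor = 0.25`), 200 samples split
  160/20/20, 20 epochs, learning rate $10^{-3}$ (chosen once for the
  smaller problem, where the full-scale rate is unnecessarily conservative).
  This is the profile the test suite and the acceptance script run; it
  completes end to end on one CPU in minutes. Held-out evaluation uses 20
  intermediate breathing phases never seen as training targets, comparing
  Dice, landmark mTRE and tumour centre-of-mass error before and after
  registration.

Epoch count and checkpoint selection are unspecified in the source design;
the package uses validation total loss with early stopping (patience 10 at
full scale).

## Numerical choices and degenerate inputs

* Field inversion: tolerance 0.01–0.05 mm, error on non-convergence with
  the residual reported.
* Warping: edge clamp; nearest mode for labels; linear mode exact for
  integer-voxel shifts.
* MI: constant images return 0 with a warning (zero entropy); NMI of two
  constant images is 1 if equal, else 0, logged.
* Dice: empty ground-truth categories are skipped and logged; empty-vs-empty
  `dice_score` is 1 by convention.
* NCC: errors on constant input (undefined).
* Demons: zero-gradient fixed image returns a zero field with a warning;
  non-finite intensities error.
* TPS: coplanar or duplicate controls produce a rank-deficiency error.
* All randomness is seed-scoped: callers' RNG state is saved and restored,
  and identical seeds give bit-identical phantoms, datasets and models.

## Known limitations

The CPU implementation is intended for desk-scale experimentation and
method study; full 128³ training with 6000 samples is configured but slow
without substantial hardware. The demons baseline is plain Thirion (no
symmetric or diffeomorphic variant), matching its role as a simple
classical reference. Projection physics omit scatter, beam hardening and
detector noise, and no DRR-to-X-ray domain correction is included — at
deployment on real radiographs such a correction (histogram matching or a
learned translation) would be a necessary preprocessing step.
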