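# Synthetic breathing-lung 4D phantom. A soft-tissue block contains a
# low-intensity lung ellipsoid with bright vessel-like strands and an
# embedded tumour sphere. Breathing is an analytic, superior-inferior
# dominant displacement field, linear in the phase fraction, so every
# phase has exact ground-truth deformations and landmark positions.

#' Specify a breathing-lung phantom
#'
#' @param grid_shape voxel grid, integer triple (default 64^3).
#' @param spacing voxel spacing mm (default 2 mm isotropic).
#' @param lung_semi_axes lung ellipsoid semi-axes mm (x = LR, y = AP, z = SI),
#'   centred in the grid.
#' @param tumor_offset tumour centre, mm offset from the lung centre.
#' @param tumor_radius tumour radius mm (0 for a tumour-free phantom).
#' @param breathing_amplitude peak displacement magnitude mm at end
#'   inspiration (phase fraction 1).
#' @param noise_sigma additive Gaussian intensity noise (images live in
#'   `[0, 1]`).
#' @param n_phases number of phases in the 4D series (>= 2).
#' @param n_landmarks landmarks sampled inside the lung (default 75,
#'   a typical 4D-CT landmark density).
#' @param seed integer seed controlling noise, vessels and landmarks.
#' @return An `orv_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L), spacing = c(2, 2, 2),
                         lung_semi_axes = c(30, 38, 42),
                         tumor_offset = c(10, 6, -12), tumor_radius = 7,
                         breathing_amplitude = 8, noise_sigma = 0.01,
                         n_phases = 10L, n_landmarks = 75L, seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (n_phases < 2) stop("n_phases must be at least 2")
  center <- (grid_shape - 1) / 2 * spacing
  tumor_center <- center + tumor_offset
  spec <- structure(list(grid_shape = grid_shape, spacing = spacing,
                         lung_semi_axes = lung_semi_axes,
                         lung_center = center, tumor_center = tumor_center,
                         tumor_radius = tumor_radius,
                         breathing_amplitude = breathing_amplitude,
                         noise_sigma = noise_sigma,
                         n_phases = as.integer(n_phases),
                         n_landmarks = as.integer(n_landmarks),
                         seed = as.integer(seed)),
                    class = "orv_phantom_spec")
  # tumour strictly inside the lung: conservative radius bound
  rho_c <- sqrt(sum(((tumor_center - center) / lung_semi_axes)^2))
  if (rho_c + tumor_radius / min(lung_semi_axes) >= 1)
    stop("tumor sphere is not strictly inside the lung ellipsoid")
  # no folding: the analytic phase-1 field must keep a positive Jacobian
  jd <- jacobian_det(breathing_field(spec, 1))
  if (min(jd) <= 0)
    stop(sprintf("breathing_amplitude %.1f mm folds the phase field (min |J| = %.3f)",
                 breathing_amplitude, min(jd)))
  spec
}

# normalized elliptical radius of mm points w.r.t. the lung
lung_rho <- function(spec, pts) {
  sqrt(((pts[, 1] - spec$lung_center[1]) / spec$lung_semi_axes[1])^2 +
       ((pts[, 2] - spec$lung_center[2]) / spec$lung_semi_axes[2])^2 +
       ((pts[, 3] - spec$lung_center[3]) / spec$lung_semi_axes[3])^2)
}

# smoothstep taper: 1 inside rho0, 0 beyond rho1
breath_taper <- function(rho, rho0 = 0.8, rho1 = 1.4) {
  t <- pmin(pmax((rho1 - rho) / (rho1 - rho0), 0), 1)
  t * t * (3 - 2 * t)
}

# analytic breathing displacement (mm) at mm points for a phase fraction
breathing_displacement <- function(spec, pts, phase_fraction) {
  rho <- lung_rho(spec, pts)
  w <- breath_taper(rho)
  amp <- spec$breathing_amplitude * phase_fraction / sqrt(1.09)
  uy <- 0.3 * (pts[, 2] - spec$lung_center[2]) / spec$lung_semi_axes[2]
  cbind(0, amp * w * uy, -amp * w)
}

#' Analytic breathing field of the phantom at a phase fraction
#'
#' Superior-inferior compression with a small anterior-posterior expansion,
#' tapered smoothly to zero outside a margin around the lung; displacement
#' scales linearly with `phase_fraction` and never exceeds
#' `breathing_amplitude`.
#'
#' @param spec an `orv_phantom_spec`.
#' @param phase_fraction breathing phase in `[0, 1]` (0 = reference,
#'   end expiration).
#' @return A forward `orv_field` (reference-to-phase point transport).
#' @export
breathing_field <- function(spec, phase_fraction) {
  stopifnot(phase_fraction >= 0, phase_fraction <= 1)
  g <- grid_mm(spec$grid_shape, spec$spacing)
  u <- breathing_displacement(spec, g, phase_fraction)
  deformation_field(array(u, c(spec$grid_shape, 3L)), spec$spacing,
                    convention = "forward")
}

#' Build the phantom reference (end-expiration) image
#'
#' @param spec an `orv_phantom_spec`.
#' @return A list with `volume` (intensities in `[0, 1]`), `lung_mask`,
#'   `tumor_mask` and `landmarks` (mm positions inside the lung). The result
#'   is deterministic given `spec$seed`.
#' @export
make_reference <- function(spec) {
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  gs <- spec$grid_shape; sp <- spec$spacing
  g <- grid_mm(gs, sp)
  rho <- lung_rho(spec, g)
  lung <- rho <= 1
  dt <- sqrt((g[, 1] - spec$tumor_center[1])^2 +
             (g[, 2] - spec$tumor_center[2])^2 +
             (g[, 3] - spec$tumor_center[3])^2)
  tumor <- spec$tumor_radius > 0 & dt <= spec$tumor_radius

  vol <- rep(0.35, nrow(g))          # soft-tissue background
  vol[lung] <- 0.05                  # air-filled lung

  # vessel-like curvilinear strands for texture: capsules between random
  # interior points
  n_vessels <- 8L
  for (v in seq_len(n_vessels)) {
    ends <- matrix(rnorm(6), 2, 3)
    ends <- ends / sqrt(rowSums(ends^2)) * runif(2, 0.2, 0.85)
    a <- spec$lung_center + ends[1, ] * spec$lung_semi_axes
    b <- spec$lung_center + ends[2, ] * spec$lung_semi_axes
    radius <- runif(1, 1.5, 3.5)
    ab <- b - a
    t <- pmin(pmax((sweep(g, 2, a) %*% ab) / sum(ab^2), 0), 1)
    proj <- sweep(t %*% t(ab), 2, a, "+")
    dseg <- sqrt(rowSums((g - proj)^2))
    vol[lung & dseg <= radius] <- 0.5
  }
  if (any(tumor)) vol[tumor] <- 0.8
  if (spec$noise_sigma > 0)
    vol <- vol + rnorm(length(vol), sd = spec$noise_sigma)
  vol <- pmin(pmax(vol, 0), 1)

  lm_pool <- which(lung & !tumor & rho <= 0.95)
  if (length(lm_pool) < spec$n_landmarks)
    stop("lung too small for the requested landmark count")
  lm_idx <- sample(lm_pool, spec$n_landmarks)
  list(volume = volume3d(array(vol, gs), sp),
       lung_mask = mask3d(array(lung, gs), sp),
       tumor_mask = mask3d(array(tumor, gs), sp),
       landmarks = landmark_set(g[lm_idx, , drop = FALSE]))
}

#' Generate the full 4D phase series
#'
#' Phase fractions are `0, 1/(n-1), ..., 1`; each phase volume and mask is
#' the reference resampled through the (inverted) analytic breathing field;
#' landmarks are transported analytically. Phase 0 is the reference itself
#' with an identically zero field.
#'
#' @param spec an `orv_phantom_spec`.
#' @return A list of phase samples, each a list with `volume`, `lung_mask`,
#'   `tumor_mask`, `true_field` (forward reference-to-phase), `landmarks`
#'   and `phase_fraction`.
#' @export
make_phase_series <- function(spec) {
  ref <- make_reference(spec)
  fractions <- seq(0, 1, length.out = spec$n_phases)
  lapply(fractions, function(f) phantom_phase(spec, ref, f))
}

#' Materialise one breathing phase of the phantom
#'
#' @param spec an `orv_phantom_spec`.
#' @param ref reference scene from [make_reference()].
#' @param f phase fraction in `[0, 1]`.
#' @return A phase sample (see [make_phase_series()]).
#' @export
phantom_phase <- function(spec, ref, f) {
  if (f == 0) {
    return(list(volume = ref$volume, lung_mask = ref$lung_mask,
                tumor_mask = ref$tumor_mask,
                true_field = zero_field(spec$grid_shape, spec$spacing,
                                        convention = "forward"),
                landmarks = ref$landmarks, phase_fraction = 0))
  }
  fwd <- breathing_field(spec, f)
  bwd <- invert_field(fwd, max_iter = 100L, tol_mm = 0.01)
  lm <- landmark_set(ref$landmarks$points +
                       breathing_displacement(spec, ref$landmarks$points, f),
                     ids = ref$landmarks$ids)
  list(volume = warp_volume(ref$volume, bwd, "linear"),
       lung_mask = warp_volume(ref$lung_mask, bwd, "nearest"),
       tumor_mask = warp_volume(ref$tumor_mask, bwd, "nearest"),
       true_field = fwd, landmarks = lm, phase_fraction = f)
}
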