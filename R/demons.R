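# Conventional intensity-based 3D/3D deformable registration: Thirion
# demons with Gaussian field regularization and a multi-resolution pyramid.
# Used to produce the inter-phase fields for hybrid augmentation and as the
# classical 3D/3D comparison baseline.

#' Demons registration settings
#'
#' @param n_levels multi-resolution pyramid depth (level 1 = coarsest).
#' @param iters_per_level iteration budget per level (coarsest first);
#'   length must equal `n_levels`.
#' @param smoothing_sigma_mm Gaussian sigma (mm) applied to the
#'   displacement update every iteration (fluid-like regularization); the
#'   accumulated field additionally receives a light half-voxel diffusion.
#' @param max_step_mm per-iteration displacement-update cap (mm).
#' @param stop_tol early-exit threshold on the mean update norm (mm).
#' @return An `orv_demons_config`.
#' @export
demons_config <- function(n_levels = 3L, iters_per_level = c(40L, 30L, 20L),
                          smoothing_sigma_mm = 2, max_step_mm = 2,
                          stop_tol = 0.01) {
  if (n_levels < 1) stop("n_levels must be >= 1")
  if (length(iters_per_level) != n_levels)
    stop("iters_per_level must have one entry per level")
  structure(list(n_levels = as.integer(n_levels),
                 iters_per_level = as.integer(iters_per_level),
                 smoothing_sigma_mm = smoothing_sigma_mm,
                 max_step_mm = max_step_mm, stop_tol = stop_tol),
            class = "orv_demons_config")
}

# image gradient (per mm) by central differences, per axis
image_gradient <- function(vol, spacing) {
  list(gx = central_diff(vol, 1) / spacing[1],
       gy = central_diff(vol, 2) / spacing[2],
       gz = central_diff(vol, 3) / spacing[3])
}

#' Thirion demons deformable registration
#'
#' Multi-resolution demons: at each level the displacement update is the
#' optical-flow-like step
#' `delta = (f - m o phi) grad(f) / (|grad f|^2 + (f - m o phi)^2)`
#' (guarded to zero where the denominator vanishes, capped at
#' `max_step_mm`), the update is Gaussian-smoothed before being added, the
#' accumulated field is lightly diffused, and the field is trilinearly
#' upsampled between levels. Intensities are expected in `[0, 1]`.
#'
#' @param fixed,moving `orv_volume`s on the same grid.
#' @param cfg an [demons_config()].
#' @return The backward `orv_field` aligning `moving` to `fixed`; attribute
#'   `trace` records the per-level NCC of the warped moving image.
#' @export
demons_register <- function(fixed, moving, cfg = demons_config()) {
  stop_if_grid_mismatch(fixed, moving, "fixed and moving")
  if (any(!is.finite(fixed)) || any(!is.finite(moving)))
    stop("demons_register: non-finite intensities")
  sp <- vox_spacing(fixed)
  gs <- grid_dim(fixed)
  if (max(abs(bare(fixed) - mean(fixed))) == 0) {
    warning("demons_register: fixed image has zero gradient; returning zero field")
    return(zero_field(gs, sp))
  }
  u <- NULL  # mm field at the current level
  trace <- numeric(0)
  for (lev in seq_len(cfg$n_levels)) {
    fac <- 2^(cfg$n_levels - lev)
    lgs <- pmax(4L, as.integer(round(gs / fac)))
    lsp <- sp * (gs - 1) / pmax(lgs - 1, 1)
    f_l <- cpp_resize3d(bare(fixed), lgs)
    m_l <- cpp_resize3d(bare(moving), lgs)
    u <- if (is.null(u)) array(0, c(lgs, 3L)) else {
      up <- cpp_resize3d(u, lgs)
      array(up, c(lgs, 3L))
    }
    gf <- image_gradient(f_l, lsp)
    g2 <- gf$gx^2 + gf$gy^2 + gf$gz^2
    sig_vox <- cfg$smoothing_sigma_mm / lsp
    for (it in seq_len(cfg$iters_per_level[lev])) {
      uvox <- u
      for (c3 in 1:3) uvox[, , , c3] <- uvox[, , , c3] / lsp[c3]
      warped <- cpp_warp(m_l, uvox, 0L)
      diff <- f_l - warped
      denom <- g2 + diff^2
      scale <- ifelse(denom < 1e-9, 0, diff / denom)
      dx <- scale * gf$gx; dy <- scale * gf$gy; dz <- scale * gf$gz
      mag <- sqrt(dx^2 + dy^2 + dz^2)
      over <- mag > cfg$max_step_mm
      if (any(over)) {
        shrink <- ifelse(over, cfg$max_step_mm / mag, 1)
        dx <- dx * shrink; dy <- dy * shrink; dz <- dz * shrink
        mag <- pmin(mag, cfg$max_step_mm)
      }
      # fluid-like regularization: smooth the update, then lightly
      # diffuse the accumulated field (half a voxel) for stability
      u[, , , 1] <- cpp_gauss_smooth3d(u[, , , 1] + cpp_gauss_smooth3d(dx, sig_vox), rep(0.5, 3))
      u[, , , 2] <- cpp_gauss_smooth3d(u[, , , 2] + cpp_gauss_smooth3d(dy, sig_vox), rep(0.5, 3))
      u[, , , 3] <- cpp_gauss_smooth3d(u[, , , 3] + cpp_gauss_smooth3d(dz, sig_vox), rep(0.5, 3))
      if (mean(mag) < cfg$stop_tol) break
    }
    uvox <- u
    for (c3 in 1:3) uvox[, , , c3] <- uvox[, , , c3] / lsp[c3]
    trace <- c(trace, stats::cor(as.vector(cpp_warp(m_l, uvox, 0L)),
                                 as.vector(f_l)))
  }
  fld <- deformation_field(u, sp, vox_origin(fixed), "backward")
  attr(fld, "trace") <- trace
  fld
}

#' Inter-phase deformation fields of a 4D series
#'
#' Registers the reference (phase 0, the moving image) to every remaining
#' phase, yielding `n - 1` backward fields (nine for a 10-phase series)
#' indexed by target phase.
#'
#' @param series phase-sample list from [make_phase_series()].
#' @param cfg an [demons_config()].
#' @return List of backward `orv_field`s, one per non-reference phase.
#' @export
make_interphase_fields <- function(series, cfg = demons_config()) {
  if (length(series) < 2) stop("series needs at least 2 phases")
  moving <- series[[1]]$volume
  lapply(series[-1], function(ph)
    demons_register(ph$volume, moving, cfg))
}
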