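# Deformation-field algebra: spatial-transformer warping, 3D thin-plate
# splines, the hybrid augmentation sampler, field inversion, landmark
# transport and the smoothness regulariser.

#' Warp a volume by a backward deformation field
#'
#' The spatial transformation: the output value at voxel position x is the
#' input sampled at x + u(x) (displacements in mm, converted to voxel units
#' internally). Out-of-bounds samples take the boundary value (edge clamp).
#'
#' @param volume an `orv_volume` (or `orv_mask`).
#' @param field a backward `orv_field` on the same grid.
#' @param mode `"linear"` (trilinear) or `"nearest"` (for label masks).
#' @return Warped `orv_volume` (masks stay `orv_mask` under `"nearest"`).
#' @export
warp_volume <- function(volume, field, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stop_if_grid_mismatch(volume, field, "volume and field")
  if (attr(field, "convention") != "backward")
    stop("warp_volume needs a backward field; invert forward fields first ",
         "(see invert_field)")
  out <- cpp_warp(bare(volume), field_to_vox(field),
                  if (mode == "nearest") 1L else 0L)
  if (inherits(volume, "orv_mask") && mode == "nearest")
    mask3d(out, vox_spacing(volume), vox_origin(volume))
  else
    volume3d(out, vox_spacing(volume), vox_origin(volume))
}

# ---------------------------------------------------------------------------
# Thin-plate splines. 3D polyharmonic kernel U(r) = r plus an affine term:
#   u(x) = sum_i w_i * |x - p_i| + a0 + A x
# per displacement component, with the usual orthogonality constraints
# (P' w = 0). Control displacements are reproduced exactly; affine (hence
# translational) displacement patterns are reproduced globally.

#' Control points for a thin-plate-spline field
#'
#' @param points n x 3 matrix of control locations (mm).
#' @param displacements n x 3 matrix of control displacements (mm).
#' @return An object of class `orv_controls`.
#' @export
control_points <- function(points, displacements) {
  points <- as.matrix(points); displacements <- as.matrix(displacements)
  stopifnot(ncol(points) == 3L, all(dim(points) == dim(displacements)))
  structure(list(points = points, displacements = displacements,
                 n = nrow(points)), class = "orv_controls")
}

#' Solve the TPS system and return an interpolating function
#'
#' @param controls an `orv_controls` with at least 4 non-coplanar points.
#' @return A function `f(pts)` mapping an m x 3 matrix of mm positions to an
#'   m x 3 matrix of mm displacements.
#' @export
tps_interpolator <- function(controls) {
  P <- controls$points
  D <- controls$displacements
  n <- nrow(P)
  if (n < 4) stop("TPS needs at least 4 control points")
  K <- as.matrix(stats::dist(P, diag = TRUE, upper = TRUE))
  Q <- cbind(1, P)
  A <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4, 4)))
  rhs <- rbind(D, matrix(0, 4, 3))
  coef <- tryCatch({
    x <- solve(A, rhs)
    x + solve(A, rhs - A %*% x)   # one step of iterative refinement
  }, error = function(e)
    stop("TPS system is rank-deficient (coplanar or duplicate control ",
         "points): ", conditionMessage(e)))
  W <- coef[1:n, , drop = FALSE]
  Aff <- coef[(n + 1):(n + 4), , drop = FALSE]
  function(pts) {
    pts <- as.matrix(pts)
    out <- matrix(0, nrow(pts), 3)
    # chunked kernel evaluation keeps memory bounded on large grids
    chunk <- max(1L, floor(2e6 / n))
    for (s in seq(1, nrow(pts), by = chunk)) {
      e <- min(nrow(pts), s + chunk - 1)
      block <- pts[s:e, , drop = FALSE]
      # distances by explicit differencing (no cancellation near controls)
      R <- matrix(0, nrow(block), n)
      for (j in seq_len(n))
        R[, j] <- sqrt((block[, 1] - P[j, 1])^2 + (block[, 2] - P[j, 2])^2 +
                       (block[, 3] - P[j, 3])^2)
      out[s:e, ] <- R %*% W + cbind(1, block) %*% Aff
    }
    out
  }
}

#' Evaluate a TPS displacement field on a voxel grid
#'
#' @param controls an `orv_controls`.
#' @param grid_shape integer triple.
#' @param spacing mm spacing triple.
#' @param origin grid origin (mm).
#' @param convention field convention tag for the result.
#' @return A dense `orv_field` reproducing the control displacements exactly
#'   at the control points.
#' @export
tps_field <- function(controls, grid_shape, spacing, origin = c(0, 0, 0),
                      convention = "backward") {
  f <- tps_interpolator(controls)
  g <- grid_mm(grid_shape, spacing, origin)
  u <- f(g)
  deformation_field(array(u, c(grid_shape, 3L)), spacing, origin, convention)
}

grid_mm <- function(grid_shape, spacing, origin = c(0, 0, 0)) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(grid_shape[a]) - 1) * spacing[a])
  cbind(rep(ax[[1]], times = grid_shape[2] * grid_shape[3]),
        rep(rep(ax[[2]], each = grid_shape[1]), times = grid_shape[3]),
        rep(ax[[3]], each = grid_shape[1] * grid_shape[2]))
}

#' Sample a random intra-phase TPS deformation
#'
#' Emulates small phase-specific shape changes: N ~ uniform on 20..60 control
#' points placed uniformly in the grid interior, displacement directions
#' uniform on the sphere with magnitudes uniform on 0-20 mm, interpolated by
#' a thin-plate spline.
#'
#' @param grid_shape,spacing,origin target grid.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param n_range range of the control-point count.
#' @param max_disp_mm maximum control displacement magnitude (mm).
#' @return A backward `orv_field`; attributes `controls` holds the sampled
#'   `orv_controls`.
#' @export
sample_intra_field <- function(grid_shape, spacing, seed,
                               origin = c(0, 0, 0),
                               n_range = c(20L, 60L), max_disp_mm = 20) {
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  n <- sample(seq(n_range[1], n_range[2]), 1)
  extent <- (grid_shape - 1) * spacing
  pts <- cbind(runif(n, 0, extent[1]), runif(n, 0, extent[2]),
               runif(n, 0, extent[3]))
  pts <- sweep(pts, 2, origin, "+")
  dir <- matrix(rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  mag <- runif(n, 0, max_disp_mm)
  ctl <- control_points(pts, dir * mag)
  fld <- tps_field(ctl, grid_shape, spacing, origin, convention = "backward")
  attr(fld, "controls") <- ctl
  fld
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Superimpose inter- and intra-phase fields with random weights
#'
#' Picks two distinct inter-phase fields uniformly, blends them convexly with
#' weight `w ~ U(0,1)`, and adds the intra-phase field scaled by an
#' independent `v ~ U(0,1)`:
#' `u = w * u_a + (1 - w) * u_b + v * u_intra` (voxel-wise addition).
#'
#' @param inter_fields list of `orv_field`s (the nine inter-phase fields in
#'   the canonical chain); at least two required.
#' @param intra an intra-phase `orv_field` (same grid), or `NULL` to omit.
#' @param seed integer seed.
#' @param weights optional list `list(pair = c(a, b), w =, v =)` overriding
#'   the random draws (test hook).
#' @return A backward `orv_field`; attribute `draw` records the indices and
#'   weights used.
#' @export
hybrid_field <- function(inter_fields, intra = NULL, seed = 1L,
                         weights = NULL) {
  if (length(inter_fields) < 2)
    stop("hybrid_field needs at least 2 inter-phase fields")
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  if (is.null(weights)) {
    pair <- sample(length(inter_fields), 2)
    w <- runif(1); v <- runif(1)
  } else {
    pair <- weights$pair; w <- weights$w; v <- weights$v
  }
  fa <- inter_fields[[pair[1]]]; fb <- inter_fields[[pair[2]]]
  stop_if_grid_mismatch(fa, fb, "inter-phase fields")
  u <- w * bare(fa) + (1 - w) * bare(fb)
  if (!is.null(intra)) {
    stop_if_grid_mismatch(fa, intra, "inter- and intra-phase fields")
    u <- u + v * bare(intra)
  }
  fld <- deformation_field(u, vox_spacing(fa), vox_origin(fa), "backward")
  attr(fld, "draw") <- list(pair = pair, w = w, v = v)
  fld
}

#' Invert a deformation field by fixed-point iteration
#'
#' Solves `u_inv(x) = -u(x + u_inv(x))` so that composing the field with its
#' inverse is close to the identity. Requires a non-folding field (positive
#' Jacobian determinant).
#'
#' @param field an `orv_field`.
#' @param max_iter iteration cap.
#' @param tol_mm stop when the largest update falls below this (mm).
#' @return The inverse `orv_field` (convention flipped).
#' @export
invert_field <- function(field, max_iter = 50L, tol_mm = 0.05) {
  sp <- vox_spacing(field)
  fvox <- field_to_vox(field)
  gs <- grid_dim(field)
  nv <- prod(gs)
  # iterate in voxel units on the flattened grid
  base <- cbind(rep(seq_len(gs[1]) - 1, times = gs[2] * gs[3]),
                rep(rep(seq_len(gs[2]) - 1, each = gs[1]), times = gs[3]),
                rep(seq_len(gs[3]) - 1, each = gs[1] * gs[2]))
  u <- matrix(0, nv, 3)
  comps <- lapply(1:3, function(c3) { f3 <- fvox[, , , c3]; dim(f3) <- gs; f3 })
  tolv <- tol_mm / max(sp)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    p <- base + u
    new_u <- -vapply(1:3, function(c3) cpp_sample_trilinear(comps[[c3]], p),
                     numeric(nv))
    delta <- max(abs(new_u - u))
    u <- new_u
    if (delta < tolv) {
      out <- array(u, c(gs, 3L))
      for (c3 in 1:3) out[, , , c3] <- out[, , , c3] * sp[c3]
      conv <- if (attr(field, "convention") == "backward") "forward" else "backward"
      return(deformation_field(out, sp, vox_origin(field), conv))
    }
  }
  stop(sprintf("invert_field did not converge in %d iterations (last update %.4f mm)",
               max_iter, delta * max(sp)))
}

#' Transport landmarks through a forward field
#'
#' Each point p maps to p + u(p), with the field trilinearly interpolated at
#' the point. Points outside the field grid are excluded with a warning.
#'
#' @param points an `orv_landmarks` (mm).
#' @param field a forward `orv_field`.
#' @return An `orv_landmarks`; attribute `n_excluded` reports any drops.
#' @export
warp_points <- function(points, field) {
  if (attr(field, "convention") != "forward")
    stop("warp_points needs a forward field (point-transport convention)")
  gs <- grid_dim(field)
  vox <- mm_to_vox0(field, points$points)
  inside <- vox[, 1] >= 0 & vox[, 1] <= gs[1] - 1 &
            vox[, 2] >= 0 & vox[, 2] <= gs[2] - 1 &
            vox[, 3] >= 0 & vox[, 3] <= gs[3] - 1
  if (any(!inside))
    warning(sprintf("%d landmark(s) outside the field grid were excluded",
                    sum(!inside)))
  vin <- vox[inside, , drop = FALSE]
  f <- bare(field)
  u <- vapply(1:3, function(c3) {
    f3 <- f[, , , c3]; dim(f3) <- gs
    cpp_sample_trilinear(f3, vin)
  }, numeric(nrow(vin)))
  dim(u) <- c(nrow(vin), 3L)
  out <- landmark_set(points$points[inside, , drop = FALSE] + u,
                      ids = points$ids[inside])
  attr(out, "n_excluded") <- sum(!inside)
  out
}

#' Smoothness penalty of a deformation field
#'
#' The diffusion regulariser: the sum over the nine Jacobian entries
#' (three displacement components by three spatial directions) of the mean
#' squared forward difference, with gradients taken per mm. Zero iff the
#' field is constant; quadratic in the field.
#'
#' @param field an `orv_field`.
#' @return Non-negative scalar.
#' @export
smoothness_penalty <- function(field) {
  sp <- vox_spacing(field)
  total <- 0
  for (c3 in 1:3) {
    u <- field[, , , c3]
    d <- dim(u)
    if (d[1] > 1) total <- total + mean(((u[-1, , ] - u[-d[1], , ]) / sp[1])^2)
    if (d[2] > 1) total <- total + mean(((u[, -1, ] - u[, -d[2], ]) / sp[2])^2)
    if (d[3] > 1) total <- total + mean(((u[, , -1] - u[, , -d[3]]) / sp[3])^2)
  }
  total
}

#' Jacobian determinant of a deformation map
#'
#' Determinant of I + grad(u) by central finite differences (per mm); values
#' above zero everywhere mean the map does not fold.
#'
#' @param field an `orv_field`.
#' @return 3D array of determinants on the field grid.
#' @export
jacobian_det <- function(field) {
  sp <- vox_spacing(field)
  g <- array(0, c(grid_dim(field), 3, 3))
  for (c3 in 1:3) {
    u <- field[, , , c3]
    g[, , , c3, 1] <- central_diff(u, 1) / sp[1]
    g[, , , c3, 2] <- central_diff(u, 2) / sp[2]
    g[, , , c3, 3] <- central_diff(u, 3) / sp[3]
  }
  for (a in 1:3) g[, , , a, a] <- g[, , , a, a] + 1
  g[, , , 1, 1] * (g[, , , 2, 2] * g[, , , 3, 3] - g[, , , 2, 3] * g[, , , 3, 2]) -
  g[, , , 1, 2] * (g[, , , 2, 1] * g[, , , 3, 3] - g[, , , 2, 3] * g[, , , 3, 1]) +
  g[, , , 1, 3] * (g[, , , 2, 1] * g[, , , 3, 2] - g[, , , 2, 2] * g[, , , 3, 1])
}

central_diff <- function(u, axis) {
  d <- dim(u)
  n <- d[axis]
  idx_hi <- pmin(seq_len(n) + 1, n)
  idx_lo <- pmax(seq_len(n) - 1, 1)
  denom <- (idx_hi - idx_lo)
  sl <- function(i) switch(axis, u[i, , , drop = FALSE],
                           u[, i, , drop = FALSE], u[, , i, drop = FALSE])
  out <- (sl(idx_hi) - sl(idx_lo))
  sweep_axis(out, axis, denom, "/")
}

sweep_axis <- function(a, axis, v, op) {
  d <- dim(a)
  perm_v <- array(rep(v, each = prod(d[seq_len(axis - 1)])), d)
  get(op)(a, perm_v)
}
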