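# Deformation algebra: warping semantics, thin-plate splines, the hybrid
# sampler, field inversion, landmark transport and the smoothness penalty.

test_that("warp_volume: identity, integer shifts, nearest-mode labels", {
  v <- desk_ref()$volume
  gs <- dim(v); sp <- attr(v, "spacing")
  expect_identical(unclass(warp_volume(v, zero_field(gs, sp))), unclass(v))
  # constant -1 voxel field along x -> index shift by +1 with edge padding
  f <- const_field(gs, sp, c(-sp[1], 0, 0))
  w <- warp_volume(v, f)
  expect_equal(unclass(w)[2:gs[1], , ], unclass(v)[1:(gs[1] - 1), , ],
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(unclass(w)[1, , ], unclass(v)[1, , ], tolerance = 1e-14,
               ignore_attr = TRUE)
  m <- warp_volume(desk_ref()$lung_mask, const_field(gs, sp, c(3, -2, 5)),
                   mode = "nearest")
  expect_true(all(m %in% c(0, 1)))
  expect_s3_class(m, "orv_mask")
  # forward fields are rejected by the resampler
  fwd <- breathing_field(desk_spec(), 0.5)
  expect_error(warp_volume(v, fwd), "backward")
})

test_that("TPS reproduces controls exactly and absorbs affine patterns", {
  set.seed(21)
  n <- 30
  ctl <- control_points(matrix(runif(3 * n, 0, 124), n, 3),
                        matrix(runif(3 * n, -20, 20), n, 3))
  f <- tps_interpolator(ctl)
  expect_lt(max(abs(f(ctl$points) - ctl$displacements)), 1e-6)
  # all-zero displacements give the zero field
  z <- tps_field(control_points(ctl$points, 0 * ctl$displacements),
                 c(8, 8, 8), c(16, 16, 16))
  expect_lt(max(abs(z)), 1e-9)
  # a pure translation is reproduced globally (affine term absorbs it)
  tr <- control_points(matrix(runif(60, 0, 124), 20, 3),
                       matrix(rep(c(3, -2, 5), each = 20), 20, 3))
  ft <- tps_field(tr, c(8, 8, 8), c(16, 16, 16))
  expect_lt(max(abs(ft[, , , 1] - 3)), 1e-6)
  expect_lt(max(abs(ft[, , , 2] + 2)), 1e-6)
  expect_lt(max(abs(ft[, , , 3] - 5)), 1e-6)
  # a general affine displacement pattern is reproduced exactly as well
  A <- matrix(c(0.02, 0.01, 0, -0.01, 0.03, 0.005, 0, 0.01, -0.02), 3, 3)
  pts <- matrix(runif(75, 0, 124), 25, 3)
  fa <- tps_interpolator(control_points(pts, pts %*% A))
  probe <- matrix(runif(30, 0, 124), 10, 3)
  expect_lt(max(abs(fa(probe) - probe %*% A)), 1e-6)
  # degenerate (coplanar) controls are rejected with a diagnostic
  flat <- cbind(runif(10, 0, 50), runif(10, 0, 50), 7)
  expect_error(tps_interpolator(control_points(flat, flat)), "rank-deficient")
})

test_that("intra-phase sampler is deterministic and respects its bounds", {
  f1 <- sample_intra_field(c(8, 8, 8), c(16, 16, 16), seed = 5)
  f2 <- sample_intra_field(c(8, 8, 8), c(16, 16, 16), seed = 5)
  expect_identical(unclass(f1), unclass(f2))
  for (s in 1:300) {
    fld <- sample_intra_field(c(8, 8, 8), c(16, 16, 16), seed = s)
    ctl <- attr(fld, "controls")
    expect_true(ctl$n >= 20 && ctl$n <= 60)
    expect_lte(max(sqrt(rowSums(ctl$displacements^2))), 20)
  }
})

test_that("hybrid_field blends fields with the stated weights", {
  gs <- c(8, 8, 8); sp <- c(16, 16, 16)
  fa <- const_field(gs, sp, c(2, 0, 0))
  fb <- const_field(gs, sp, c(0, 4, 0))
  intra <- const_field(gs, sp, c(0, 0, 6))
  # forced weights: w = 1, v = 0 reproduces the first field exactly
  h <- hybrid_field(list(fa, fb), intra, weights = list(pair = c(1, 2), w = 1, v = 0))
  expect_identical(as.vector(h), as.vector(fa))
  expect_identical(dim(h), dim(fa))
  # zero inputs give a zero output
  z <- const_field(gs, sp, c(0, 0, 0))
  expect_true(all(hybrid_field(list(z, z), z, seed = 3) == 0))
  # random draw matches the voxel-wise formula recomputed from the draw
  h2 <- hybrid_field(list(fa, fb), intra, seed = 9)
  d <- attr(h2, "draw")
  flds <- list(fa, fb)
  manual <- d$w * unclass(flds[[d$pair[1]]]) +
    (1 - d$w) * unclass(flds[[d$pair[2]]]) + d$v * unclass(intra)
  expect_equal(unclass(h2), manual, tolerance = 1e-14, ignore_attr = TRUE)
  expect_error(hybrid_field(list(fa)), "at least 2")
})

test_that("invert_field inverts translations and round-trips smooth fields", {
  gs <- c(16, 16, 16); sp <- c(8, 8, 8)
  z <- invert_field(zero_field(gs, sp))
  expect_true(all(z == 0))
  ci <- invert_field(const_field(gs, sp, c(5, -3, 2)))
  core <- ci[4:13, 4:13, 4:13, ]  # interior, away from edge clamping
  expect_lt(max(abs(core[, , , 1] + 5)), 0.1)
  expect_lt(max(abs(core[, , , 2] - 3)), 0.1)
  expect_lt(max(abs(core[, , , 3] + 2)), 0.1)
  # warp a smooth blob through a breathing field and back
  spec <- desk_spec()
  fwd <- breathing_field(spec, 1)
  bwd <- invert_field(fwd, max_iter = 100, tol_mm = 0.01)
  v <- blob_volume(spec$grid_shape, spec$spacing, sigma_mm = 18)
  there <- warp_volume(v, bwd)
  # the forward field, seen as a resampling field, plays the inverse role
  back <- warp_volume(there, deformation_field(unclass(fwd),
                                               attr(fwd, "spacing"),
                                               convention = "backward"))
  expect_gt(ncc(back, v), 0.99)
})

test_that("warp_points transports landmarks through forward fields", {
  spec <- desk_spec()
  lm <- desk_ref()$landmarks
  zf <- zero_field(spec$grid_shape, spec$spacing, convention = "forward")
  expect_identical(warp_points(lm, zf)$points, lm$points)
  cf <- const_field(spec$grid_shape, spec$spacing, c(3, 0, 0))
  attr(cf, "convention") <- "forward"
  expect_equal(warp_points(lm, cf)$points,
               lm$points + matrix(rep(c(3, 0, 0), each = nrow(lm$points)),
                                  ncol = 3), tolerance = 1e-12)
  # dense-oracle agreement: warp a point mask and compare centroids
  f <- breathing_field(spec, 1)
  pt_mm <- spec$tumor_center
  moved <- warp_points(landmark_set(matrix(pt_mm, 1)), f)$points
  bwd <- invert_field(f, max_iter = 100, tol_mm = 0.005)
  pm <- array(0, spec$grid_shape)
  idx <- round(pt_mm / spec$spacing) + 1
  pm[idx[1], idx[2], idx[3]] <- 1
  wm <- warp_volume(volume3d(pm, spec$spacing), bwd, "linear")
  com <- colSums(which(unclass(wm) > 0, arr.ind = TRUE) * unclass(wm)[unclass(wm) > 0]) /
    sum(wm) - 1
  expect_lt(max(abs(com * spec$spacing - moved)), 0.5 * max(spec$spacing) +
              max(abs(pt_mm - (idx - 1) * spec$spacing)))
  # points outside the grid are excluded with a report
  far <- landmark_set(rbind(pt_mm, c(-50, 0, 0)))
  expect_warning(out <- warp_points(far, f), "excluded")
  expect_equal(nrow(out$points), 1)
})

test_that("smoothness penalty: zero on constants, unit shear, quadratic", {
  gs <- c(4, 4, 4); sp <- c(1, 1, 1)
  expect_equal(smoothness_penalty(const_field(gs, sp, c(5, -2, 1))), 0)
  # u_x = x (mm) -> exactly one unit mean squared gradient entry
  a <- array(0, c(gs, 3))
  a[, , , 1] <- array(rep(0:3, 16), gs)
  shear <- deformation_field(a, sp)
  expect_equal(smoothness_penalty(shear), 1, tolerance = 1e-12)
  double <- deformation_field(2 * a, sp)
  expect_equal(smoothness_penalty(double), 4, tolerance = 1e-12)
})
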