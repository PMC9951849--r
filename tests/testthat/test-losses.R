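# Training losses: soft Dice, Parzen mutual information and the combined
# objective.

test_that("dice_term matches hand counts and its limiting cases", {
  f <- array(0, c(2, 2, 2)); p <- array(0, c(2, 2, 2))
  # |F| = 4 (left half), |P| = 4 (front half), overlap 2 -> 0.5
  f[1, , ] <- 1
  p[, 1, ] <- 1
  expect_equal(dice_term(p, f), 2 * 2 / (4 + 4), tolerance = 1e-5)
  expect_equal(dice_term(f, f), 1, tolerance = 1e-5)
  g <- array(0, c(2, 2, 2)); g[2, 2, 2] <- 1
  h <- array(0, c(2, 2, 2)); h[1, 1, 1] <- 1
  expect_lt(dice_term(g, h), 1e-5)
  # invariant to a simultaneous voxel permutation of both masks
  set.seed(3)
  perm <- sample(8)
  fp <- array(as.vector(f)[perm], c(2, 2, 2))
  pp <- array(as.vector(p)[perm], c(2, 2, 2))
  expect_equal(dice_term(pp, fp), dice_term(p, f))
  # empty ground-truth categories are skipped with a message
  expect_message(v <- dice_term(list(p, p * 0), list(f, f * 0)), "skipped")
  expect_equal(v, dice_term(p, f))
})

test_that("mi_term agrees with the hard-histogram entropy oracle", {
  a <- as.vector(desk_ref()$volume)
  h <- hard_entropy01(a)
  expect_lt(abs(mi_term(a, a) - h) / h, 0.02)
  set.seed(4)
  u <- runif(1e5)
  hu <- hard_entropy01(u)
  expect_lt(abs(mi_term(u, u) - hu) / hu, 0.02)
})

test_that("mi_term is symmetric and near zero for independent noise", {
  set.seed(5)
  x <- runif(1e5); y <- runif(1e5)
  expect_lt(mi_term(x, y), 0.02)
  expect_lt(abs(mi_term(x, y) - mi_term(y, x)), 1e-6)
  expect_warning(mi_term(rep(0.5, 100), runif(100)), "constant")
})

test_that("total_loss composes the three terms with the lambda weights", {
  w <- loss_weights()
  expect_equal(w$lambda_dice, 0.5)
  expect_equal(w$lambda_mi, 0.5)
  expect_equal(w$lambda_reg, 0.1)
  ref <- desk_ref()
  gs <- dim(ref$volume); sp <- attr(ref$volume, "spacing")
  zf <- zero_field(gs, sp)
  v <- unclass(ref$volume); m <- unclass(ref$lung_mask)
  # perfect prediction with zero field: only the MI reward remains
  L <- total_loss(v, v, m, m, zf, w)
  H <- mi_term(v, v)
  expect_equal(as.numeric(L), w$lambda_dice * (1 - 1) - w$lambda_mi * H,
               tolerance = 1e-4)
  # reg-only weights on a constant field give exactly zero
  L0 <- total_loss(v, v, m, m, const_field(gs, sp, c(4, 4, 4)),
                   loss_weights(0, 0, 1))
  expect_equal(as.numeric(L0), 0)
  # loss decreases when Dice increases, all else fixed
  worse <- m * 0; worse[1:8, , ] <- 1
  L_bad <- total_loss(v, v, worse, m, zf, w)
  expect_gt(as.numeric(L_bad), as.numeric(L))
})

test_that("loss gradients match finite differences through the warp path", {
  ref <- tiny_ref()
  spec <- tiny_spec()
  fwd <- breathing_field(spec, 0.8)
  bwd <- invert_field(fwd)
  fixed <- warp_volume(ref$volume, bwd)
  fixed_seg <- warp_volume(ref$lung_mask, bwd, "nearest")
  phi <- array(rnorm(prod(spec$grid_shape) * 3, 0, 0.2), c(spec$grid_shape, 3))
  w <- loss_weights()
  loss_of <- function(phi) {
    p_ct <- orthoreg:::cpp_warp(unclass(ref$volume), phi, 0L)
    p_seg <- orthoreg:::cpp_warp(unclass(ref$lung_mask), phi, 0L)
    fld <- phi
    for (c3 in 1:3) fld[, , , c3] <- fld[, , , c3] * spec$spacing[c3]
    as.numeric(total_loss(p_ct, unclass(fixed), p_seg, unclass(fixed_seg),
                          deformation_field(fld, spec$spacing), w))
  }
  # analytic gradient assembled the same way the trainer does it
  p_ct <- orthoreg:::cpp_warp(unclass(ref$volume), phi, 0L)
  p_seg <- orthoreg:::cpp_warp(unclass(ref$lung_mask), phi, 0L)
  dg <- orthoreg:::dice_term_grad(list(p_seg), list(unclass(fixed_seg)))
  mg <- orthoreg:::mi_term_grad(p_ct, unclass(fixed))
  fldmm <- phi
  for (c3 in 1:3) fldmm[, , , c3] <- fldmm[, , , c3] * spec$spacing[c3]
  rg <- orthoreg:::smoothness_penalty_grad(
    deformation_field(fldmm, spec$spacing))
  gphi <- orthoreg:::cpp_warp_field_grad(unclass(ref$volume), phi,
                                         -w$lambda_mi * mg$grad) +
    orthoreg:::cpp_warp_field_grad(unclass(ref$lung_mask), phi,
                                   -w$lambda_dice * dg$grads[[1]])
  greg <- w$lambda_reg * rg$grad
  for (c3 in 1:3) greg[, , , c3] <- greg[, , , c3] * spec$spacing[c3]
  gphi <- gphi + greg
  set.seed(8)
  idx <- sample(length(phi), 5)
  eps <- 1e-5
  for (i in idx) {
    up <- phi; up[i] <- up[i] + eps
    dn <- phi; dn[i] <- dn[i] - eps
    num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
    expect_lt(abs(num - gphi[i]), 1e-4 + 0.05 * abs(num))
  }
})
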