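# Demons 3D/3D registration: fixed points, known-translation recovery,
# similarity improvement and the inter-phase field factory.

test_that("registering an image to itself yields a near-zero field", {
  v <- blob_volume()
  fld <- demons_register(v, v, demons_config(2, c(10, 10)))
  expect_lt(mean(sqrt(fld[, , , 1]^2 + fld[, , , 2]^2 + fld[, , , 3]^2)),
            0.1 * min(attr(v, "spacing")))
})

test_that("a 2-voxel translation of a smooth blob is recovered", {
  fx <- blob_volume()
  mv <- blob_volume(centre_mm = c(31 + 4, 31, 31))  # +2 voxels in x
  fld <- demons_register(fx, mv, demons_config(3, c(40, 30, 20),
                                               smoothing_sigma_mm = 2,
                                               max_step_mm = 4))
  supp <- unclass(fx) > 0.1
  err <- abs(fld[, , , 1][supp] - 4)
  expect_lt(mean(err), 0.5 * 2)  # within half a voxel on average
  # NCC is non-decreasing across pyramid levels
  expect_true(all(diff(attr(fld, "trace")) > -1e-6))
})

test_that("zero-gradient fixed image returns a zero field with a warning", {
  flat <- volume3d(array(0.5, c(16, 16, 16)), c(2, 2, 2))
  mv <- blob_volume(c(16, 16, 16), c(2, 2, 2))
  expect_warning(fld <- demons_register(flat, mv), "zero gradient")
  expect_true(all(fld == 0))
  bad <- volume3d(array(c(NA, runif(16^3 - 1)), c(16, 16, 16)), c(2, 2, 2))
  expect_error(demons_register(bad, mv), "non-finite")
})

test_that("phantom phase registration improves NCC and reduces mTRE", {
  ser <- desk_series()
  fixed <- ser[[10]]; moving <- ser[[1]]
  fld <- demons_register(fixed$volume, moving$volume,
                         demons_config(3, c(30, 20, 10),
                                       smoothing_sigma_mm = 3, max_step_mm = 4))
  warped <- warp_volume(moving$volume, fld)
  expect_gt(ncc(warped, fixed$volume), ncc(moving$volume, fixed$volume))
  # backward field maps fixed-frame landmarks toward their moving positions
  q <- fixed$landmarks$points
  fvox <- orthoreg:::field_to_vox(fld)
  qv <- orthoreg:::mm_to_vox0(fld, q)
  gs <- dim(fld)[1:3]
  u <- vapply(1:3, function(c3) {
    f3 <- fvox[, , , c3]; dim(f3) <- gs
    orthoreg:::cpp_sample_trilinear(f3, qv) * attr(fld, "spacing")[c3]
  }, numeric(nrow(q)))
  before <- mtre(fixed$landmarks, moving$landmarks)$mean_mm
  after <- mtre(landmark_set(q + u, fixed$landmarks$ids),
                moving$landmarks)$mean_mm
  expect_gt(before, max(attr(fld, "spacing")))  # initial error > 1 voxel
  expect_lt(after, before)
})

test_that("stronger update smoothing yields smoother fields", {
  ser <- desk_series()
  cfg_rough <- demons_config(2, c(20, 15), smoothing_sigma_mm = 1.5,
                             max_step_mm = 4)
  cfg_smooth <- demons_config(2, c(20, 15), smoothing_sigma_mm = 6,
                              max_step_mm = 4)
  f_rough <- demons_register(ser[[6]]$volume, ser[[1]]$volume, cfg_rough)
  f_smooth <- demons_register(ser[[6]]$volume, ser[[1]]$volume, cfg_smooth)
  expect_lt(smoothness_penalty(f_smooth), smoothness_penalty(f_rough))
})

test_that("a 10-phase series yields nine inter-phase fields, ordered by amplitude", {
  inter <- desk_inter_fields()
  expect_length(inter, 9)
  mags <- vapply(inter, function(f)
    mean(sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2)), numeric(1))
  # the linear breathing law makes later phases larger targets
  expect_lt(mags[1], mags[5])
  expect_lt(mags[1], mags[9])
  # registering phase 0 to itself is the degenerate request
  ser <- desk_series()
  self_fld <- demons_register(ser[[1]]$volume, ser[[1]]$volume,
                              demons_config(2, c(10, 5)))
  expect_lt(mean(abs(self_fld)), 0.2)
  expect_error(make_interphase_fields(ser[1]), "at least 2")
})

test_that("demons configuration is validated", {
  expect_error(demons_config(n_levels = 0), "n_levels")
  expect_error(demons_config(n_levels = 2, iters_per_level = c(5L)),
               "per level")
})
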