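# Registration network: shape contracts, initialisation, determinism and
# gradient flow.

small_cfg <- function(scale = 0.25, seed = 3)
  net_config(proj_size = c(16, 16), vol_size = c(16, 16, 16),
             unet_levels = 2, scale_factor = scale, seed = seed)

tiny_pair <- function(seed = 1) {
  set.seed(seed)
  structure(list(drr_0 = matrix(runif(256), 16, 16),
                 drr_90 = matrix(runif(256), 16, 16),
                 geometry = NULL, domain_tag = "line_integral"),
            class = "orv_projection_pair")
}

test_that("encode_projections obeys the shape contract and is deterministic", {
  model <- regnet_init(small_cfg())
  fm1 <- encode_projections(tiny_pair(), model)
  expect_equal(dim(fm1), c(16, 16, 16))
  fm2 <- encode_projections(tiny_pair(), model)
  expect_identical(fm1, fm2)
  # channel order matters: swapping the projections changes the output
  p <- tiny_pair()
  swapped <- p
  swapped$drr_0 <- p$drr_90; swapped$drr_90 <- p$drr_0
  expect_gt(max(abs(encode_projections(swapped, model) - fm1)), 1e-8)
  bad <- p; bad$drr_90 <- matrix(0, 8, 8)
  expect_error(encode_projections(bad, model), "detector shape")
})

test_that("predict_field emits a near-zero field at initialisation", {
  model <- regnet_init(small_cfg())
  mv <- volume3d(array(runif(16^3), c(16, 16, 16)), c(8, 8, 8))
  fm <- encode_projections(tiny_pair(), model)
  fld <- predict_field(fm, mv, model)
  expect_equal(dim(fld), c(16, 16, 16, 3))
  mean_vox <- mean(abs(orthoreg:::field_to_vox(fld)))
  expect_lt(mean_vox, 0.01)
  expect_gt(mean_vox, 0)           # not exactly zero: gradients must flow
})

test_that("every trainable parameter receives a nonzero gradient", {
  spec <- tiny_spec()
  ref <- tiny_ref()
  model <- regnet_init(small_cfg())
  fwd <- breathing_field(spec, 0.8)
  bwd <- invert_field(fwd)
  sample <- list(
    drr_pair = tiny_pair(4),
    fixed = warp_volume(ref$volume, bwd),
    fixed_seg = list(lung = warp_volume(ref$lung_mask, bwd, "nearest"),
                     tumor = warp_volume(ref$tumor_mask, bwd, "nearest")))
  st <- orthoreg:::train_step_grad(model, sample, ref$volume,
                                   list(lung = ref$lung_mask,
                                        tumor = ref$tumor_mask),
                                   loss_weights(), 32L)
  leaves <- orthoreg:::param_leaves(st$grads)
  expect_gt(length(leaves), 20)
  for (nm in names(leaves)) {
    expect_true(any(leaves[[nm]] != 0), label = paste("gradient of", nm))
  }
})

test_that("capacity scales monotonically and shapes audit across scales", {
  counts <- vapply(c(0.25, 0.5, 1), function(s)
    regnet_n_params(regnet_init(small_cfg(scale = s))), numeric(1))
  expect_true(all(diff(counts) > 0))
  mv <- volume3d(array(runif(16^3), c(16, 16, 16)), c(8, 8, 8))
  for (s in c(0.25, 0.5, 1)) {
    model <- regnet_init(small_cfg(scale = s))
    out <- regnet_forward(tiny_pair(), mv, mask3d(array(0:1, c(16, 16, 16)),
                                                  c(8, 8, 8)), model)
    expect_equal(dim(out$field), c(16, 16, 16, 3))
    expect_equal(dim(out$pred_vol), c(16, 16, 16))
  }
})

test_that("a zero head gives the exact identity transform", {
  model <- regnet_init(small_cfg())
  model$params$unet$head$W[] <- 0
  model$params$unet$head$b[] <- 0
  mv <- volume3d(array(runif(16^3), c(16, 16, 16)), c(8, 8, 8))
  out <- regnet_forward(tiny_pair(), mv, mask3d(array(1, c(16, 16, 16)),
                                                c(8, 8, 8)), model)
  expect_true(all(out$field == 0))
  expect_identical(unclass(out$pred_vol), unclass(mv))
})

test_that("outputs stay finite for degenerate inputs", {
  model <- regnet_init(small_cfg())
  mv <- volume3d(array(0, c(16, 16, 16)), c(8, 8, 8))
  p <- tiny_pair()
  p$drr_0[] <- 0; p$drr_90[] <- 0
  out <- regnet_forward(p, mv, mask3d(array(0, c(16, 16, 16)), c(8, 8, 8)),
                        model)
  expect_true(all(is.finite(out$field)))
  expect_true(all(is.finite(out$pred_vol)))
})

test_that("identical seeds give identical initialisation; configs validate", {
  m1 <- regnet_init(small_cfg(seed = 9))
  m2 <- regnet_init(small_cfg(seed = 9))
  expect_identical(orthoreg:::param_leaves(m1$params),
                   orthoreg:::param_leaves(m2$params))
  expect_error(net_config(proj_size = c(18, 18)), "divisible by 4")
  expect_error(net_config(vol_size = c(20, 20, 20), unet_levels = 4),
               "divisible")
  expect_error(net_config(res_stage_channels = c(128, 64)), "non-decreasing")
})

test_that("checkpoints round-trip through disk", {
  model <- regnet_init(small_cfg())
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(orthoreg:::param_leaves(back$params),
                   orthoreg:::param_leaves(model$params))
  expect_equal(back$cfg$vol_size, model$cfg$vol_size)
  unlink(path)
})
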