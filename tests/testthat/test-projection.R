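# DRR generation: closed-form and axis-summation oracles, the Beer-Lambert
# conversion, and the orthogonal-pair conventions.

test_that("line integrals match closed forms and axis-summation oracles", {
  # all-zero volume projects to zero
  z <- volume3d(array(0, c(16, 16, 16)), c(2, 2, 2))
  geom <- projection_geometry(detector_shape = c(16, 16),
                              detector_spacing = c(2, 2), step_mm = 1)
  expect_true(all(line_integral_image(z, geom, 0) == 0))

  # homogeneous cube, mu = 0.02 / mm, axis-aligned path 100 mm -> 2.0
  cube <- array(0, c(60, 60, 60))
  cube[6:55, 6:55, 6:55] <- 0.02
  cv <- volume3d(cube, c(2, 2, 2))
  gcube <- projection_geometry(detector_shape = c(30, 30),
                               detector_spacing = c(2, 2), step_mm = 1)
  li <- line_integral_image(cv, gcube, 0)
  expect_lt(abs(li[15, 15] - 2) / 2, 0.01)

  # parallel beam at 0: per-column sum along y times spacing
  v <- desk_ref()$volume
  g <- projection_geometry(detector_shape = c(32, 32),
                           detector_spacing = c(4, 4), step_mm = 2)
  or0 <- apply(unclass(v), c(1, 3), sum) * 4
  expect_lt(max(abs(line_integral_image(v, g, 0) - or0)) / max(or0), 0.01)
  # at 90 degrees the detector u-axis runs along -y
  or90 <- (apply(unclass(v), c(2, 3), sum) * 4)[32:1, ]
  expect_lt(max(abs(line_integral_image(v, g, 90) - or90)) / max(or90), 0.01)
})

test_that("to_intensity applies the Beer-Lambert law", {
  expect_equal(to_intensity(matrix(0, 2, 2), I0 = 3)[1], 3)
  expect_equal(to_intensity(matrix(2, 1, 1), I0 = 1)[1], exp(-2),
               tolerance = 1e-12)
  li <- matrix(seq(0, 3, length.out = 7), 1)
  expect_true(all(diff(as.vector(to_intensity(li))) < 0))
  expect_error(to_intensity(li, I0 = 0), "positive")
})

test_that("orthogonal pair: normalization, symmetry, ray-axis invariance", {
  geom <- projection_geometry(detector_shape = c(32, 32),
                              detector_spacing = c(2, 2), step_mm = 1)
  v <- blob_volume()
  pair <- orthogonal_pair(v, geom)
  expect_equal(range(pair$drr_0), c(0, 1))
  expect_equal(range(pair$drr_90), c(0, 1))
  # centred sphere: the two views coincide up to discretization
  expect_lt(max(abs(pair$drr_0 - pair$drr_90)), 1e-6)
  # translating along the 0-degree ray axis (y) leaves drr_0 unchanged
  v2 <- blob_volume(centre_mm = c(31, 31 + 6, 31))
  pair2 <- orthogonal_pair(v2, geom)
  expect_lt(max(abs(pair2$drr_0 - pair$drr_0)), 1e-6)
  expect_error(orthogonal_pair(v, projection_geometry(angles_deg = c(0, 45))),
               "90")
})

test_that("line integral is linear in the volume and converges in step size", {
  geom <- projection_geometry(detector_shape = c(16, 16),
                              detector_spacing = c(4, 4), step_mm = 2)
  v1 <- blob_volume(c(16, 16, 16), c(4, 4, 4))
  set.seed(11)
  v2 <- volume3d(array(runif(16^3, 0, 0.3), c(16, 16, 16)), c(4, 4, 4))
  a <- 1.7; b <- -0.4
  comb <- volume3d(a * unclass(v1) + b * unclass(v2), c(4, 4, 4))
  lhs <- line_integral_image(comb, geom, 30)
  rhs <- a * line_integral_image(v1, geom, 30) +
    b * line_integral_image(v2, geom, 30)
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  li2 <- line_integral_image(v1, geom, 40)
  geom_half <- projection_geometry(detector_shape = c(16, 16),
                                   detector_spacing = c(4, 4), step_mm = 1)
  li1 <- line_integral_image(v1, geom_half, 40)
  expect_lt(max(abs(li2 - li1)) / max(li1), 0.005)
})

test_that("cone beam reduces to parallel beam as the source recedes", {
  v <- blob_volume()
  par <- projection_geometry(detector_shape = c(32, 32),
                             detector_spacing = c(2, 2), step_mm = 1)
  far <- projection_geometry(beam_model = "cone", source_to_axis_mm = 1e5,
                             detector_shape = c(32, 32),
                             detector_spacing = c(2, 2), step_mm = 1)
  expect_lt(max(abs(line_integral_image(v, par, 0) -
                    line_integral_image(v, far, 0))), 0.01)
})
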