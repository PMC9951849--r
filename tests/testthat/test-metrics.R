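# Evaluation metrics: Dice, 95% Hausdorff, NCC, NMI, mTRE, centre of mass.

mk <- function(a, sp = c(1, 1, 1)) mask3d(a, spacing = sp)

test_that("dice_score: closed forms and hand arithmetic", {
  a <- array(0, c(10, 10, 10)); a[1:5, , 1:4] <- 1   # 200 voxels
  b <- a
  expect_equal(dice_score(mk(a), mk(b)), 1)
  d <- array(0, c(10, 10, 10)); d[6:10, , 5:8] <- 1
  expect_equal(dice_score(mk(a), mk(d)), 0)
  # |A| = 100, |B| = 60, overlap 40 -> 2*40/160 = 0.5
  A <- array(0, c(10, 10, 10)); A[, 1:10, 1] <- 1
  B <- array(0, c(10, 10, 10)); B[, 1:4, 1] <- 1; B[, 1:2, 2] <- 1
  expect_equal(sum(A), 100); expect_equal(sum(B), 60)
  expect_equal(sum(A * B), 40)
  expect_equal(dice_score(mk(A), mk(B)), 0.5)
})

test_that("hausdorff95: closed forms and brute-force agreement", {
  a <- array(0, c(12, 12, 12)); a[4:9, 4:9, 4:9] <- 1
  expect_equal(hausdorff95(mk(a), mk(a)), 0)
  # two parallel unit-spacing planes 3 mm apart
  p1 <- array(0, c(10, 10, 10)); p1[, , 3] <- 1
  p2 <- array(0, c(10, 10, 10)); p2[, , 6] <- 1
  expect_equal(hausdorff95(mk(p1), mk(p2)), 3)
  expect_equal(hausdorff95(mk(p2), mk(p1)), 3)  # symmetric pooling
  # O(N^2) oracle on random small masks
  brute <- function(ma, mb, q = 0.95) {
    pa <- orthoreg:::boundary_voxels(ma) - 1
    pb <- orthoreg:::boundary_voxels(mb) - 1
    dists <- function(P, Q) {
      apply(P, 1, function(r) min(sqrt(colSums((t(Q) - r)^2))))
    }
    unname(quantile(c(dists(pa, pb), dists(pb, pa)), q, type = 7))
  }
  set.seed(13)
  for (i in 1:20) {
    ma <- array(0, c(9, 9, 9)); mb <- array(0, c(9, 9, 9))
    ma[sample(729, 40)] <- 1; mb[sample(729, 40)] <- 1
    expect_equal(hausdorff95(mk(ma), mk(mb)), brute(mk(ma), mk(mb)),
                 tolerance = 1e-10)
  }
})

test_that("ncc: identity, anti-correlation, noise monotonicity", {
  v <- desk_ref()$volume
  expect_equal(ncc(v, v), 1)
  neg <- volume3d(-unclass(v) + 2, attr(v, "spacing"))
  expect_equal(ncc(v, neg), -1)
  set.seed(17)
  r1 <- ncc(v, volume3d(unclass(v) + array(rnorm(length(v), 0, 0.05), dim(v)),
                        attr(v, "spacing")))
  r2 <- ncc(v, volume3d(unclass(v) + array(rnorm(length(v), 0, 0.3), dim(v)),
                        attr(v, "spacing")))
  expect_true(r2 < r1 && r1 < 1 && r2 > 0)
  expect_error(ncc(v, volume3d(array(1, dim(v)), attr(v, "spacing"))),
               "constant")
})

test_that("mi_score: NMI limits and monotone relabelling invariance", {
  v <- desk_ref()$volume
  expect_equal(mi_score(v, v)$nmi, 1)
  set.seed(19)
  x <- runif(1e5); y <- runif(1e5)
  expect_lt(mi_score(x, y)$nmi, 0.02)
  # discrete images: a strictly monotone relabelling of both leaves NMI
  a <- sample(0:9, 4000, replace = TRUE, prob = (1:10) / 55)
  b <- (a + sample(0:1, 4000, replace = TRUE)) %% 10
  relabel <- c(0, 2, 3, 7, 10, 11, 15, 21, 30, 40)
  expect_equal(mi_score(a, b, n_bins = 64)$nmi,
               mi_score(relabel[a + 1], relabel[b + 1], n_bins = 64)$nmi,
               tolerance = 1e-10)
})

test_that("mtre: identity, 3-4-5 offset, id matching", {
  p <- landmark_set(matrix(runif(30, 0, 100), 10, 3))
  expect_equal(mtre(p, p)$mean_mm, 0)
  q <- landmark_set(p$points + matrix(rep(c(3, 4, 0), each = 10), 10, 3),
                    ids = p$ids)
  r <- mtre(q, p)
  expect_equal(r$mean_mm, 5)
  expect_equal(r$sd_mm, 0)
  expect_error(mtre(q, landmark_set(p$points[1:5, ])), "size")
})

test_that("center_of_mass_error: analytic shifts and the norm inequality", {
  a <- array(0, c(20, 20, 20))
  g <- orthoreg:::grid_mm(c(20, 20, 20), c(1, 1, 1))
  a[rowSums(sweep(g, 2, c(9, 9, 9))^2) <= 16] <- 1
  b <- array(0, c(20, 20, 20))
  b[rowSums(sweep(g, 2, c(11, 9, 9))^2) <= 16] <- 1
  r <- center_of_mass_error(mk(a), mk(b))
  expect_equal(unname(r$per_axis_mm["x_lr"]), 2, tolerance = 1e-9)
  expect_lt(max(r$per_axis_mm[c("y_ap", "z_si")]), 1e-9)
  expect_gte(r$total_mm + 1e-12, max(r$per_axis_mm))
  same <- center_of_mass_error(mk(a), mk(a))
  expect_equal(unname(same$total_mm), 0)
})

test_that("metrics are invariant to a simultaneous rigid re-indexing", {
  ref <- desk_ref()
  v <- unclass(ref$volume); m <- unclass(ref$lung_mask)
  flip <- function(x) x[dim(x)[1]:1, , ]
  sp <- attr(ref$volume, "spacing")
  expect_equal(ncc(volume3d(flip(v), sp), volume3d(flip(v * 0.9 + 0.01), sp)),
               ncc(volume3d(v, sp), volume3d(v * 0.9 + 0.01, sp)))
  expect_equal(dice_score(mk(flip(m), sp), mk(flip(m), sp)),
               dice_score(mk(m, sp), mk(m, sp)))
  tm <- unclass(ref$tumor_mask)
  expect_equal(hausdorff95(mk(flip(m), sp), mk(flip(tm), sp)),
               hausdorff95(mk(m, sp), mk(tm, sp)))
})

test_that("metric_report aggregates the suite", {
  ref <- desk_ref()
  ser <- desk_series()
  ph <- ser[[5]]
  rep <- metric_report(ph$volume, ref$volume, ph$lung_mask, ref$lung_mask,
                       warped_lm = ph$landmarks, true_lm = ref$landmarks,
                       pred_tumor = ph$tumor_mask, true_tumor = ref$tumor_mask)
  expect_true(rep$dice > 0 && rep$dice < 1)
  expect_gt(rep$hausdorff95_mm, 0)
  expect_gt(rep$mtre_mean_mm, 0)
  expect_gt(rep$com_error_mm$total_mm, 0)
  expect_output(print(rep), "Dice")
})
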