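# Evaluation suite: Dice overlap, 95% Hausdorff surface distance, NCC,
# (normalized) mutual information, mean target registration error, and
# tumour centre-of-mass error.

#' Dice overlap of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b `orv_mask`s on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a > 0); nb <- sum(b > 0)
  if (na + nb == 0) {
    message("dice_score: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * sum(a > 0 & b > 0) / (na + nb)
}

# boundary voxels under 6-connectivity: mask voxels with at least one
# face-neighbour outside the mask (the grid border counts as outside)
boundary_voxels <- function(mask) {
  m <- bare(mask) > 0
  d <- dim(m)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  eroded <- core &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] & pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] & pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(m & !eroded, arr.ind = TRUE)
}

# for each row of A (mm), distance to the nearest row of B (mm), chunked
nearest_dists <- function(A, B) {
  out <- numeric(nrow(A))
  chunk <- max(1L, floor(2e7 / nrow(B)))
  b2 <- rowSums(B^2)
  for (s in seq(1, nrow(A), by = chunk)) {
    e <- min(nrow(A), s + chunk - 1)
    blk <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), b2, "+") - 2 * blk %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' 95\% Hausdorff surface distance (mm)
#'
#' Boundary voxels are extracted by 6-connectivity erosion difference; the
#' directed surface distances of both directions are pooled and the 95th
#' percentile (linear-interpolation percentile) of the pooled set returned.
#'
#' @param a,b non-empty `orv_mask`s on the same grid.
#' @param percentile percentile of the pooled symmetric distances
#'   (default 95).
#' @return Distance in mm.
#' @export
hausdorff95 <- function(a, b, percentile = 95) {
  stop_if_grid_mismatch(a, b, "masks")
  if (sum(a) == 0 || sum(b) == 0) stop("hausdorff95 requires non-empty masks")
  sp <- vox_spacing(a)
  pa <- sweep(boundary_voxels(a) - 1, 2, sp, "*")
  pb <- sweep(boundary_voxels(b) - 1, 2, sp, "*")
  pooled <- c(nearest_dists(pa, pb), nearest_dists(pb, pa))
  unname(stats::quantile(pooled, percentile / 100, type = 7))
}

#' Normalized cross-correlation of two volumes
#'
#' Global Pearson correlation of the voxel intensities.
#'
#' @param a,b `orv_volume`s of the same shape; neither may be constant.
#' @return Scalar in `[-1, 1]`.
#' @export
ncc <- function(a, b) {
  stop_if_grid_mismatch(a, b, "volumes")
  av <- as.vector(a); bv <- as.vector(b)
  if (sd(av) == 0 || sd(bv) == 0)
    stop("NCC is undefined for a constant image")
  stats::cor(av, bv)
}

#' Mutual information and normalized mutual information
#'
#' Hard-histogram estimate on `n_bins` equal-width bins spanning the joint
#' intensity range. The headline score is the normalized variant
#' `NMI = 2 I(A;B) / (H(A) + H(B))` in `[0, 1]`; plain MI (nats) and the
#' marginal entropies are also returned.
#'
#' @param a,b `orv_volume`s (or plain arrays) of the same shape.
#' @param n_bins histogram bins per axis (default 32).
#' @return List with `nmi`, `mi`, `h_a`, `h_b`.
#' @export
mi_score <- function(a, b, n_bins = 32L) {
  av <- as.vector(a); bv <- as.vector(b)
  stopifnot(length(av) == length(bv))
  ca <- sd(av) == 0; cb <- sd(bv) == 0
  if (ca || cb) {
    message("mi_score: constant image; NMI set by convention")
    nmi <- if (ca && cb && av[1] == bv[1]) 1 else 0
    return(list(nmi = nmi, mi = 0, h_a = 0, h_b = 0))
  }
  rng <- range(c(av, bv))
  ia <- pmin(pmax(findInterval(av, seq(rng[1], rng[2], length.out = n_bins + 1),
                               rightmost.closed = TRUE), 1L), n_bins)
  ib <- pmin(pmax(findInterval(bv, seq(rng[1], rng[2], length.out = n_bins + 1),
                               rightmost.closed = TRUE), 1L), n_bins)
  joint <- table(factor(ia, levels = 1:n_bins), factor(ib, levels = 1:n_bins))
  p <- joint / sum(joint)
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  h_a <- ent(pa); h_b <- ent(pb); h_ab <- ent(as.vector(p))
  mi <- h_a + h_b - h_ab
  list(nmi = 2 * mi / (h_a + h_b), mi = mi, h_a = h_a, h_b = h_b)
}

#' Mean target registration error (mm)
#'
#' Mean and standard deviation of the per-landmark Euclidean distances
#' between two matched landmark sets.
#'
#' @param warped,target `orv_landmarks` with identical ids.
#' @return List with `mean_mm`, `sd_mm`, `n` and the per-landmark `dists`.
#' @export
mtre <- function(warped, target) {
  if (nrow(warped$points) != nrow(target$points))
    stop("landmark sets differ in size")
  if (!identical(warped$ids, target$ids)) {
    m <- match(warped$ids, target$ids)
    if (any(is.na(m))) stop("landmark ids do not match")
    target <- landmark_set(target$points[m, , drop = FALSE], warped$ids)
  }
  d <- sqrt(rowSums((warped$points - target$points)^2))
  list(mean_mm = mean(d), sd_mm = if (length(d) > 1) sd(d) else 0,
       n = length(d), dists = d)
}

#' Tumour centre-of-mass error (mm)
#'
#' Unweighted mask centroids; reports per-axis absolute differences
#' (LR, AP, SI) and the Euclidean total.
#'
#' @param a,b non-empty `orv_mask`s on the same grid.
#' @return List with `per_axis_mm` (named x/y/z) and `total_mm`.
#' @export
center_of_mass_error <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  if (sum(a) == 0 || sum(b) == 0)
    stop("center_of_mass_error requires non-empty masks")
  com <- function(m) {
    idx <- which(bare(m) > 0, arr.ind = TRUE)
    colMeans(sweep(sweep(idx - 1, 2, vox_spacing(m), "*"), 2, vox_origin(m), "+"))
  }
  d <- abs(com(a) - com(b))
  names(d) <- c("x_lr", "y_ap", "z_si")
  list(per_axis_mm = d, total_mm = sqrt(sum(d^2)))
}

#' Full evaluation report for one registration result
#'
#' @param pred_vol,true_vol predicted and ground-truth volumes.
#' @param pred_seg,true_seg predicted and ground-truth masks.
#' @param warped_lm,true_lm optional matched landmark sets for mTRE.
#' @param pred_tumor,true_tumor optional tumour masks for the
#'   centre-of-mass error.
#' @param n_bins histogram bins for the MI score.
#' @return A `metric_report` list: `dice`, `hausdorff95_mm`, `ncc`, `mi`
#'   (normalized), `mi_nats`, optional `mtre_mean_mm`/`mtre_sd_mm`,
#'   optional `com_error_mm`, plus voxel/landmark `counts`.
#' @export
metric_report <- function(pred_vol, true_vol, pred_seg, true_seg,
                          warped_lm = NULL, true_lm = NULL,
                          pred_tumor = NULL, true_tumor = NULL,
                          n_bins = 32L) {
  mi <- mi_score(pred_vol, true_vol, n_bins)
  rep <- list(dice = dice_score(pred_seg, true_seg),
              hausdorff95_mm = hausdorff95(pred_seg, true_seg),
              ncc = ncc(pred_vol, true_vol),
              mi = mi$nmi, mi_nats = mi$mi,
              counts = list(pred_seg_voxels = sum(pred_seg > 0),
                            true_seg_voxels = sum(true_seg > 0)))
  if (!is.null(warped_lm) && !is.null(true_lm)) {
    tre <- mtre(warped_lm, true_lm)
    rep$mtre_mean_mm <- tre$mean_mm
    rep$mtre_sd_mm <- tre$sd_mm
    rep$counts$landmarks <- tre$n
  }
  if (!is.null(pred_tumor) && !is.null(true_tumor))
    rep$com_error_mm <- center_of_mass_error(pred_tumor, true_tumor)
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Dice %.4f | HD95 %.3f mm | NCC %.4f | MI(norm) %.4f\n",
              x$dice, x$hausdorff95_mm, x$ncc, x$mi))
  if (!is.null(x$mtre_mean_mm))
    cat(sprintf("mTRE %.4f (%.4f) mm over %d landmarks\n",
                x$mtre_mean_mm, x$mtre_sd_mm, x$counts$landmarks))
  if (!is.null(x$com_error_mm))
    cat(sprintf("tumour COM error %.4f mm\n", x$com_error_mm$total_mm))
  invisible(x)
}
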