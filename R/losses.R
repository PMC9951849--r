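# Training objective: soft Dice on the warped segmentations, differentiable
# soft-histogram mutual information on the warped intensities, and the
# diffusion smoothness regulariser on the predicted field, combined as
#   L = l1 * (1 - Dice) + l2 * (-MI) + l3 * Reg.
# The similarity terms are negated so that minimizing L maximizes
# similarity. Gradient helpers (suffix _grad) back the training loop.

#' Loss term weights
#'
#' @param lambda_dice,lambda_mi,lambda_reg non-negative weights of the Dice,
#'   mutual-information and smoothness terms (defaults 0.5, 0.5, 0.1).
#' @return An `orv_loss_weights` list.
#' @export
loss_weights <- function(lambda_dice = 0.5, lambda_mi = 0.5,
                         lambda_reg = 0.1) {
  stopifnot(lambda_dice >= 0, lambda_mi >= 0, lambda_reg >= 0)
  structure(list(lambda_dice = lambda_dice, lambda_mi = lambda_mi,
                 lambda_reg = lambda_reg), class = "orv_loss_weights")
}

as_category_list <- function(seg) {
  if (is.list(seg)) return(seg)
  d <- dim(seg)
  if (length(d) == 4L) lapply(seq_len(d[4]), function(c4) {
    s <- seg[, , , c4]; dim(s) <- d[1:3]; s
  }) else list(seg)
}

#' Soft Dice similarity over foreground categories
#'
#' For each category, `(2 sum(F * P) + eps) / (sum F + sum P + eps)` with
#' `eps = 1e-6`; the mean over categories is returned. Categories with an
#' empty ground-truth mask are skipped (with a message).
#'
#' @param pred_seg soft predicted segmentation in `[0, 1]`: a 3D array, a 4D
#'   array with categories on the 4th axis, or a list of 3D arrays.
#' @param true_seg ground-truth segmentation, same layout.
#' @return Similarity in `[0, 1]`.
#' @export
dice_term <- function(pred_seg, true_seg) {
  dice_term_grad(pred_seg, true_seg, with_grad = FALSE)$value
}

# value and d(value)/d(pred) per category
dice_term_grad <- function(pred_seg, true_seg, with_grad = TRUE) {
  eps <- 1e-6
  P <- as_category_list(pred_seg)
  F_ <- as_category_list(true_seg)
  stopifnot(length(P) == length(F_))
  vals <- c(); grads <- vector("list", length(P)); used <- logical(length(P))
  for (i in seq_along(P)) {
    f <- F_[[i]]; p <- P[[i]]
    if (sum(f) == 0) {
      message(sprintf("dice_term: category %d has an empty ground truth; skipped", i))
      next
    }
    used[i] <- TRUE
    num <- 2 * sum(f * p) + eps
    den <- sum(f) + sum(p) + eps
    vals <- c(vals, num / den)
    if (with_grad) grads[[i]] <- (2 * f * den - num) / den^2
  }
  if (!length(vals)) stop("dice_term: all ground-truth categories empty")
  n_used <- sum(used)
  if (with_grad)
    grads[used] <- lapply(grads[used], function(g) g / n_used)
  list(value = mean(vals), grads = grads, used = used)
}

#' Differentiable mutual information of two intensity volumes
#'
#' Parzen-window (Gaussian kernel) soft joint histogram with `n_bins` bins
#' per axis over `[0, 1]`; MI in nats. The kernel makes the estimate smooth
#' in the intensities so it can drive the registration network. The kernel
#' is deliberately narrow (default 0.03 bin widths): bias against a hard
#' histogram grows roughly linearly with the bandwidth (bin-edge straddling
#' splits mass across adjacent bins), and a narrow window keeps
#' `mi_term(A, A)` within about 1.5\% of the hard-histogram entropy while
#' still providing gradients for intensities near bin boundaries.
#'
#' @param pred_vol,true_vol volumes/arrays with intensities in `[0, 1]`.
#' @param n_bins bins per axis (default 32).
#' @param bandwidth_frac kernel standard deviation in units of one bin
#'   width.
#' @return MI in nats (>= 0 up to kernel bias).
#' @export
mi_term <- function(pred_vol, true_vol, n_bins = 32L, bandwidth_frac = 0.03) {
  mi_term_grad(pred_vol, true_vol, n_bins, bandwidth_frac,
               with_grad = FALSE)$value
}

# value and gradient with respect to pred_vol; the Gaussian window is
# evaluated over the bins where it has non-negligible mass and renormalized
# there (exact to machine precision), see cpp_mi_grad
mi_term_grad <- function(pred_vol, true_vol, n_bins = 32L,
                         bandwidth_frac = 0.03, with_grad = TRUE) {
  a <- as.vector(pred_vol); b <- as.vector(true_vol)
  stopifnot(length(a) == length(b))
  if (sd(pmin(pmax(a, 0), 1)) == 0 || sd(pmin(pmax(b, 0), 1)) == 0) {
    warning("mi_term: constant image has zero entropy; returning 0")
    return(list(value = 0, grad = array(0, dim(pred_vol) %||% length(a))))
  }
  r <- cpp_mi_grad(a, b, as.integer(n_bins), bandwidth_frac, with_grad)
  if (!with_grad) return(list(value = r$value))
  g <- r$grad
  g[a < 0 | a > 1] <- 0   # values clipped into [0,1] carry no gradient
  if (!is.null(dim(pred_vol))) dim(g) <- dim(pred_vol)
  list(value = r$value, grad = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combined registration training loss
#'
#' `L = l1 (1 - Dice(Fseg, Pseg)) + l2 (-MI(Fct, Pct)) + l3 Reg(phi)`.
#' Lower is better; a perfect prediction with a constant field attains
#' `-l2 * H` where `H` is the image entropy.
#'
#' @param pred_vol,true_vol warped and ground-truth intensity volumes.
#' @param pred_seg,true_seg warped (soft) and ground-truth segmentations.
#' @param field the predicted `orv_field`.
#' @param w an [loss_weights()] object.
#' @param n_bins MI histogram bins.
#' @return Scalar loss; attribute `terms` holds the three components.
#' @export
total_loss <- function(pred_vol, true_vol, pred_seg, true_seg, field,
                       w = loss_weights(), n_bins = 32L) {
  d <- if (w$lambda_dice > 0) dice_term(pred_seg, true_seg) else 1
  m <- if (w$lambda_mi > 0) mi_term(pred_vol, true_vol, n_bins) else 0
  r <- if (w$lambda_reg > 0) smoothness_penalty(field) else 0
  out <- w$lambda_dice * (1 - d) + w$lambda_mi * (-m) + w$lambda_reg * r
  attr(out, "terms") <- c(dice = d, mi = m, reg = r)
  out
}

# gradient of the smoothness penalty with respect to the mm field
smoothness_penalty_grad <- function(field) {
  cpp_smooth_penalty_grad(bare(field), vox_spacing(field), TRUE)
}
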