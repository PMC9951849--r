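# End-to-end orchestration: isotropic resampling, hybrid-augmentation
# dataset synthesis, the training loop (Adam over the combined loss with
# hand-derived backpropagation), inference, and phantom-based evaluation.

#' Resample a volume onto a new isotropic grid
#'
#' Trilinear (or nearest, for masks) resampling onto a target grid centred
#' on the input's physical centre; the canonical full-scale target is
#' 128^3 at 1 mm isotropic spacing.
#'
#' @param volume an `orv_volume` or `orv_mask`.
#' @param target_shape integer triple (default `c(128, 128, 128)`).
#' @param target_spacing mm triple (default 1 mm isotropic).
#' @param mode `"linear"` or `"nearest"` (masks default to nearest).
#' @return Resampled `orv_volume`/`orv_mask` with the new spacing.
#' @export
resample_isotropic <- function(volume, target_shape = c(128L, 128L, 128L),
                               target_spacing = c(1, 1, 1),
                               mode = if (inherits(volume, "orv_mask"))
                                 "nearest" else "linear") {
  target_shape <- as.integer(rep_len(target_shape, 3L))
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  sp <- vox_spacing(volume); gs <- grid_dim(volume)
  if (all(target_shape == gs) && isTRUE(all.equal(target_spacing, sp)))
    return(volume)
  in_center <- (gs - 1) / 2 * sp
  out_center <- (target_shape - 1) / 2 * target_spacing
  g <- grid_mm(target_shape, target_spacing)       # out-grid mm, origin 0
  pts_vox <- sweep(sweep(g, 2, out_center - in_center, "-"), 2, sp, "/")
  if (mode == "linear") {
    vals <- cpp_sample_trilinear(bare(volume), pts_vox)
  } else {
    idx <- pmin(pmax(round(pts_vox) + 1, 1),
                matrix(gs, nrow(pts_vox), 3, byrow = TRUE))
    vals <- bare(volume)[cbind(idx[, 1], idx[, 2], idx[, 3])]
  }
  out_origin <- vox_origin(volume) + in_center - out_center
  if (inherits(volume, "orv_mask"))
    mask3d(array(vals, target_shape), target_spacing, out_origin)
  else
    volume3d(array(vals, target_shape), target_spacing, out_origin)
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe: Adam, learning rate 1e-4, batch
#' size 8, 6000 hybrid samples split 5400/300/300, loss weights
#' (0.5, 0.5, 0.1).
#'
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param optimizer only `"adam"` is available.
#' @param n_samples dataset size.
#' @param split train/validation/test sizes (must sum to `n_samples`).
#' @param epochs training epochs.
#' @param loss_weights an [loss_weights()].
#' @param net an [net_config()].
#' @param n_bins MI histogram bins.
#' @param patience early-stopping patience on the validation loss.
#' @param seed master seed for shuffling and initialisation fallback.
#' @param device informational hint; computation is CPU-only.
#' @return An `orv_train_config`.
#' @export
train_config <- function(lr = 1e-4, batch_size = 8L, optimizer = "adam",
                         n_samples = 6000L, split = c(5400L, 300L, 300L),
                         epochs = 50L, loss_weights = orthoreg::loss_weights(),
                         net = net_config(), n_bins = 32L, patience = 10L,
                         seed = 1L, device = "cpu") {
  optimizer <- match.arg(optimizer, "adam")
  if (sum(split) != n_samples)
    stop("split must sum to n_samples")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 optimizer = optimizer, n_samples = as.integer(n_samples),
                 split = as.integer(split), epochs = as.integer(epochs),
                 loss_weights = loss_weights, net = net,
                 n_bins = as.integer(n_bins), patience = as.integer(patience),
                 seed = as.integer(seed), device = device),
            class = "orv_train_config")
}

#' Synthesize a hybrid-augmentation training dataset
#'
#' For each sample a hybrid deformation (random convex pair of inter-phase
#' fields plus a weighted random TPS intra-phase field) warps the moving
#' image and segmentations into a synthetic fixed anatomy, from which an
#' orthogonal DRR pair is rendered. Fully deterministic given `seed`.
#'
#' @param series phase series from [make_phase_series()]; phase 0 is the
#'   moving image.
#' @param inter_fields inter-phase fields from [make_interphase_fields()].
#' @param geometry an [projection_geometry()].
#' @param n_samples number of samples.
#' @param seed master seed.
#' @param split train/val/test fractions (default `c(0.9, 0.05, 0.05)`; a
#'   6000-sample run yields 5400/300/300).
#' @param store_fields keep each hybrid field in the sample (provenance;
#'   disable to halve memory).
#' @return An `orv_dataset`: `moving`, `moving_seg` (lung + tumour),
#'   `samples` (each with `drr_pair`, `fixed`, `fixed_seg`,
#'   `hybrid_field_used`, `sample_id`, `seeds`), `split` index lists,
#'   `geometry` and `seed`.
#' @export
build_dataset <- function(series, inter_fields, geometry, n_samples,
                          seed = 1L, split = c(0.9, 0.05, 0.05),
                          store_fields = TRUE) {
  moving <- series[[1]]
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_samples),
                  ncol = 2L)
  gs <- grid_dim(moving$volume); sp <- vox_spacing(moving$volume)
  samples <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    intra <- sample_intra_field(gs, sp, seed = seeds[i, 1])
    attr(intra, "controls") <- NULL
    hyb <- hybrid_field(inter_fields, intra, seed = seeds[i, 2])
    f_ct <- warp_volume(moving$volume, hyb, "linear")
    f_lung <- warp_volume(moving$lung_mask, hyb, "nearest")
    f_tumor <- warp_volume(moving$tumor_mask, hyb, "nearest")
    samples[[i]] <- list(
      drr_pair = orthogonal_pair(f_ct, geometry),
      fixed = f_ct, fixed_seg = list(lung = f_lung, tumor = f_tumor),
      hybrid_field_used = if (store_fields) hyb else NULL,
      sample_id = i, seeds = seeds[i, ])
  }
  if (abs(sum(split) - 1) < 1e-9) split <- round(split * n_samples)
  split <- as.integer(split)
  split[1] <- n_samples - sum(split[-1])   # absorb rounding
  perm <- sample.int(n_samples)
  idx <- list(train = perm[seq_len(split[1])],
              val = perm[split[1] + seq_len(split[2])],
              test = perm[split[1] + split[2] + seq_len(split[3])])
  structure(list(moving = moving$volume,
                 moving_seg = list(lung = moving$lung_mask,
                                   tumor = moving$tumor_mask),
                 samples = samples, split = idx, geometry = geometry,
                 seed = seed),
            class = "orv_dataset")
}

# full forward pass keeping every cache (training internal)
regnet_fw_full <- function(model, sample, moving) {
  ec <- encoder_fw(model, sample$drr_pair$drr_0, sample$drr_pair$drr_90)
  x <- concat_ch(ec$y, bare(moving))
  uc <- unet_fw(model, x)
  list(enc = ec, unet = uc, phi_vox = uc$y)
}

# loss + gradient of one sample with respect to all parameters
train_step_grad <- function(model, sample, moving, moving_segs, w, n_bins) {
  fw <- regnet_fw_full(model, sample, moving)
  phi <- fw$phi_vox
  sp <- vox_spacing(moving)
  m_bare <- bare(moving)
  p_ct <- cpp_warp(m_bare, phi, 0L)
  cats <- names(moving_segs)
  p_seg <- lapply(moving_segs, function(s) cpp_warp(bare(s), phi, 0L))
  f_seg <- lapply(sample$fixed_seg, bare)
  dg <- dice_term_grad(p_seg, f_seg)
  mg <- mi_term_grad(p_ct, bare(sample$fixed), n_bins)
  field_mm <- phi
  for (c3 in 1:3) field_mm[, , , c3] <- field_mm[, , , c3] * sp[c3]
  fld <- deformation_field(field_mm, sp, convention = "backward")
  rg <- smoothness_penalty_grad(fld)
  loss <- w$lambda_dice * (1 - dg$value) + w$lambda_mi * (-mg$value) +
    w$lambda_reg * rg$value
  # gradient w.r.t. the voxel-unit field
  gphi <- cpp_warp_field_grad(m_bare, phi, -w$lambda_mi * mg$grad)
  for (i in seq_along(p_seg)) {
    if (!dg$used[i]) next
    gphi <- gphi + cpp_warp_field_grad(bare(moving_segs[[i]]), phi,
                                       -w$lambda_dice * dg$grads[[i]])
  }
  greg <- w$lambda_reg * rg$grad
  for (c3 in 1:3) greg[, , , c3] <- greg[, , , c3] * sp[c3]
  gphi <- gphi + greg
  dim(gphi) <- dim(phi)
  ub <- unet_bw(model, fw$unet, gphi)
  gin <- split_ch(ub$gx, 1L)
  eb <- encoder_bw(model, fw$enc, gin[[1]])
  list(loss = loss,
       terms = c(dice = dg$value, mi = mg$value, reg = rg$value),
       grads = list(enc = eb$grads, unet = ub$grads))
}

# forward-only loss (validation)
eval_loss <- function(model, sample, moving, moving_segs, w, n_bins) {
  fw <- regnet_fw_full(model, sample, moving)
  phi <- fw$phi_vox
  sp <- vox_spacing(moving)
  p_ct <- cpp_warp(bare(moving), phi, 0L)
  p_seg <- lapply(moving_segs, function(s) cpp_warp(bare(s), phi, 0L))
  d <- dice_term(p_seg, lapply(sample$fixed_seg, bare))
  m <- mi_term(p_ct, bare(sample$fixed), n_bins)
  field_mm <- phi
  for (c3 in 1:3) field_mm[, , , c3] <- field_mm[, , , c3] * sp[c3]
  r <- smoothness_penalty(deformation_field(field_mm, sp,
                                            convention = "backward"))
  w$lambda_dice * (1 - d) + w$lambda_mi * (-m) + w$lambda_reg * r
}

#' Train the registration network
#'
#' Adam optimisation of the combined Dice / mutual-information / smoothness
#' loss over minibatches of hybrid-augmentation samples; logs per-epoch
#' training and validation losses, keeps the best-validation parameters and
#' stops early when validation stops improving.
#'
#' @param dataset an `orv_dataset` from [build_dataset()].
#' @param cfg an [train_config()]; `cfg$net` must match the dataset shapes.
#' @param model optional warm-start `orv_regnet` (default: fresh
#'   [regnet_init()]).
#' @param opt_state optimiser state from a previous run (exact resume).
#' @param start_epoch first epoch number (continue a run from
#'   `best_epoch + 1` with the returned `opt_state` to resume exactly).
#' @param verbose print a line per epoch.
#' @return List with `model` (best-validation weights), `last_model`,
#'   `history` (data frame: epoch, train_loss, val_loss), `best_epoch` and
#'   `opt_state`.
#' @export
train_regnet <- function(dataset, cfg, model = NULL, opt_state = NULL,
                         start_epoch = 1L, verbose = FALSE) {
  if (is.null(model)) model <- regnet_init(cfg$net)
  w <- cfg$loss_weights
  moving <- dataset$moving
  segs <- dataset$moving_seg
  tr_idx <- dataset$split$train
  va_idx <- dataset$split$val
  state <- if (is.null(opt_state)) adam_init(model$params) else opt_state
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(val = Inf, params = model$params, epoch = 0L)
  bad_epochs <- 0L
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  for (ep in seq_len(cfg$epochs)[seq_len(cfg$epochs) >= start_epoch]) {
    set.seed(cfg$seed + ep)
    order_idx <- sample(tr_idx)
    batch_starts <- seq(1, length(order_idx), by = cfg$batch_size)
    ep_loss <- 0; n_seen <- 0
    for (bs in batch_starts) {
      ids <- order_idx[bs:min(bs + cfg$batch_size - 1, length(order_idx))]
      acc <- NULL; bloss <- 0
      for (id in ids) {
        st <- train_step_grad(model, dataset$samples[[id]], moving, segs,
                              w, cfg$n_bins)
        if (!is.finite(st$loss))
          stop(sprintf("training diverged (non-finite loss at sample %d)", id))
        acc <- tree_add(acc, st$grads)
        bloss <- bloss + st$loss
      }
      acc <- tree_scale(acc, 1 / length(ids))
      upd <- adam_step(model$params, acc, state, lr = cfg$lr)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bloss
      n_seen <- n_seen + length(ids)
    }
    train_loss <- ep_loss / n_seen
    val_loss <- if (length(va_idx))
      mean(vapply(va_idx, function(id)
        eval_loss(model, dataset$samples[[id]], moving, segs, w, cfg$n_bins),
        numeric(1)))
    else train_loss
    history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, train_loss,
                      val_loss))
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = model$params, epoch = ep)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= cfg$patience) break
    }
  }
  best_model <- model
  best_model$params <- best$params
  list(model = best_model, last_model = model, history = history,
       best_epoch = best$epoch, opt_state = state)
}

#' Run inference with a trained model
#'
#' A single forward pass (no optimisation): predicts the field and warps
#' the moving volume and segmentation.
#'
#' @param model an `orv_regnet` (or a checkpoint path).
#' @param drr_pair an `orv_projection_pair`.
#' @param moving moving `orv_volume`.
#' @param moving_seg `orv_mask` or list of masks.
#' @return See [regnet_forward()].
#' @export
infer <- function(model, drr_pair, moving, moving_seg) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (!all(grid_dim(moving) == model$cfg$vol_size))
    stop(sprintf("moving volume %s does not match the checkpoint vol_size %s",
                 paste(grid_dim(moving), collapse = "x"),
                 paste(model$cfg$vol_size, collapse = "x")))
  regnet_forward(drr_pair, moving, moving_seg, model)
}

#' Evaluate a model against analytic phantom phases
#'
#' For each phase fraction the ground-truth anatomy, masks and landmarks
#' are generated analytically from the phantom; the model sees only the DRR
#' pair and the moving (reference) image. Reports Dice, tumour
#' centre-of-mass error and landmark mTRE before (unregistered) and after
#' registration.
#'
#' @param model a trained `orv_regnet`.
#' @param spec the `orv_phantom_spec` the model was trained for.
#' @param ref reference scene from [make_reference()].
#' @param fractions phase fractions to evaluate.
#' @param geometry the DRR [projection_geometry()] used in training.
#' @return Data frame with one row per phase: dice_before/after,
#'   com_before/after_mm, mtre_before/after_mm.
#' @export
evaluate_phases <- function(model, spec, ref, fractions, geometry) {
  moving_lung <- ref$lung_mask; moving_tumor <- ref$tumor_mask
  rows <- lapply(fractions, function(f) {
    ph <- phantom_phase(spec, ref, f)
    pair <- orthogonal_pair(ph$volume, geometry)
    out <- regnet_forward(pair, ref$volume,
                          list(lung = moving_lung, tumor = moving_tumor),
                          model)
    seg_after <- out$pred_seg_nearest
    # union lung+tumour for the whole-lung Dice, as segmented organs
    dice_before <- dice_score(moving_lung, ph$lung_mask)
    dice_after <- dice_score(seg_after$lung, ph$lung_mask)
    com_before <- center_of_mass_error(moving_tumor, ph$tumor_mask)$total_mm
    com_after <- center_of_mass_error(seg_after$tumor, ph$tumor_mask)$total_mm
    # mTRE: the predicted backward field maps fixed-space landmarks to the
    # moving frame; perfect registration lands them on the reference points
    q <- ph$landmarks$points
    fvox <- field_to_vox(out$field)
    gs <- grid_dim(out$field)
    qvox <- mm_to_vox0(out$field, q)
    u <- vapply(1:3, function(c3) {
      f3 <- fvox[, , , c3]; dim(f3) <- gs
      cpp_sample_trilinear(f3, qvox) * vox_spacing(out$field)[c3]
    }, numeric(nrow(q)))
    dim(u) <- c(nrow(q), 3L)
    p_ref <- ref$landmarks$points
    mtre_before <- mean(sqrt(rowSums((q - p_ref)^2)))
    mtre_after <- mean(sqrt(rowSums((q + u - p_ref)^2)))
    data.frame(phase_fraction = f, dice_before = dice_before,
               dice_after = dice_after, com_before_mm = com_before,
               com_after_mm = com_after, mtre_before_mm = mtre_before,
               mtre_after_mm = mtre_after)
  })
  do.call(rbind, rows)
}
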