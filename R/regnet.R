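# The 2D/3D registration network: a residual 2D encoder over the two
# stacked orthogonal projections, channel-to-depth lifting into a 3D
# feature map aligned with the moving volume, and a 3D attention U-Net
# that regresses the dense deformation field. Forward and backward passes
# are written out explicitly; see nn.R for the layer primitives.

#' Registration network configuration
#'
#' Channel widths follow the full-scale design (stem 32; residual stages
#' 64 and 128; U-Net base 16) multiplied by `scale_factor`, which shrinks
#' the network uniformly for desk-scale experiments.
#'
#' @param proj_size projection image size (square side or pair); must be a
#'   multiple of 4 (stem pooling + strided stage).
#' @param vol_size moving-volume grid (triple or scalar); each side must be
#'   divisible by `2^(unet_levels - 1)`.
#' @param stem_channels stem convolution width at full scale.
#' @param res_stage_channels widths of the two residual stages at full
#'   scale (non-decreasing).
#' @param unet_levels U-Net depth (>= 2).
#' @param unet_base_channels first-level U-Net width at full scale.
#' @param use_attention_gates gate the skip connections (default `TRUE`).
#' @param scale_factor uniform channel shrink factor in `(0, 1]`.
#' @param seed initialisation seed.
#' @return An `orv_net_config`.
#' @export
net_config <- function(proj_size = c(128L, 128L), vol_size = c(128L, 128L, 128L),
                       stem_channels = 32L, res_stage_channels = c(64L, 128L),
                       unet_levels = 3L, unet_base_channels = 16L,
                       use_attention_gates = TRUE, scale_factor = 1,
                       seed = 1L) {
  proj_size <- as.integer(rep_len(proj_size, 2L))
  vol_size <- as.integer(rep_len(vol_size, 3L))
  if (diff(res_stage_channels) < 0)
    stop("res_stage_channels must be non-decreasing")
  if (any(proj_size %% 4L != 0L))
    stop("proj_size must be divisible by 4 (pool + strided stage)")
  if (unet_levels < 2) stop("unet_levels must be >= 2")
  if (any(vol_size %% 2L^(unet_levels - 1L) != 0L))
    stop("vol_size must be divisible by 2^(unet_levels - 1)")
  ch <- function(x) max(2L, as.integer(round(x * scale_factor)))
  structure(list(proj_size = proj_size, vol_size = vol_size,
                 stem_channels = ch(stem_channels),
                 res_stage_channels = vapply(res_stage_channels, ch, 1L),
                 unet_levels = as.integer(unet_levels),
                 unet_base_channels = ch(unet_base_channels),
                 use_attention_gates = isTRUE(use_attention_gates),
                 scale_factor = scale_factor, seed = as.integer(seed)),
            class = "orv_net_config")
}

unet_widths <- function(cfg) cfg$unet_base_channels * 2L^(seq_len(cfg$unet_levels) - 1L)

#' Initialise the registration network
#'
#' He-initialised weights throughout, except the final field head which is
#' initialised near zero so the untrained network emits an (almost exactly)
#' identity transform.
#'
#' @param cfg an [net_config()].
#' @return An `orv_regnet` model: `list(cfg, params)`.
#' @export
regnet_init <- function(cfg) {
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(cfg$seed)
  rng <- function(n) rnorm(n)
  S <- cfg$stem_channels
  C1 <- cfg$res_stage_channels[1]; C2 <- cfg$res_stage_channels[2]
  enc <- list(
    stem = conv2d_init(2L, S, 3L, 1, rng),
    s1b1 = res_block_init2d(S, C1, project = TRUE, rng),
    s1b2 = res_block_init2d(C1, C1, project = FALSE, rng),
    s2b1 = res_block_init2d(C1, C2, project = TRUE, rng),
    s2b2 = res_block_init2d(C2, C2, project = FALSE, rng))
  W <- unet_widths(cfg)
  L <- cfg$unet_levels
  unet <- list()
  cin <- 2L
  for (l in seq_len(L)) {
    unet[[paste0("enc", l)]] <- conv_block_init3d(cin, W[l], rng)
    cin <- W[l]
  }
  for (l in seq(L - 1, 1)) {
    if (cfg$use_attention_gates)
      unet[[paste0("att", l)]] <- attgate_init(W[l], W[l + 1], rng)
    unet[[paste0("dec", l)]] <- conv_block_init3d(W[l] + W[l + 1], W[l], rng)
  }
  unet$head <- conv3d_init(W[1], 3L, 1L, sd_scale = 1e-3, rng = rng)
  structure(list(cfg = cfg, params = list(enc = enc, unet = unet)),
            class = "orv_regnet")
}

res_block_init2d <- function(cin, cout, project, rng) {
  b <- list(c1 = conv2d_init(cin, cout, 3L, 1, rng),
            c2 = conv2d_init(cout, cout, 3L, 1, rng))
  if (project) b$sc <- conv2d_init(cin, cout, 1L, 1, rng)
  b
}

conv_block_init3d <- function(cin, cout, rng) {
  list(c1 = conv3d_init(cin, cout, 3L, 1, rng),
       c2 = conv3d_init(cout, cout, 3L, 1, rng))
}

res_block_fw2d <- function(x, p, stride = 1L) {
  c1 <- conv2d_fw(x, p$c1, stride)
  a1 <- lrelu_fw(c1$y)
  c2 <- conv2d_fw(a1$y, p$c2, 1L)
  if (!is.null(p$sc)) {
    sc <- conv2d_fw(x, p$sc, stride)
    s <- sc$y
  } else {
    sc <- NULL
    s <- ensure3d_img(x)
  }
  a2 <- lrelu_fw(c2$y + s)
  list(y = a2$y, c1 = c1, a1 = a1, c2 = c2, sc = sc, a2 = a2)
}
res_block_bw2d <- function(p, cache, gy) {
  g <- lrelu_bw(cache$a2, gy)
  bw2 <- conv2d_bw(p$c2, cache$c2, g)
  ga1 <- lrelu_bw(cache$a1, bw2$gx)
  bw1 <- conv2d_bw(p$c1, cache$c1, ga1)
  grads <- list(c1 = list(W = bw1$gW, b = bw1$gb),
                c2 = list(W = bw2$gW, b = bw2$gb))
  gx <- bw1$gx
  if (!is.null(p$sc)) {
    bws <- conv2d_bw(p$sc, cache$sc, g)
    grads$sc <- list(W = bws$gW, b = bws$gb)
    gx <- gx + bws$gx
  } else {
    gx <- gx + g
  }
  list(gx = gx, grads = grads)
}

conv_block_fw3d <- function(x, p) {
  c1 <- conv3d_fw(x, p$c1)
  a1 <- lrelu_fw(c1$y)
  c2 <- conv3d_fw(a1$y, p$c2)
  a2 <- lrelu_fw(c2$y)
  list(y = a2$y, c1 = c1, a1 = a1, c2 = c2, a2 = a2)
}
conv_block_bw3d <- function(p, cache, gy) {
  g <- lrelu_bw(cache$a2, gy)
  bw2 <- conv3d_bw(p$c2, cache$c2, g)
  ga1 <- lrelu_bw(cache$a1, bw2$gx)
  bw1 <- conv3d_bw(p$c1, cache$c1, ga1)
  list(gx = bw1$gx,
       grads = list(c1 = list(W = bw1$gW, b = bw1$gb),
                    c2 = list(W = bw2$gW, b = bw2$gb)))
}

# --- 2D encoder + channel-to-depth lifting ---------------------------------

encoder_fw <- function(model, drr0, drr90) {
  p <- model$params$enc
  cfg <- model$cfg
  x <- array(c(drr0, drr90), c(dim(drr0), 2L))  # channel-stacked projections
  stem <- conv2d_fw(x, p$stem)
  a0 <- lrelu_fw(stem$y)
  pool <- maxpool2d_fw(a0$y)
  b1 <- res_block_fw2d(pool$y, p$s1b1)
  b2 <- res_block_fw2d(b1$y, p$s1b2)
  b3 <- res_block_fw2d(b2$y, p$s2b1, stride = 2L)
  b4 <- res_block_fw2d(b3$y, p$s2b2)
  # channels become the third spatial dimension, then trilinear resample
  lift_in <- b4$y                      # [u, v, C2] read as a 3D block
  rs <- resize3d_fw(lift_in, cfg$vol_size)
  fm <- rs$y
  dim(fm) <- cfg$vol_size
  list(y = fm, stem = stem, a0 = a0, pool = pool, b1 = b1, b2 = b2,
       b3 = b3, b4 = b4, rs = rs)
}

encoder_bw <- function(model, cache, g_fm) {
  p <- model$params$enc
  dim(g_fm) <- c(model$cfg$vol_size, 1L)
  g_lift <- resize3d_bw(cache$rs, g_fm)
  dim(g_lift) <- dim(cache$b4$y)
  r4 <- res_block_bw2d(p$s2b2, cache$b4, g_lift)
  r3 <- res_block_bw2d(p$s2b1, cache$b3, r4$gx)
  r2 <- res_block_bw2d(p$s1b2, cache$b2, r3$gx)
  r1 <- res_block_bw2d(p$s1b1, cache$b1, r2$gx)
  gp <- maxpool2d_bw(cache$pool, r1$gx)
  ga <- lrelu_bw(cache$a0, gp)
  bs <- conv2d_bw(p$stem, cache$stem, ga)
  list(grads = list(stem = list(W = bs$gW, b = bs$gb),
                    s1b1 = r1$grads, s1b2 = r2$grads,
                    s2b1 = r3$grads, s2b2 = r4$grads))
}

# --- 3D attention U-Net ----------------------------------------------------

unet_fw <- function(model, x) {
  p <- model$params$unet
  L <- model$cfg$unet_levels
  enc <- vector("list", L); pools <- vector("list", L - 1)
  h <- x
  for (l in seq_len(L)) {
    enc[[l]] <- conv_block_fw3d(h, p[[paste0("enc", l)]])
    if (l < L) {
      pools[[l]] <- maxpool3d_fw(enc[[l]]$y)
      h <- pools[[l]]$y
    }
  }
  dec <- list(); ups <- list(); atts <- list()
  h <- enc[[L]]$y
  for (l in seq(L - 1, 1)) {
    target <- dim(enc[[l]]$y)[1:3]
    ups[[l]] <- resize3d_fw(h, target)
    skip <- enc[[l]]$y
    if (model$cfg$use_attention_gates) {
      atts[[l]] <- attgate_fw(skip, ups[[l]]$y, p[[paste0("att", l)]])
      skip <- atts[[l]]$y
    }
    dec[[l]] <- conv_block_fw3d(concat_ch(skip, ups[[l]]$y),
                                p[[paste0("dec", l)]])
    h <- dec[[l]]$y
  }
  head <- conv3d_fw(h, p$head)
  list(y = head$y, enc = enc, pools = pools, ups = ups, atts = atts,
       dec = dec, head = head)
}

unet_bw <- function(model, cache, gy) {
  p <- model$params$unet
  L <- model$cfg$unet_levels
  grads <- list()
  bh <- conv3d_bw(p$head, cache$head, gy)
  grads$head <- list(W = bh$gW, b = bh$gb)
  g <- bh$gx
  genc <- vector("list", L)   # gradients flowing into each encoder output
  for (l in seq(1, L - 1)) {
    bd <- conv_block_bw3d(p[[paste0("dec", l)]], cache$dec[[l]], g)
    grads[[paste0("dec", l)]] <- bd$grads
    nskip <- dim(cache$enc[[l]]$y)[4]
    sp <- split_ch(bd$gx, nskip)
    gskip <- sp[[1]]; gup <- sp[[2]]
    if (model$cfg$use_attention_gates) {
      ba <- attgate_bw(p[[paste0("att", l)]], cache$atts[[l]], gskip)
      grads[[paste0("att", l)]] <- ba$grads
      gskip <- ba$gx
      gup <- gup + ba$gg
    }
    genc[[l]] <- tree_add(genc[[l]], gskip)
    g <- resize3d_bw(cache$ups[[l]], gup)   # flows to the deeper level
  }
  # g now targets enc[[L]]$y; walk the encoder back down
  for (l in seq(L, 1)) {
    be <- conv_block_bw3d(p[[paste0("enc", l)]], cache$enc[[l]],
                          if (l == L) g else genc[[l]])
    grads[[paste0("enc", l)]] <- be$grads
    if (l > 1) {
      gpool <- maxpool3d_bw(cache$pools[[l - 1]], be$gx)
      genc[[l - 1]] <- tree_add(genc[[l - 1]], gpool)
    } else {
      gin <- be$gx
    }
  }
  list(gx = gin, grads = grads)
}

# --- public operations -----------------------------------------------------

#' Lift an orthogonal projection pair into a 3D feature map
#'
#' The two projections are stacked on the channel axis, passed through the
#' residual 2D encoder (stem convolution, max pooling, two residual stages),
#' the final activation's channel axis is reinterpreted as a third spatial
#' dimension, and the block is trilinearly resampled onto the moving
#' volume's grid.
#'
#' @param pair an `orv_projection_pair` (line-integral domain, normalized).
#' @param model an `orv_regnet` from [regnet_init()].
#' @return A 3D array of shape `cfg$vol_size`.
#' @export
encode_projections <- function(pair, model) {
  if (!all(dim(pair$drr_0) == dim(pair$drr_90)))
    stop("projections must share detector shape")
  if (!all(dim(pair$drr_0) == model$cfg$proj_size))
    stop("projection size does not match the network configuration")
  encoder_fw(model, pair$drr_0, pair$drr_90)$y
}

#' Predict a deformation field from a feature map and the moving volume
#'
#' Concatenates the feature map and the moving volume on the channel axis
#' and runs the 3D attention U-Net; the 3-channel output is the field in
#' voxel units, converted to mm via the moving volume's spacing.
#'
#' @param feature_map 3D array from [encode_projections()].
#' @param moving the moving `orv_volume`.
#' @param model an `orv_regnet`.
#' @return A backward `orv_field`.
#' @export
predict_field <- function(feature_map, moving, model) {
  if (!all(dim(feature_map)[1:3] == grid_dim(moving)))
    stop("feature map and moving volume shapes differ")
  x <- concat_ch(feature_map, bare(moving))
  out <- unet_fw(model, x)$y
  sp <- vox_spacing(moving)
  for (c3 in 1:3) out[, , , c3] <- out[, , , c3] * sp[c3]
  deformation_field(out, sp, vox_origin(moving), "backward")
}

#' Full forward pass of the registration model
#'
#' @param pair an `orv_projection_pair` rendered from the (unknown) fixed
#'   anatomy.
#' @param moving moving `orv_volume` (`M_CT`).
#' @param moving_seg moving segmentation: an `orv_mask` or a named list of
#'   masks (categories).
#' @param model an `orv_regnet`.
#' @return List with `field` (backward `orv_field`), `pred_vol` (warped
#'   moving volume), `pred_seg` (masks warped with linear interpolation,
#'   the differentiable convention) and `pred_seg_nearest` (label-preserving
#'   warp for reporting).
#' @export
regnet_forward <- function(pair, moving, moving_seg, model) {
  fm <- encode_projections(pair, model)
  field <- predict_field(fm, moving, model)
  segs <- if (inherits(moving_seg, "orv_mask")) list(seg = moving_seg)
          else moving_seg
  fvox <- field_to_vox(field)
  pred_vol <- volume3d(cpp_warp(bare(moving), fvox, 0L),
                       vox_spacing(moving), vox_origin(moving))
  pred_seg <- lapply(segs, function(s)
    volume3d(cpp_warp(bare(s), fvox, 0L), vox_spacing(s), vox_origin(s)))
  pred_seg_nn <- lapply(segs, function(s)
    mask3d(cpp_warp(bare(s), fvox, 1L), vox_spacing(s), vox_origin(s)))
  list(field = field, pred_vol = pred_vol, pred_seg = pred_seg,
       pred_seg_nearest = pred_seg_nn)
}

#' Number of trainable parameters of a model
#' @param model an `orv_regnet`.
#' @export
regnet_n_params <- function(model) n_parameters(model$params)

#' Save / load a model checkpoint (config embedded)
#' @param model an `orv_regnet`.
#' @param path file path (RDS).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
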