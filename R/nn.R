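# Minimal CPU neural-network toolkit backing the registration network:
# 2D/3D convolutions (im2col + BLAS in C++), leaky-ReLU, max pooling,
# trilinear resizing, additive attention gates, He initialisation and Adam.
# Every forward returns a cache; every backward consumes it and returns
# gradients for its inputs and parameters. Parameters live in a flat named
# list of arrays ("path-style" keys), gradients in a parallel list.

lrelu_fw <- function(x, slope = 0.1) {
  neg <- x < 0
  y <- x
  y[neg] <- slope * y[neg]
  dim(y) <- dim(x)
  list(y = y, neg = neg, slope = slope)
}
lrelu_bw <- function(cache, gy) {
  g <- gy
  g[cache$neg] <- cache$slope * g[cache$neg]
  dim(g) <- dim(gy)
  g
}

sigmoid <- function(x) 1 / (1 + exp(-x))

he_init <- function(cout, fan_in, sd_scale = 1, rng) {
  matrix(rng(cout * fan_in) * sqrt(2 / fan_in) * sd_scale, cout, fan_in)
}

conv3d_init <- function(cin, cout, k = 3L, sd_scale = 1, rng) {
  list(W = he_init(cout, cin * k^3, sd_scale, rng), b = numeric(cout), k = k)
}
conv2d_init <- function(cin, cout, k = 3L, sd_scale = 1, rng) {
  list(W = he_init(cout, cin * k^2, sd_scale, rng), b = numeric(cout), k = k)
}

ensure4d <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}
ensure3d_img <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

conv3d_fw <- function(x, p, stride = 1L) {
  x <- ensure4d(x)
  y <- cpp_conv3d_fw(x, p$W, p$b, p$k, as.integer(stride))
  list(y = y, x = x, stride = as.integer(stride))
}
conv3d_bw <- function(p, cache, gy) {
  cpp_conv3d_bw(cache$x, p$W, gy, p$k, cache$stride)
}

conv2d_fw <- function(x, p, stride = 1L) {
  x <- ensure3d_img(x)
  y <- cpp_conv2d_fw(x, p$W, p$b, p$k, as.integer(stride))
  list(y = y, x = x, stride = as.integer(stride))
}
conv2d_bw <- function(p, cache, gy) {
  cpp_conv2d_bw(cache$x, p$W, gy, p$k, cache$stride)
}

maxpool3d_fw <- function(x) {
  x <- ensure4d(x)
  r <- cpp_maxpool3d_fw(x)
  list(y = r$y, idx = r$idx, xdim = dim(x))
}
maxpool3d_bw <- function(cache, gy) {
  g <- numeric(prod(cache$xdim))
  # scatter-add via aggregation (argmax indices are unique per output)
  g[cache$idx] <- as.vector(gy)
  dim(g) <- cache$xdim
  g
}

maxpool2d_fw <- function(x) {
  x <- ensure3d_img(x)
  r <- cpp_maxpool2d_fw(x)
  list(y = r$y, idx = r$idx, xdim = dim(x))
}
maxpool2d_bw <- function(cache, gy) {
  g <- numeric(prod(cache$xdim))
  g[cache$idx] <- as.vector(gy)
  dim(g) <- cache$xdim
  g
}

resize3d_fw <- function(x, out_shape) {
  x <- ensure4d(x)
  list(y = cpp_resize3d(x, as.integer(out_shape)), xdim = dim(x))
}
resize3d_bw <- function(cache, gy) {
  cpp_resize3d_adj(gy, as.integer(cache$xdim[1:3]))
}

concat_ch <- function(a, b) {
  a <- ensure4d(a); b <- ensure4d(b)
  stopifnot(all(dim(a)[1:3] == dim(b)[1:3]))
  y <- array(0, c(dim(a)[1:3], dim(a)[4] + dim(b)[4]))
  y[, , , seq_len(dim(a)[4])] <- a
  y[, , , dim(a)[4] + seq_len(dim(b)[4])] <- b
  y
}
split_ch <- function(g, n_first) {
  d <- dim(g)
  ga <- g[, , , seq_len(n_first), drop = FALSE]
  gb <- g[, , , n_first + seq_len(d[4] - n_first), drop = FALSE]
  list(ga, gb)
}

# Additive attention gate on a skip connection (gating signal g from the
# decoder, skip features x): alpha = sigmoid(psi(lrelu(Wx x + Wg g))),
# out = x * alpha.
attgate_init <- function(cx, cg, rng) {
  ci <- max(1L, cx %/% 2L)
  list(wx = conv3d_init(cx, ci, 1L, 1, rng),
       wg = conv3d_init(cg, ci, 1L, 1, rng),
       psi = conv3d_init(ci, 1L, 1L, 1, rng))
}
attgate_fw <- function(x, g, p) {
  cx <- conv3d_fw(x, p$wx); cg <- conv3d_fw(g, p$wg)
  s <- cx$y + cg$y
  act <- lrelu_fw(s)
  cp <- conv3d_fw(act$y, p$psi)
  alpha <- sigmoid(cp$y)            # [*,*,*,1]
  nx <- dim(ensure4d(x))[4]
  al <- array(rep(as.vector(alpha), nx), c(dim(alpha)[1:3], nx))
  y <- ensure4d(x) * al
  list(y = y, cx = cx, cg = cg, act = act, cp = cp, alpha = alpha,
       al = al, x = ensure4d(x))
}
attgate_bw <- function(p, cache, gy) {
  gx_direct <- gy * cache$al
  galpha_full <- gy * cache$x
  galpha <- rowSums(galpha_full, dims = 3)
  dim(galpha) <- c(dim(galpha), 1L)
  gpre <- galpha * cache$alpha * (1 - cache$alpha)
  bw_psi <- conv3d_bw(p$psi, cache$cp, gpre)
  gact <- lrelu_bw(cache$act, bw_psi$gx)
  bw_x <- conv3d_bw(p$wx, cache$cx, gact)
  bw_g <- conv3d_bw(p$wg, cache$cg, gact)
  list(gx = gx_direct + bw_x$gx, gg = bw_g$gx,
       grads = list(wx = list(W = bw_x$gW, b = bw_x$gb),
                    wg = list(W = bw_g$gW, b = bw_g$gb),
                    psi = list(W = bw_psi$gW, b = bw_psi$gb)))
}

# ---------------------------------------------------------------------------
# flat parameter tree helpers: parameters are nested lists whose leaves are
# list(W = matrix, b = vector, k = int); gradients mirror the structure.

param_leaves <- function(p, path = character()) {
  if (is.list(p) && !is.null(p$W)) {
    out <- list()
    out[[paste(c(path, "W"), collapse = ".")]] <- p$W
    out[[paste(c(path, "b"), collapse = ".")]] <- p$b
    return(out)
  }
  out <- list()
  for (nm in names(p)) {
    if (nm == "k") next
    out <- c(out, param_leaves(p[[nm]], c(path, nm)))
  }
  out
}

n_parameters <- function(params) sum(vapply(param_leaves(params), length, 1L))

# elementwise tree combination (used for gradient accumulation)
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (nm in names(b)) out[[nm]] <- tree_add(a[[nm]], b[[nm]])
  out
}
tree_scale <- function(a, s) {
  if (is.numeric(a)) return(a * s)
  lapply(a, tree_scale, s = s)
}

# Adam over the flattened leaves
adam_init <- function(params) {
  leaves <- param_leaves(params)
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0), t = 0L)
}
adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  pl <- param_leaves(params)
  gl <- param_leaves(grads)
  state$t <- state$t + 1L
  for (key in names(pl)) {
    g <- gl[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    pl[[key]] <- pl[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = assign_leaves(params, pl), state = state)
}

assign_leaves <- function(p, leaves, path = character()) {
  if (is.list(p) && !is.null(p$W)) {
    p$W <- leaves[[paste(c(path, "W"), collapse = ".")]]
    p$b <- leaves[[paste(c(path, "b"), collapse = ".")]]
    return(p)
  }
  for (nm in names(p)) {
    if (nm == "k") next
    p[[nm]] <- assign_leaves(p[[nm]], leaves, c(path, nm))
  }
  p
}
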