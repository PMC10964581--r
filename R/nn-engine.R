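# Minimal deterministic CPU engine for the segmentation networks.
#
# Feature maps are channel-last arrays: (H, W, C) in 2D, (D, H, W, C) in 3D.
# Convolutions are "same"-padded stride-1, implemented as im2col + GEMM
# (compiled kernels in src/ops.cpp, BLAS for the matrix products). Backward
# passes are hand-derived per primitive; optimization is Adam. Everything is
# single-threaded and deterministic given the seed.

.ndims <- function(x) length(dim(x))
.nchan <- function(x) dim(x)[.ndims(x)]
.spatial <- function(x) dim(x)[-.ndims(x)]

chan_get <- function(x, idx) {
  if (.ndims(x) == 3) x[, , idx, drop = FALSE] else x[, , , idx, drop = FALSE]
}

chan_cat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  nd <- length(da)
  stopifnot(identical(da[-nd], db[-nd]))
  out <- array(0, c(da[-nd], da[nd] + db[nd]))
  if (nd == 3) { out[, , seq_len(da[3])] <- a; out[, , da[3] + seq_len(db[3])] <- b }
  else { out[, , , seq_len(da[4])] <- a; out[, , , da[4] + seq_len(db[4])] <- b }
  out
}

# ---- conv ------------------------------------------------------------------

nn_conv_fwd <- function(x, Wm, b, k) {
  d <- dim(x); nd <- length(d)
  n <- prod(d[-nd]); C <- d[nd]; Cout <- length(b)
  cols <- if (k == 1) matrix(x, n, C)
          else if (nd == 3) cpp_im2col2(as.vector(x), d[1], d[2], C, k)
          else cpp_im2col3(as.vector(x), d[1], d[2], d[3], C, k)
  y <- cols %*% Wm
  y <- sweep(y, 2, b, `+`)
  list(out = array(y, c(d[-nd], Cout)), cols = cols, dims = d, k = k)
}

nn_conv_bwd <- function(cache, Wm, dy) {
  d <- cache$dims; nd <- length(d); k <- cache$k
  n <- prod(d[-nd]); C <- d[nd]
  dY <- matrix(dy, n, ncol(Wm))
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  dcols <- dY %*% t(Wm)
  dx <- if (k == 1) array(dcols, d)
        else if (nd == 3) array(cpp_col2im2(dcols, d[1], d[2], C, k), d)
        else array(cpp_col2im3(dcols, d[1], d[2], d[3], C, k), d)
  list(dx = dx, dW = dW, db = db)
}

# ---- relu / pool / upsample ------------------------------------------------

nn_relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
nn_relu_bwd <- function(cache, dy) dy * cache$mask

nn_pool_fwd <- function(x) {
  d <- dim(x); nd <- length(d)
  if (nd == 3) {
    r <- cpp_maxpool2(as.vector(x), d[1], d[2], d[3])
    list(out = array(r$y, c(d[1] / 2, d[2] / 2, d[3])), idx = r$idx, dims = d)
  } else {
    r <- cpp_maxpool3(as.vector(x), d[1], d[2], d[3], d[4])
    list(out = array(r$y, c(d[1] / 2, d[2] / 2, d[3] / 2, d[4])),
         idx = r$idx, dims = d)
  }
}

nn_pool_bwd <- function(cache, dy) {
  d <- cache$dims
  if (length(d) == 3)
    array(cpp_maxpool2_bwd(as.vector(dy), cache$idx, d[1], d[2], d[3]), d)
  else
    array(cpp_maxpool3_bwd(as.vector(dy), cache$idx, d[1], d[2], d[3], d[4]), d)
}

nn_up_fwd <- function(x) {
  d <- dim(x)
  if (length(d) == 3)
    list(out = array(cpp_upsample2(as.vector(x), d[1], d[2], d[3]),
                     c(2 * d[1], 2 * d[2], d[3])), dims = d)
  else
    list(out = array(cpp_upsample3(as.vector(x), d[1], d[2], d[3], d[4]),
                     c(2 * d[1], 2 * d[2], 2 * d[3], d[4])), dims = d)
}

nn_up_bwd <- function(cache, dy) {
  d <- cache$dims
  if (length(d) == 3)
    array(cpp_upsample2_bwd(as.vector(dy), d[1], d[2], d[3]), d)
  else
    array(cpp_upsample3_bwd(as.vector(dy), d[1], d[2], d[3], d[4]), d)
}

# ---- softmax over the trailing class dimension -----------------------------

nn_softmax <- function(z) {
  d <- dim(z); nd <- length(d)
  n <- prod(d[-nd]); K <- d[nd]
  zm <- matrix(z, n, K)
  zm <- zm - apply(zm, 1, max)
  e <- exp(zm)
  array(e / rowSums(e), d)
}

# dL/dlogits from dL/dprobs for a per-voxel softmax
nn_softmax_bwd <- function(probs, dprobs) {
  d <- dim(probs); nd <- length(d)
  n <- prod(d[-nd]); K <- d[nd]
  p <- matrix(probs, n, K); g <- matrix(dprobs, n, K)
  array(p * (g - rowSums(g * p)), d)
}

# ---- conv blocks -----------------------------------------------------------
# plain: (conv3 -> relu) x 2
# dense: n layers of conv3(acc)->relu concatenated onto acc ("tightly
#        connected paths"), then a 1x1 transition conv -> relu

block_fwd <- function(bp, x) {
  if (bp$type == "plain") {
    caches <- vector("list", length(bp$convs))
    h <- x
    for (i in seq_along(bp$convs)) {
      cv <- nn_conv_fwd(h, bp$convs[[i]]$W, bp$convs[[i]]$b, 3)
      rl <- nn_relu_fwd(cv$out)
      caches[[i]] <- list(conv = cv, relu = rl)
      h <- rl$out
    }
    list(out = h, caches = caches)
  } else {
    acc <- x
    lcaches <- vector("list", length(bp$layers))
    for (i in seq_along(bp$layers)) {
      cv <- nn_conv_fwd(acc, bp$layers[[i]]$W, bp$layers[[i]]$b, 3)
      rl <- nn_relu_fwd(cv$out)
      lcaches[[i]] <- list(conv = cv, relu = rl, cin = .nchan(acc))
      acc <- chan_cat(acc, rl$out)
    }
    cv <- nn_conv_fwd(acc, bp$trans$W, bp$trans$b, 1)
    rl <- nn_relu_fwd(cv$out)
    list(out = rl$out, caches = lcaches, trans = list(conv = cv, relu = rl))
  }
}

block_bwd <- function(bp, cache, dout) {
  if (bp$type == "plain") {
    g <- list(type = "plain", convs = vector("list", length(bp$convs)))
    dh <- dout
    for (i in rev(seq_along(bp$convs))) {
      dh <- nn_relu_bwd(cache$caches[[i]]$relu, dh)
      cb <- nn_conv_bwd(cache$caches[[i]]$conv, bp$convs[[i]]$W, dh)
      g$convs[[i]] <- list(W = cb$dW, b = cb$db)
      dh <- cb$dx
    }
    list(dx = dh, grads = g)
  } else {
    g <- list(type = "dense", layers = vector("list", length(bp$layers)),
              trans = NULL)
    dt <- nn_relu_bwd(cache$trans$relu, dout)
    cb <- nn_conv_bwd(cache$trans$conv, bp$trans$W, dt)
    g$trans <- list(W = cb$dW, b = cb$db)
    dacc <- cb$dx
    for (i in rev(seq_along(bp$layers))) {
      cin <- cache$caches[[i]]$cin
      gsz <- .nchan(dacc) - cin
      dy <- chan_get(dacc, cin + seq_len(gsz))
      dacc <- chan_get(dacc, seq_len(cin))
      dy <- nn_relu_bwd(cache$caches[[i]]$relu, dy)
      cb <- nn_conv_bwd(cache$caches[[i]]$conv, bp$layers[[i]]$W, dy)
      g$layers[[i]] <- list(W = cb$dW, b = cb$db)
      dacc <- dacc + cb$dx
    }
    list(dx = dacc, grads = g)
  }
}

# ---- parameter utilities ---------------------------------------------------

# recursively apply f to every numeric leaf of nested lists a (and b, c)
param_map <- function(f, a, b = NULL, c_ = NULL) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) {
      if (is.null(a[[i]]) || is.character(a[[i]])) next
      out[[i]] <- param_map(f, a[[i]],
                            if (!is.null(b)) b[[i]],
                            if (!is.null(c_)) c_[[i]])
    }
    out
  } else if (is.numeric(a)) {
    f(a, b, c_)
  } else a
}

adam_init <- function(params) {
  list(m = param_map(function(a, ...) a * 0, params),
       v = param_map(function(a, ...) a * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map(function(m, g, ...) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- param_map(function(v, g, ...) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- param_map(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

grad_zero <- function(params) param_map(function(a, ...) a * 0, params)
grad_add <- function(a, b) param_map(function(x, y, ...) x + y, a, b)
grad_scale <- function(a, s) param_map(function(x, ...) x * s, a)

grad_global_norm <- function(g) {
  s <- 0
  param_map(function(x, ...) { s <<- s + sum(x^2); x }, g)
  sqrt(s)
}

grad_clip <- function(g, max_norm) {
  n <- grad_global_norm(g)
  if (is.finite(n) && n > max_norm) grad_scale(g, max_norm / n) else g
}
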