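#' @title Segmentation network architectures
#' @name networks
#' @description
#' The three architectures used by HFS-Net: a 2D U-Net, a 2D DenseU-Net (a
#' U-Net whose convolution blocks are dense blocks with concatenative
#' tightly-connected paths), and a 3D U-Net for the volumetric fusion stage.
#' All map a channel-last input to per-voxel class probabilities (softmax
#' over the trailing dimension). Sizes are fully configurable; the tiny
#' profile (depth 3, base width 8) is the default used in tests and
#' desk-scale experiments.
NULL

#' Network configuration
#'
#' @param arch one of `"unet2d"`, `"denseunet2d"`, `"unet3d"`.
#' @param in_channels input channels: 1 (portal-venous), 3 (dynamic stack) or
#'   5 (fusion stack).
#' @param out_classes number of output classes (>= 2; default 2,
#'   background/foreground).
#' @param depth number of resolution levels including the bottleneck
#'   (default 3); spatial dims must be divisible by `2^(depth - 1)`.
#' @param base_width channels at the first level, doubling per level
#'   (default 8).
#' @param growth_rate dense-block growth rate (DenseU-Net only, default 8;
#'   0 degenerates the block to a plain 1x1 projection).
#' @param n_dense_layers layers per dense block (default 2).
#' @param seed seed for deterministic weight initialization.
#' @return object of class `net_config`.
#' @export
net_config <- function(arch = c("unet2d", "denseunet2d", "unet3d"),
                       in_channels = 1, out_classes = 2, depth = 3,
                       base_width = 8, growth_rate = 8, n_dense_layers = 2,
                       seed = 1L) {
  arch <- match.arg(arch)
  if (out_classes < 2) stop2("out_classes must be >= 2")
  if (depth < 2) stop2("depth must be >= 2")
  structure(list(arch = arch, in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 growth_rate = as.integer(growth_rate),
                 n_dense_layers = as.integer(n_dense_layers),
                 seed = as.integer(seed)),
            class = "net_config")
}

.init_conv <- function(cin, cout, k, nspatial) {
  fan_in <- k^nspatial * cin
  list(W = matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
       b = rep(0, cout))
}

.make_block <- function(type, cin, width, cfg, nspatial) {
  if (type == "plain") {
    list(type = "plain",
         convs = list(.init_conv(cin, width, 3, nspatial),
                      .init_conv(width, width, 3, nspatial)))
  } else {
    g <- cfg$growth_rate
    nl <- if (g > 0) cfg$n_dense_layers else 0L
    layers <- vector("list", nl)
    acc <- cin
    for (i in seq_len(nl)) {
      layers[[i]] <- .init_conv(acc, g, 3, nspatial)
      acc <- acc + g
    }
    list(type = "dense", layers = layers,
         trans = .init_conv(acc, width, 1, nspatial))
  }
}

#' Build a network from its configuration
#'
#' Weight initialization is He-scaled Gaussian, deterministic given
#' `config$seed`.
#'
#' @param config a [net_config()].
#' @return object of class `hfs_net` with fields `config` and `params`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "net_config"))
  set.seed(config$seed)
  nsp <- if (config$arch == "unet3d") 3L else 2L
  btype <- if (config$arch == "denseunet2d") "dense" else "plain"
  L <- config$depth
  w <- config$base_width * 2^(seq_len(L) - 1)
  enc <- vector("list", L - 1)
  cin <- config$in_channels
  for (l in seq_len(L - 1)) {
    enc[[l]] <- .make_block(btype, cin, w[l], config, nsp)
    cin <- w[l]
  }
  bott <- .make_block(btype, cin, w[L], config, nsp)
  dec <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    dec[[l]] <- .make_block(btype, w[l + 1] + w[l], w[l], config, nsp)
  }
  outc <- .init_conv(w[1], config$out_classes, 1, nsp)
  structure(list(config = config,
                 params = list(enc = enc, bott = bott, dec = dec, out = outc),
                 widths = w),
            class = "hfs_net")
}

#' @export
print.hfs_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<hfs_net> %s in=%d classes=%d depth=%d base=%d%s\n",
              cfg$arch, cfg$in_channels, cfg$out_classes, cfg$depth,
              cfg$base_width,
              if (cfg$arch == "denseunet2d")
                sprintf(" growth=%d", cfg$growth_rate) else ""))
  invisible(x)
}

.check_input <- function(net, x) {
  cfg <- net$config
  nd <- .ndims(x)
  need <- if (cfg$arch == "unet3d") 4L else 3L
  if (nd != need)
    stop2("%s expects a %dD channel-last array, got %d dims", cfg$arch, need, nd)
  if (.nchan(x) != cfg$in_channels)
    stop2("%s expects %d input channel(s), got %d", cfg$arch,
          cfg$in_channels, .nchan(x))
  f <- 2^(cfg$depth - 1)
  if (any(.spatial(x) %% f != 0))
    stop2("spatial dims (%s) must be divisible by %d",
          paste(.spatial(x), collapse = "x"), f)
}

# forward pass; returns probs and (optionally) caches for backprop
network_forward <- function(net, x, with_cache = FALSE) {
  .check_input(net, x)
  p <- net$params
  L <- net$config$depth
  skips <- vector("list", L - 1)
  cc <- list(enc = vector("list", L - 1), dec = vector("list", L - 1))
  h <- x
  for (l in seq_len(L - 1)) {
    bf <- block_fwd(p$enc[[l]], h)
    skips[[l]] <- bf$out
    pf <- nn_pool_fwd(bf$out)
    if (with_cache) cc$enc[[l]] <- list(block = bf, pool = pf)
    h <- pf$out
  }
  bb <- block_fwd(p$bott, h)
  if (with_cache) cc$bott <- bb
  h <- bb$out
  for (l in rev(seq_len(L - 1))) {
    uf <- nn_up_fwd(h)
    hcat <- chan_cat(uf$out, skips[[l]])
    df <- block_fwd(p$dec[[l]], hcat)
    if (with_cache)
      cc$dec[[l]] <- list(up = uf, block = df, up_ch = .nchan(uf$out))
    h <- df$out
  }
  oc <- nn_conv_fwd(h, p$out$W, p$out$b, 1)
  probs <- nn_softmax(oc$out)
  if (with_cache) { cc$out <- oc; cc$probs <- probs }
  list(probs = probs, cache = if (with_cache) cc else NULL)
}

# backward pass from dL/dprobs; returns gradients shaped like net$params
network_backward <- function(net, cache, dprobs) {
  p <- net$params
  L <- net$config$depth
  g <- list(enc = vector("list", L - 1), bott = NULL,
            dec = vector("list", L - 1), out = NULL)
  dlogits <- nn_softmax_bwd(cache$probs, dprobs)
  cb <- nn_conv_bwd(cache$out, p$out$W, dlogits)
  g$out <- list(W = cb$dW, b = cb$db)
  dh <- cb$dx
  dskip <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    bb <- block_bwd(p$dec[[l]], cache$dec[[l]]$block, dh)
    g$dec[[l]] <- bb$grads
    upc <- cache$dec[[l]]$up_ch
    d_up <- chan_get(bb$dx, seq_len(upc))
    dskip[[l]] <- chan_get(bb$dx, upc + seq_len(.nchan(bb$dx) - upc))
    dh <- nn_up_bwd(cache$dec[[l]]$up, d_up)
  }
  bb <- block_bwd(p$bott, cache$bott, dh)
  g$bott <- bb$grads
  dh <- bb$dx
  for (l in rev(seq_len(L - 1))) {
    dpool <- nn_pool_bwd(cache$enc[[l]]$pool, dh)
    bb <- block_bwd(p$enc[[l]], cache$enc[[l]]$block,
                    dpool + dskip[[l]])
    g$enc[[l]] <- bb$grads
    dh <- bb$dx
  }
  g
}

#' Per-voxel class probabilities for a batch
#'
#' Runs the network in inference mode. Outputs are in `[0, 1]` and sum to 1
#' over the class dimension at every voxel; no parameters are updated.
#'
#' @param model an `hfs_net`.
#' @param batch a single channel-last array or a list of them.
#' @return probability array(s) matching the input spatial shape with
#'   `out_classes` trailing channels.
#' @export
predict_probs <- function(model, batch) {
  stopifnot(inherits(model, "hfs_net"))
  if (is.list(batch)) return(lapply(batch, function(x) predict_probs(model, x)))
  network_forward(model, batch, with_cache = FALSE)$probs
}

#' Save / load a model checkpoint
#'
#' Stores weights, the network configuration, and any training configuration
#' attached to the model.
#'
#' @param model an `hfs_net` (possibly with a `$training` record).
#' @param path checkpoint file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "hfs_net"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "hfs_net"))
  m
}
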