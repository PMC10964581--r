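#' @title Sub-model specification and training
#' @name training
#' @description
#' Each of the five HFS-Net sub-models is a (phase input, architecture, loss)
#' triple. The defaults reproduce the published strategy table: `f_liver`
#' (portal-venous, 2D DenseU-Net, ce+dice), `f_size` (dynamic, 2D DenseU-Net,
#' focal+dice), `f_large` (portal-venous, 2D U-Net, ce), `f_small` (dynamic,
#' 2D DenseU-Net, focal+dice), `f_3d` (fusion stack, 3D U-Net, focal+dice).
#' Training is Adam with per-slice (or per-patch) updates, best-validation
#' checkpoint selection, and a divergence guard; deterministic given the
#' seed.
NULL

#' Sub-model specification
#'
#' @param name one of `"f_liver"`, `"f_size"`, `"f_large"`, `"f_small"`,
#'   `"f_3d"`.
#' @param phase_input `"portal-venous"`, `"dynamic"` or `"fusion-stack"`.
#' @param arch a [net_config()].
#' @param loss a [loss_spec()] or a spec string like `"focal+dice"`.
#' @return object of class `submodel_spec`.
#' @export
submodel_spec <- function(name, phase_input, arch, loss) {
  if (is.character(loss)) loss <- loss_spec(loss)
  stopifnot(inherits(arch, "net_config"), inherits(loss, "loss_spec"))
  structure(list(name = name, phase_input = phase_input, arch = arch,
                 loss = loss), class = "submodel_spec")
}

.phase_channels <- c("portal-venous" = 1L, "dynamic" = 3L, "fusion-stack" = 5L)

#' Default sub-model specifications
#'
#' The five defaults of the published strategy table, at a configurable
#' network scale. The `"tiny"` profile (depth 3, base width 8 for 2D; depth
#' 2, base width 8 for the 3D fusion net) is sized for single-CPU training on
#' phantom cohorts.
#'
#' @param profile `"tiny"` or `"full"`.
#' @param seed base seed; each sub-model derives its own offset.
#' @return named list of [submodel_spec()]s.
#' @export
default_submodel_specs <- function(profile = c("tiny", "full"), seed = 1L) {
  profile <- match.arg(profile)
  d2 <- if (profile == "tiny") list(depth = 3L, base = 8L, growth = 8L)
        else list(depth = 4L, base = 16L, growth = 12L)
  d3 <- if (profile == "tiny") list(depth = 2L, base = 8L)
        else list(depth = 3L, base = 12L)
  mk2 <- function(arch, inch, s)
    net_config(arch, in_channels = inch, out_classes = 2, depth = d2$depth,
               base_width = d2$base, growth_rate = d2$growth, seed = seed + s)
  list(
    f_liver = submodel_spec("f_liver", "portal-venous",
      mk2("denseunet2d", 1L, 11L), "ce+dice"),
    f_size = submodel_spec("f_size", "dynamic",
      mk2("denseunet2d", 3L, 12L), "focal+dice"),
    f_large = submodel_spec("f_large", "portal-venous",
      mk2("unet2d", 1L, 13L), "ce"),
    f_small = submodel_spec("f_small", "dynamic",
      mk2("denseunet2d", 3L, 14L), "focal+dice"),
    f_3d = submodel_spec("f_3d", "fusion-stack",
      net_config("unet3d", in_channels = 5L, out_classes = 2,
                 depth = d3$depth, base_width = d3$base, seed = seed + 15L),
      "focal+dice"))
}

#' Split cases into train / validation / test
#'
#' Seeded case-level shuffle into non-overlapping sets at the given ratio
#' (default 5:2:3); rounding favors the training set.
#'
#' @param n number of cases.
#' @param ratio three nonnegative weights (default `c(5, 2, 3)`).
#' @param seed shuffle seed.
#' @return list of index vectors `train`, `val`, `test`.
#' @export
split_cases <- function(n, ratio = c(5, 2, 3), seed = 1L) {
  if (n < 3) stop2("need at least 3 cases to split")
  set.seed(seed)
  idx <- sample.int(n)
  p <- ratio / sum(ratio)
  n_val <- floor(n * p[2])
  n_test <- floor(n * p[3])
  n_train <- n - n_val - n_test
  list(train = sort(idx[seq_len(n_train)]),
       val = sort(idx[n_train + seq_len(n_val)]),
       test = sort(idx[n_train + n_val + seq_len(n_test)]))
}

# ---- model-space intensities ----------------------------------------------

# phantom phases are HU-like; modelling uses the soft-tissue window followed
# by per-volume min-max to [0,1] (same policy as preprocess())
case_model_phases <- function(case, clip = c(-200, 300)) {
  lapply(case$volume$phases, function(v) {
    v <- pmin(pmax(v, clip[1]), clip[2])
    rng <- range(v)
    if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  })
}

# channel-last input for one slice of a case under a phase_input mode
slice_input <- function(phases_norm, s, phase_input) {
  if (phase_input == "portal-venous") {
    v <- phases_norm$portal_venous[s, , ]
    array(v, c(dim(v), 1L))
  } else if (phase_input == "dynamic") {
    h <- dim(phases_norm$non_contrast)[2]
    w <- dim(phases_norm$non_contrast)[3]
    out <- array(0, c(h, w, 3L))
    out[, , 1] <- phases_norm$non_contrast[s, , ]
    out[, , 2] <- phases_norm$arterial[s, , ]
    out[, , 3] <- phases_norm$portal_venous[s, , ]
    out
  } else stop2("fusion-stack inputs are assembled per volume, not per slice")
}

# per-slice target mask for a sub-model (class ids 1 = background, 2 = fg)
slice_target <- function(case, s, spec, m_px = 30) {
  if (spec$name == "f_liver") return(case$liver_mask[s, , ] + 1L)
  sl <- case$tumor_labels[s, , ]
  if (spec$name %in% c("f_small", "f_large")) {
    keep <- matrix(FALSE, nrow(sl), ncol(sl))
    for (id in unique(sl[sl > 0])) {
      ax <- longest_axis_px(which(sl == id, arr.ind = TRUE))
      small <- ax <= m_px
      if ((spec$name == "f_small") == small) keep <- keep | (sl == id)
    }
    return(keep + 1L)
  }
  (sl > 0) + 1L
}

# choose training slices for a 2D sub-model: tumor-bearing (branch-matching
# for f_small / f_large) slices plus a fraction of empty slices
select_slices <- function(case, spec, m_px = 30, empty_frac = 0.5,
                          max_per_case = 12L) {
  ns <- dim(case$tumor_labels)[1]
  if (spec$name == "f_liver") {
    liver_s <- which(apply(case$liver_mask, 1, any))
    pick <- liver_s[unique(round(seq(1, length(liver_s),
                                     length.out = min(max_per_case,
                                                      length(liver_s)))))]
    return(pick)
  }
  pos <- integer()
  for (s in seq_len(ns)) {
    tg <- slice_target(case, s, spec, m_px)
    if (any(tg == 2L)) pos <- c(pos, s)
  }
  if (length(pos) > max_per_case)
    pos <- pos[unique(round(seq(1, length(pos), length.out = max_per_case)))]
  neg <- setdiff(seq_len(ns), which(apply(case$tumor_labels, 1, function(x)
    any(x > 0))))
  n_neg <- min(length(neg), max(1L, round(length(pos) * empty_frac)))
  if (n_neg > 0 && length(neg) > 0)
    pos <- c(pos, sample(neg, n_neg))
  sort(unique(pos))
}

# random crop of a (H,W,C) input / (H,W) target pair, centered near a
# foreground pixel when one exists; keeps foreground well represented so
# per-sample updates do not collapse to all-background
crop_sample <- function(x, y, crop, fg_class = 2L, center_mask = NULL) {
  d <- dim(y)
  if (crop >= d[1] && crop >= d[2]) return(list(x = x, y = y))
  fg <- which(y == fg_class, arr.ind = TRUE)
  if (nrow(fg) == 0 && !is.null(center_mask))
    fg <- which(center_mask, arr.ind = TRUE)  # hard negatives inside the liver
  ctr <- if (nrow(fg) > 0) fg[sample.int(nrow(fg), 1), ] else
    c(sample.int(d[1], 1), sample.int(d[2], 1))
  ctr <- ctr + round(runif(2, -crop / 4, crop / 4))
  r0 <- min(max(ctr[1] - crop %/% 2, 1), d[1] - crop + 1)
  c0 <- min(max(ctr[2] - crop %/% 2, 1), d[2] - crop + 1)
  ri <- r0:(r0 + crop - 1); ci <- c0:(c0 + crop - 1)
  list(x = x[ri, ci, , drop = FALSE], y = y[ri, ci])
}

# foreground dice of a trained model over validation samples
.val_dice <- function(model, samples, threshold = 0.5) {
  num <- 0; den <- 0
  for (sm in samples) {
    p <- network_forward(model, sm$x)$probs
    fg <- array(chan_get(p, .nchan(p)) >= threshold, dim(p)[-.ndims(p)])
    t <- sm$y == 2L
    num <- num + 2 * sum(fg & t)
    den <- den + sum(fg) + sum(t)
  }
  if (den == 0) 1 else num / den
}

#' Train one sub-model on a phantom cohort
#'
#' Builds the network from the spec, assembles per-slice (or per-patch)
#' samples from the training cases, and runs Adam with per-sample updates.
#' The epoch with the best validation foreground dice is kept. For losses
#' with a `mfb_focal` term, class weights are computed from training-set
#' class frequencies via [mfb_weights()]. Divergent losses (NaN) abort with
#' diagnostics. Deterministic given `seed`.
#'
#' @param cases list of `phantom_case` objects (training set).
#' @param spec a [submodel_spec()].
#' @param val_cases validation cases.
#' @param epochs training epochs (default 6).
#' @param lr Adam learning rate (default 2e-3).
#' @param m_px size demarcation used to build branch targets (default 30).
#' @param max_per_case cap on sampled slices per case.
#' @param patience early-stopping patience in epochs (default 3).
#' @param seed RNG seed for sampling order.
#' @param crop_size training samples are square crops of this size centered
#'   near foreground (default: 32 for tumor models, full slices for
#'   `f_liver`); validation uses full slices. Keeps the foreground class
#'   represented under per-sample updates.
#' @param clip_norm global gradient-norm clip (default 5).
#' @param batch_size samples per averaged gradient step (default 2).
#' @param samples,val_samples optional pre-built sample lists (used by the
#'   fusion stage); override `cases` / `val_cases`.
#' @return the trained `hfs_net` with a `$training` record (per-epoch
#'   validation dice, losses, best epoch).
#' @export
train_submodel <- function(cases, spec, val_cases = NULL, epochs = 6,
                           lr = 2e-3, m_px = 30, max_per_case = 12L,
                           patience = 3L, seed = 1L, crop_size = NULL,
                           clip_norm = 5, batch_size = 2L,
                           samples = NULL, val_samples = NULL) {
  stopifnot(inherits(spec, "submodel_spec"))
  # tumor models train on foreground-centered crops sized so the foreground
  # class stays well represented (a >30 px lesion fills about a third of a
  # 48 px crop); the liver occupies a large, balanced fraction of a slice,
  # so the liver model trains on full slices
  crop_size <- crop_size %||% switch(spec$name,
    f_size = 32L, f_small = 32L, f_large = 48L, .Machine$integer.max)
  set.seed(seed)
  if (is.null(samples)) {
    if (length(cases) == 0) stop2("empty training split")
    samples <- list()
    for (case in cases) {
      ph <- case_model_phases(case)
      for (s in select_slices(case, spec, m_px, max_per_case = max_per_case)) {
        sm <- crop_sample(slice_input(ph, s, spec$phase_input),
                          slice_target(case, s, spec, m_px), crop_size,
                          center_mask = case$liver_mask[s, , ])
        samples[[length(samples) + 1L]] <- sm
      }
    }
    if (!is.null(val_cases)) {
      val_samples <- list()
      for (case in val_cases) {
        ph <- case_model_phases(case)
        for (s in select_slices(case, spec, m_px, max_per_case = max_per_case)) {
          val_samples[[length(val_samples) + 1L]] <- list(
            x = slice_input(ph, s, spec$phase_input),
            y = slice_target(case, s, spec, m_px))
        }
      }
    }
  }
  if (length(samples) == 0) stop2("no training samples for %s", spec$name)

  loss <- spec$loss
  if ("mfb_focal" %in% loss$terms && is.null(loss$class_weights)) {
    K <- spec$arch$out_classes
    cnt <- rep(0, K)
    for (sm in samples) cnt <- cnt + tabulate(sm$y, K)
    loss$class_weights <- mfb_weights(cnt / sum(cnt))
  }

  run_once <- function(init_seed) {
    arch <- spec$arch
    arch$seed <- init_seed
    model <- build_network(arch)
    state <- adam_init(model$params)
    hist <- data.frame(epoch = integer(), mean_loss = numeric(),
                       val_dice = numeric())
    best <- list(dice = -Inf, params = model$params, epoch = 0L)
    stall <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(samples))
      tot <- 0
      acc <- NULL; n_acc <- 0L
      for (i in ord) {
        sm <- samples[[i]]
        fw <- network_forward(model, sm$x, with_cache = TRUE)
        lg <- compound_loss(loss, fw$probs, sm$y, grad = TRUE)
        if (!is.finite(lg$value))
          stop2("loss diverged (%.3g) for %s at epoch %d", lg$value,
                spec$name, ep)
        g <- network_backward(model, fw$cache, lg$grad)
        acc <- if (is.null(acc)) g else grad_add(acc, g)
        n_acc <- n_acc + 1L
        if (n_acc == batch_size || i == ord[length(ord)]) {
          grads <- grad_clip(grad_scale(acc, 1 / n_acc), clip_norm)
          upd <- adam_step(model$params, grads, state, lr = lr)
          model$params <- upd$params
          state <- upd$state
          acc <- NULL; n_acc <- 0L
        }
        tot <- tot + lg$value
      }
      vd <- if (!is.null(val_samples) && length(val_samples))
        .val_dice(model, val_samples) else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep,
                                     mean_loss = tot / length(samples),
                                     val_dice = vd))
      if (!is.na(vd)) {
        if (vd > best$dice) {
          best <- list(dice = vd, params = model$params, epoch = ep)
          stall <- 0L
        } else if (best$dice > 0) {
          # a model that has not learned anything yet is warming up, not
          # stalling: early stopping engages once validation dice is nonzero
          stall <- stall + 1L
        }
        if (stall >= patience) break
      } else best <- list(dice = NA_real_, params = model$params, epoch = ep)
    }
    model$params <- best$params
    list(model = model, hist = hist, best = best)
  }
  # one restart from a fresh initialization if a run ends with zero
  # validation dice (plain-CE models can fail to leave the background
  # optimum from an unlucky init)
  res <- run_once(spec$arch$seed)
  if (!is.null(val_samples) && length(val_samples) &&
      !is.na(res$best$dice) && res$best$dice <= 0) {
    res <- run_once(spec$arch$seed + 7919L)
  }
  model <- res$model
  model$training <- list(spec = spec, history = res$hist,
                         best_epoch = res$best$epoch,
                         val_dice = res$best$dice, loss = loss, lr = lr,
                         seed = seed, m_px = m_px)
  model
}
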