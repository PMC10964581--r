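#' @title The HFS-Net pipeline
#' @name pipeline
#' @description
#' The three-stage hierarchical fusion strategy. Stage I segments the liver
#' (portal-venous DenseU-Net) and produces a tumor probability map from the
#' dynamic stack whose only purpose is per-slice tumor size estimation. Stage
#' II routes every per-slice tumor instance by its longest in-plane axis —
#' `<= m` pixels (default `m = 30`, about 4.2 cm at 1.4 mm/px) to the
#' small-tumor branch (dynamic DenseU-Net), `> m` to the large-tumor branch
#' (portal-venous U-Net); a slice carrying both kinds of instance feeds both
#' branches. Stage III stacks the portal-venous image with the four sub-model
#' outputs into a 5-channel volume and segments the final 3D tumor mask with
#' a patch-based 3D U-Net. `mode = "2d"` skips the fusion stage and unions
#' the branch outputs.
NULL

#' Slice-wise liver segmentation (Stage I)
#'
#' @param phases_norm normalized phase volumes (see the `phases` element of a
#'   `phantom_case`, windowed to `[0, 1]`).
#' @param model trained `f_liver` network.
#' @return liver foreground-probability volume, same shape as the input
#'   phase.
#' @export
segment_liver <- function(phases_norm, model) {
  .slicewise_prob(phases_norm, model, "portal-venous")
}

#' Slice-wise tumor probability for size estimation (Stage I)
#'
#' Per-slice tumor probability maps from the dynamic three-channel stack;
#' used for size estimation and routing, not for the final mask.
#'
#' @inheritParams segment_liver
#' @param model trained `f_size` network.
#' @export
segment_size <- function(phases_norm, model) {
  .slicewise_prob(phases_norm, model, "dynamic")
}

.slicewise_prob <- function(phases_norm, model, phase_input) {
  stopifnot(inherits(model, "hfs_net"))
  d <- dim(phases_norm$portal_venous)
  out <- array(0, d)
  for (s in seq_len(d[1])) {
    x <- slice_input(phases_norm, s, phase_input)
    p <- network_forward(model, x)$probs
    out[s, , ] <- chan_get(p, .nchan(p))[, , 1]
  }
  out
}

#' Route per-slice tumor instances by size (Stage II)
#'
#' Binarizes the Stage-I tumor probability, labels per-slice connected
#' components (8-connectivity), measures each component's longest axis, and
#' assigns it to the small branch iff the axis is `<= m` pixels, else to the
#' large branch. A slice enters a branch's slice set when it carries at least
#' one component of that branch (it may enter both).
#'
#' @param size_prob tumor probability volume from [segment_size()] (or a
#'   binary volume).
#' @param m demarcation in pixels (default 30).
#' @param threshold binarization threshold (default 0.5).
#' @param min_px per-slice components smaller than this many pixels are
#'   ignored as speckle (default 3).
#' @return a `routing_plan`: data.frame `instances` (slice, comp, axis_px,
#'   branch), slice sets `slices_for_small`, `slices_for_large`, and the
#'   per-slice component label volume.
#' @export
route <- function(size_prob, m = 30, threshold = 0.5, min_px = 3) {
  d <- dim(size_prob)
  comp_vol <- array(0L, d)
  rows <- list()
  for (s in seq_len(d[1])) {
    lab <- label_components(size_prob[s, , ] >= threshold)
    n <- max(lab)
    if (n == 0) next
    keep <- 0L
    for (k in seq_len(n)) {
      px <- which(lab == k, arr.ind = TRUE)
      if (nrow(px) < min_px) next
      keep <- keep + 1L
      ax <- longest_axis_px(px)
      comp_vol[s, , ][lab == k] <- keep
      rows[[length(rows) + 1L]] <- data.frame(
        slice = s, comp = keep, axis_px = ax,
        branch = if (ax <= m) "small" else "large")
    }
  }
  inst <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice = integer(), comp = integer(), axis_px = numeric(),
               branch = character())
  structure(list(instances = inst,
                 slices_for_small = sort(unique(inst$slice[inst$branch == "small"])),
                 slices_for_large = sort(unique(inst$slice[inst$branch == "large"])),
                 components = comp_vol, m = m, threshold = threshold,
                 min_px = min_px),
            class = "routing_plan")
}

#' @export
print.routing_plan <- function(x, ...) {
  cat(sprintf("<routing_plan> m=%d px: %d instance(s), %d small slice(s), %d large slice(s)\n",
              x$m, nrow(x$instances), length(x$slices_for_small),
              length(x$slices_for_large)))
  invisible(x)
}

#' Run one divide-and-conquer branch (Stage II)
#'
#' Applies the branch network on the slices the routing plan assigns to that
#' branch (small branch: 3-channel dynamic input; large branch: 1-channel
#' portal-venous input), leaving all other slices zero.
#'
#' @inheritParams segment_liver
#' @param plan a [route()] result.
#' @param branch `"small"` or `"large"`.
#' @param model the trained branch network.
#' @return branch tumor probability volume (zeros on unrouted slices).
#' @export
run_branch <- function(phases_norm, plan, branch = c("small", "large"),
                       model) {
  branch <- match.arg(branch)
  stopifnot(inherits(plan, "routing_plan"), inherits(model, "hfs_net"))
  d <- dim(phases_norm$portal_venous)
  out <- array(0, d)
  slices <- if (branch == "small") plan$slices_for_small else
    plan$slices_for_large
  phase_input <- if (branch == "small") "dynamic" else "portal-venous"
  need <- .phase_channels[[phase_input]]
  if (model$config$in_channels != need)
    stop2("%s branch model must take %d channel(s), got %d", branch, need,
          model$config$in_channels)
  for (s in slices) {
    x <- slice_input(phases_norm, s, phase_input)
    p <- network_forward(model, x)$probs
    out[s, , ] <- chan_get(p, .nchan(p))[, , 1]
  }
  out
}

#' Assemble the Stage-III fusion input
#'
#' Stacks, in fixed channel order, the portal-venous image and the four
#' sub-model outputs: `(pv, liver, size, large, small)`. The order is
#' recorded on the result (`attr "channel_order"`) together with a config
#' hash so silent reordering is detectable.
#'
#' @param pv_norm normalized portal-venous volume `(slices, H, W)`.
#' @param liver_prob,size_prob,large_prob,small_prob same-shape sub-model
#'   output volumes.
#' @return `(slices, H, W, 5)` array with attributes `channel_order` and
#'   `config_hash`.
#' @export
assemble_fusion_input <- function(pv_norm, liver_prob, size_prob, large_prob,
                                  small_prob) {
  chans <- list(pv = pv_norm, liver = liver_prob, size = size_prob,
                large = large_prob, small = small_prob)
  d <- dim(pv_norm)
  for (nm in names(chans))
    if (!identical(dim(chans[[nm]]), d))
      stop2("fusion channel '%s' shape mismatch", nm)
  out <- array(0, c(d, 5L))
  for (k in seq_along(chans)) out[, , , k] <- chans[[k]]
  attr(out, "channel_order") <- names(chans)
  attr(out, "config_hash") <- paste(names(chans), collapse = "|")
  out
}

#' 3D fusion inference (Stage III)
#'
#' Splits the 5-channel fusion volume into fixed-depth Z patches, runs the 3D
#' U-Net on each, and blends overlapping patches by averaging.
#'
#' @param fusion_input output of [assemble_fusion_input()].
#' @param model trained `f_3d` network.
#' @param patch_depth Z extent of each patch (default 8).
#' @param stride Z stride between patches (default `patch_depth / 2`).
#' @return fused tumor probability volume `(slices, H, W)`.
#' @export
fuse_3d <- function(fusion_input, model, patch_depth = 8,
                    stride = patch_depth / 2) {
  stopifnot(inherits(model, "hfs_net"))
  d <- dim(fusion_input)
  ns <- d[1]
  acc <- array(0, d[1:3])
  wt <- array(0, d[1:3])
  starts <- unique(pmin(pmax(seq(1, ns, by = stride), 1), ns - patch_depth + 1))
  if (ns <= patch_depth) starts <- 1
  for (s0 in starts) {
    zz <- s0:(min(s0 + patch_depth - 1, ns))
    x <- fusion_input[zz, , , , drop = FALSE]
    p <- network_forward(model, x)$probs
    fg <- chan_get(p, .nchan(p))[, , , 1]
    acc[zz, , ] <- acc[zz, , ] + fg
    wt[zz, , ] <- wt[zz, , ] + 1
  }
  acc / pmax(wt, 1)
}

# drop 3D components below a voxel count (26-connectivity)
filter_small_components <- function(mask, min_voxels = 3) {
  lab <- label_components(mask != 0)
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}

#' Run the full HFS-Net pipeline on one case
#'
#' `mode = "3d"` runs all three stages; `mode = "2d"` applies the
#' hierarchical stages only and takes the union of the routed branch outputs
#' as the final probability (no fusion). The final tumor mask is binarized at
#' `threshold`, optionally gated to the predicted liver, and cleaned of
#' components below `min_component` voxels.
#'
#' @param case a `phantom_case`, or a list with `phases` (raw HU-like
#'   volumes).
#' @param models named list with entries `f_liver`, `f_size`, `f_large`,
#'   `f_small` and (for 3d mode) `f_3d`, as trained by [train_hfsnet()].
#' @param mode `"3d"` (full pipeline) or `"2d"` (hierarchical only).
#' @param m size demarcation in pixels (default 30).
#' @param threshold probability binarization threshold (default 0.5).
#' @param min_component minimum 3D component size in voxels (default 3).
#' @param gate_liver intersect the final tumor mask with the predicted liver
#'   (default TRUE).
#' @param patch_depth Z patch depth for the fusion stage.
#' @return a `case_result`: probability volumes `liver_prob`, `size_prob`,
#'   `large_prob`, `small_prob` (and `fused_prob` in 3d mode), the
#'   `routing` plan, and binary `final_mask` / `final_liver`.
#' @export
run_hfsnet <- function(case, models, mode = c("3d", "2d"), m = 30,
                       threshold = 0.5, min_component = 3, gate_liver = TRUE,
                       patch_depth = 8) {
  mode <- match.arg(mode)
  need <- c("f_liver", "f_size", "f_large", "f_small",
            if (mode == "3d") "f_3d")
  miss <- setdiff(need, names(models))
  if (length(miss)) stop2("missing sub-model(s) for mode %s: %s", mode,
                          paste(miss, collapse = ", "))
  ph <- if (!is.null(case$volume)) case_model_phases(case) else
    case_model_phases(list(volume = list(phases = case$phases)))
  liver_prob <- segment_liver(ph, models$f_liver)
  size_prob <- segment_size(ph, models$f_size)
  plan <- route(size_prob, m = m, threshold = threshold)
  large_prob <- run_branch(ph, plan, "large", models$f_large)
  small_prob <- run_branch(ph, plan, "small", models$f_small)
  if (mode == "3d") {
    fin <- assemble_fusion_input(ph$portal_venous, liver_prob, size_prob,
                                 large_prob, small_prob)
    fused <- fuse_3d(fin, models$f_3d, patch_depth = patch_depth)
    final_prob <- fused
  } else {
    fused <- NULL
    final_prob <- pmax(large_prob, small_prob)
  }
  final_liver <- liver_prob >= threshold
  mask <- final_prob >= threshold
  if (gate_liver) mask <- mask & final_liver
  mask <- filter_small_components(mask, min_component)
  structure(list(liver_prob = liver_prob, size_prob = size_prob,
                 large_prob = large_prob, small_prob = small_prob,
                 fused_prob = fused, final_mask = mask,
                 final_liver = final_liver, routing = plan, mode = mode),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result> mode=%s final tumor voxels=%d\n", x$mode,
              sum(x$final_mask)))
  invisible(x)
}

#' Train all five HFS-Net sub-models
#'
#' Trains `f_liver`, `f_size`, `f_large` and `f_small` on slice samples from
#' the training cases, then builds 5-channel fusion volumes for the training
#' cases with the trained Stage-I/II models and trains `f_3d` on Z patches of
#' those volumes.
#'
#' @param cases list of `phantom_case`s.
#' @param split a [split_cases()] result (indices into `cases`).
#' @param specs sub-model specs, default [default_submodel_specs()].
#' @param epochs_2d,epochs_3d training epochs for the 2D sub-models and the
#'   fusion net.
#' @param lr Adam learning rate.
#' @param m size demarcation in pixels.
#' @param patch_depth Z patch depth for fusion training.
#' @param seed RNG seed.
#' @param verbose print per-model validation dice.
#' @return named list of trained models (class `hfsnet_models`).
#' @export
train_hfsnet <- function(cases, split, specs = default_submodel_specs(),
                         epochs_2d = 6, epochs_3d = 6, lr = 2e-3, m = 30,
                         patch_depth = 8, seed = 1L, verbose = FALSE) {
  tr <- cases[split$train]
  va <- cases[split$val]
  models <- list()
  for (nm in c("f_liver", "f_size", "f_large", "f_small")) {
    # the plain-CE large-tumor model warms up slowly; give it twice the
    # epoch budget of the dice-driven models
    ep_n <- if (nm == "f_large") 2L * epochs_2d else epochs_2d
    models[[nm]] <- train_submodel(tr, specs[[nm]], val_cases = va,
                                   epochs = ep_n, lr = lr, m_px = m,
                                   patience = max(3L, epochs_2d),
                                   seed = seed + match(nm, names(specs)))
    if (verbose)
      message(sprintf("%s: val dice %.3f", nm, models[[nm]]$training$val_dice))
  }
  patches <- function(case_set, crop = 0L) {
    out <- list()
    for (case in case_set) {
      ph <- case_model_phases(case)
      liver_prob <- segment_liver(ph, models$f_liver)
      size_prob <- segment_size(ph, models$f_size)
      plan <- route(size_prob, m = m)
      fin <- assemble_fusion_input(ph$portal_venous, liver_prob, size_prob,
                                   run_branch(ph, plan, "large", models$f_large),
                                   run_branch(ph, plan, "small", models$f_small))
      target <- (case$tumor_labels > 0) + 1L
      ns <- dim(target)[1]
      tum_s <- which(apply(case$tumor_labels, 1, function(x) any(x > 0)))
      ctr <- if (length(tum_s)) round(mean(range(tum_s))) else round(ns / 2)
      starts <- unique(pmin(pmax(c(ctr - patch_depth,
                                   ctr - patch_depth %/% 2, ctr), 1),
                            ns - patch_depth + 1))
      for (s0 in starts) {
        zz <- s0:(s0 + patch_depth - 1)
        x <- fin[zz, , , , drop = FALSE]
        y <- target[zz, , , drop = FALSE]
        if (crop > 0 && crop < dim(y)[2]) {
          # in-plane crop around tumor foreground for class balance
          fg <- which(y == 2L, arr.ind = TRUE)
          ctr <- if (nrow(fg)) fg[sample.int(nrow(fg), 1), 2:3] else
            c(sample.int(dim(y)[2], 1), sample.int(dim(y)[3], 1))
          r0 <- min(max(ctr[1] - crop %/% 2, 1), dim(y)[2] - crop + 1)
          c0 <- min(max(ctr[2] - crop %/% 2, 1), dim(y)[3] - crop + 1)
          ri <- r0:(r0 + crop - 1); ci <- c0:(c0 + crop - 1)
          x <- x[, ri, ci, , drop = FALSE]
          y <- y[, ri, ci, drop = FALSE]
        }
        out[[length(out) + 1L]] <- list(x = x, y = array(y, dim(y)))
      }
    }
    out
  }
  set.seed(seed + 50L)
  models$f_3d <- train_submodel(NULL, specs$f_3d, epochs = epochs_3d, lr = lr,
                                seed = seed + 5L,
                                samples = patches(tr, crop = 32L),
                                val_samples = patches(va))
  if (verbose)
    message(sprintf("f_3d: val dice %.3f", models$f_3d$training$val_dice))
  structure(models, class = "hfsnet_models")
}

#' Ablation experiment grid
#'
#' Trains one single-strategy tumor-segmentation model per (phase,
#' architecture, loss) combination and evaluates dice per case, dice global
#' and per-pixel-size-bin detection sensitivity (bins `<=10`, `10-30`,
#' `30-50`, `>50` px) on the test split.
#'
#' @param cases list of `phantom_case`s.
#' @param split a [split_cases()] result.
#' @param phases subset of `c("portal-venous", "dynamic")`.
#' @param archs subset of `c("unet2d", "denseunet2d")`.
#' @param losses loss spec strings, e.g. `c("ce", "focal+dice")`.
#' @param epochs,lr training settings per combination.
#' @param theta detection threshold.
#' @param seed RNG seed.
#' @param out_csv optional CSV path for the results table.
#' @return data.frame, one row per grid point.
#' @export
ablation_grid <- function(cases, split, phases = c("portal-venous", "dynamic"),
                          archs = c("unet2d", "denseunet2d"),
                          losses = c("ce", "focal+dice"), epochs = 4,
                          lr = 2e-3, theta = 0.2, seed = 1L, out_csv = NULL) {
  ok_ph <- c("portal-venous", "dynamic")
  ok_ar <- c("unet2d", "denseunet2d")
  if (length(setdiff(phases, ok_ph)))
    stop2("unknown phase level(s): %s", paste(setdiff(phases, ok_ph), collapse = ", "))
  if (length(setdiff(archs, ok_ar)))
    stop2("unknown architecture level(s): %s",
          paste(setdiff(archs, ok_ar), collapse = ", "))
  grid <- expand.grid(phase = phases, arch = archs, loss = losses,
                      stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    gp <- grid[i, ]
    spec <- submodel_spec("f_size", gp$phase,
                          net_config(gp$arch,
                                     in_channels = .phase_channels[[gp$phase]],
                                     seed = seed + i),
                          gp$loss)
    model <- train_submodel(cases[split$train], spec,
                            val_cases = cases[split$val], epochs = epochs,
                            lr = lr, seed = seed + 100L + i)
    preds <- list(); refs <- list(); matches <- list()
    for (case in cases[split$test]) {
      ph <- case_model_phases(case)
      prob <- .slicewise_prob(ph, model, gp$phase)
      mask <- filter_small_components(prob >= 0.5, 3)
      preds[[length(preds) + 1L]] <- mask
      refs[[length(refs) + 1L]] <- case$tumor_labels
      matches[[length(matches) + 1L]] <- match_instances(mask, case$tumor_labels,
                                                         theta)
    }
    hits <- do.call(rbind, lapply(matches, `[[`, "ref_hits"))
    bin <- cut(hits$axis_px, c(-Inf, 10, 30, 50, Inf),
               labels = c("<=10px", "10-30px", "30-50px", ">50px"))
    det_bin <- tapply(hits$detected, bin, mean)
    rows[[i]] <- cbind(gp, data.frame(
      val_dice = model$training$val_dice,
      dice_per_case = dice_per_case(preds, refs),
      dice_global = dice_global(preds, lapply(refs, function(r) r > 0)),
      det_le10 = det_bin[["<=10px"]] %||% NA_real_,
      det_10_30 = det_bin[["10-30px"]] %||% NA_real_,
      det_30_50 = det_bin[["30-50px"]] %||% NA_real_,
      det_gt50 = det_bin[[">50px"]] %||% NA_real_))
  }
  res <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(res, out_csv, row.names = FALSE)
  res
}
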