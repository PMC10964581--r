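#' @title Detection and segmentation metrics
#' @name metrics
#' @description
#' The evaluation protocol for liver-tumor segmentation: Dice overlap per case
#' and pooled over cases ("dice global"), instance-level detection at overlap
#' threshold `theta` (a predicted component detects a labeled tumor in a slice
#' when their Dice exceeds `theta`; default `theta = 0.2`), sensitivity /
#' precision / F1 at four granularities (per tumor volume, per tumor cut, per
#' slice, per patient), mean absolute error of the maximum tumor diameter
#' (MTD MAE), and reporting stratified by tumor size and tumor count.
NULL

#' Dice coefficient
#'
#' `2|A ∩ B| / (|A| + |B|)` between two same-shape binary masks. Defined as 1
#' when both masks are empty. The Jaccard index is available via
#' [jaccard()].
#'
#' @param pred_mask,ref_mask binary (logical or 0/1) arrays of the same shape.
#' @return a fraction in `[0, 1]`.
#' @export
dice <- function(pred_mask, ref_mask) {
  if (!identical(dim(pred_mask) %||% length(pred_mask),
                 dim(ref_mask) %||% length(ref_mask)))
    stop2("mask shapes differ")
  a <- sum(pred_mask != 0)
  b <- sum(ref_mask != 0)
  if (a + b == 0) return(1)
  2 * sum(pred_mask != 0 & ref_mask != 0) / (a + b)
}

#' Jaccard index
#' @inheritParams dice
#' @return a fraction in `[0, 1]`; 1 when both masks are empty.
#' @export
jaccard <- function(pred_mask, ref_mask) {
  d <- dice(pred_mask, ref_mask)
  d / (2 - d)
}

#' Mean of per-case Dice
#'
#' Unweighted mean of the case-level Dice scores ("dice per case").
#'
#' @param pred_masks,ref_masks lists of same-shape binary volumes, one per case.
#' @export
dice_per_case <- function(pred_masks, ref_masks) {
  stopifnot(length(pred_masks) == length(ref_masks))
  if (length(pred_masks) == 0) stop2("empty case list")
  mean(mapply(dice, pred_masks, ref_masks))
}

#' Pooled Dice over cases
#'
#' Dice computed on the voxel sets pooled across all cases ("dice global"):
#' intersections and mask sizes are summed before the ratio, so large cases
#' dominate.
#'
#' @inheritParams dice_per_case
#' @export
dice_global <- function(pred_masks, ref_masks) {
  stopifnot(length(pred_masks) == length(ref_masks))
  if (length(pred_masks) == 0) stop2("empty case list")
  inter <- 0; a <- 0; b <- 0
  for (i in seq_along(pred_masks)) {
    p <- pred_masks[[i]] != 0
    r <- ref_masks[[i]] != 0
    if (!identical(dim(p), dim(r))) stop2("mask shapes differ in case %d", i)
    inter <- inter + sum(p & r)
    a <- a + sum(p); b <- b + sum(r)
  }
  if (a + b == 0) return(1)
  2 * inter / (a + b)
}

#' Longest in-plane axis of a pixel set
#'
#' Maximum pairwise Euclidean distance between pixel centers of one connected
#' component in one slice, in pixels. Uses the convex hull for large
#' components; a single pixel has axis 0.
#'
#' @param component_pixels two-column matrix of (row, col) pixel coordinates.
#' @return axis length in pixels.
#' @examples
#' longest_axis_px(cbind(1, 1:31)) # 30
#' @export
longest_axis_px <- function(component_pixels) {
  xy <- as.matrix(component_pixels)
  if (nrow(xy) == 0) stop2("empty pixel set")
  if (nrow(xy) == 1) return(0)
  if (nrow(xy) > 100) {
    h <- grDevices::chull(xy[, 2], xy[, 1])
    if (length(h) >= 2) xy <- xy[h, , drop = FALSE]
  }
  max(stats::dist(xy))
}

# connected-component labelling wrappers ------------------------------------

#' Label connected components
#'
#' 2D labelling uses 8-connectivity on an `(H, W)` mask; 3D labelling uses
#' 26-connectivity on a `(slices, H, W)` mask. Labels are `1..n` in scan order.
#'
#' @param mask binary matrix (2D) or array (3D).
#' @return integer array of the same shape.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  m <- as.integer(mask != 0)
  if (length(d) == 2) {
    out <- cpp_label2(m, d[1], d[2])
  } else if (length(d) == 3) {
    out <- cpp_label3(m, d[1], d[2], d[3])
  } else stop2("mask must be 2D or 3D")
  array(out, d)
}

# per-slice instance matching ------------------------------------------------

#' Match predicted components to labeled tumors slice by slice
#'
#' In every slice, predicted connected components (8-connectivity) are matched
#' greedily by descending pairwise Dice, one-to-one, to the cross-sections of
#' the reference tumor instances. A reference instance is detected in a slice
#' when its matched component's Dice exceeds `theta`; unmatched predicted
#' components are false positives and undetected reference instances false
#' negatives.
#'
#' @param pred_labels binary prediction volume `(slices, H, W)` (nonzero =
#'   tumor), or an already-labelled instance volume.
#' @param ref_labels integer reference instance volume (0 background, ids
#'   `1..n` label distinct tumors).
#' @param theta detection overlap threshold in `(0, 1)`; default 0.2.
#' @return a `case_matches` list with `ref_hits` (one row per reference
#'   instance per slice: `slice`, `ref_id`, `detected`, `best_dice`,
#'   `axis_px`) and `pred_comps` (one row per predicted component per slice:
#'   `slice`, `comp`, `matched`).
#' @export
match_instances <- function(pred_labels, ref_labels, theta = 0.2) {
  if (theta <= 0 || theta >= 1) stop2("theta must lie in (0, 1)")
  if (!identical(dim(pred_labels), dim(ref_labels))) stop2("shape mismatch")
  ns <- dim(ref_labels)[1]
  ref_rows <- list(); pred_rows <- list()
  for (s in seq_len(ns)) {
    rs <- ref_labels[s, , ]
    ps <- pred_labels[s, , ]
    pl <- label_components(ps != 0)
    ref_ids <- sort(unique(rs[rs > 0]))
    n_pred <- max(pl)
    if (length(ref_ids) == 0 && n_pred == 0) next
    dmat <- NULL
    if (length(ref_ids) > 0 && n_pred > 0) {
      dmat <- matrix(0, length(ref_ids), n_pred)
      for (ri in seq_along(ref_ids))
        for (pi in seq_len(n_pred))
          dmat[ri, pi] <- dice(pl == pi, rs == ref_ids[ri])
    }
    det <- rep(FALSE, length(ref_ids))
    best <- rep(0, length(ref_ids))
    matched_pred <- rep(FALSE, n_pred)
    if (!is.null(dmat)) {
      best <- apply(dmat, 1, max)
      repeat {
        m <- which(dmat == max(dmat), arr.ind = TRUE)[1, , drop = TRUE]
        if (dmat[m[1], m[2]] <= theta) break
        det[m[1]] <- TRUE
        matched_pred[m[2]] <- TRUE
        dmat[m[1], ] <- -1
        dmat[, m[2]] <- -1
        if (all(dmat <= theta)) break
      }
    }
    if (length(ref_ids) > 0) {
      axis <- vapply(ref_ids, function(id) {
        longest_axis_px(which(rs == id, arr.ind = TRUE))
      }, numeric(1))
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        slice = s, ref_id = ref_ids, detected = det,
        best_dice = best, axis_px = axis)
    }
    if (n_pred > 0) {
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        slice = s, comp = seq_len(n_pred), matched = matched_pred)
    }
  }
  empty_ref <- data.frame(slice = integer(), ref_id = integer(),
                          detected = logical(), best_dice = numeric(),
                          axis_px = numeric())
  empty_pred <- data.frame(slice = integer(), comp = integer(),
                           matched = logical())
  structure(list(
    ref_hits = if (length(ref_rows)) do.call(rbind, ref_rows) else empty_ref,
    pred_comps = if (length(pred_rows)) do.call(rbind, pred_rows) else empty_pred,
    n_slices = ns, theta = theta), class = "case_matches")
}

#' Detection sensitivity, precision and F1 at one granularity
#'
#' * `per_tumor_volume`: all per-slice tumor instances pooled across cases.
#' * `per_tumor_cut`: per-case instance detection rates, averaged over cases.
#' * `per_slice`: a tumor-bearing slice counts as detected when at least one
#'   of its tumors is detected; a slice with predicted components but no
#'   detected tumor is a false-positive slice.
#' * `per_patient`: same rule at the case level.
#'
#' @param matches list of [match_instances()] results, one per case.
#' @param granularity one of `"per_tumor_volume"`, `"per_tumor_cut"`,
#'   `"per_slice"`, `"per_patient"`.
#' @return named list with `sensitivity`, `precision`, `f1`.
#' @export
detection_metrics <- function(matches, granularity = c("per_tumor_volume",
    "per_tumor_cut", "per_slice", "per_patient")) {
  granularity <- match.arg(granularity)
  if (inherits(matches, "case_matches")) matches <- list(matches)
  sens <- prec <- NA_real_
  if (granularity == "per_tumor_volume") {
    tp <- sum(vapply(matches, function(m) sum(m$ref_hits$detected), numeric(1)))
    fn <- sum(vapply(matches, function(m) sum(!m$ref_hits$detected), numeric(1)))
    fp <- sum(vapply(matches, function(m) sum(!m$pred_comps$matched), numeric(1)))
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  } else if (granularity == "per_tumor_cut") {
    sv <- vapply(matches, function(m) {
      n <- nrow(m$ref_hits)
      if (n == 0) NA_real_ else sum(m$ref_hits$detected) / n
    }, numeric(1))
    pv <- vapply(matches, function(m) {
      n <- nrow(m$pred_comps)
      if (n == 0) NA_real_ else sum(m$pred_comps$matched) / n
    }, numeric(1))
    sens <- mean(sv, na.rm = TRUE)
    prec <- mean(pv, na.rm = TRUE)
  } else if (granularity == "per_slice") {
    tp <- fn <- fp <- 0
    for (m in matches) {
      det_slices <- unique(m$ref_hits$slice[m$ref_hits$detected])
      tum_slices <- unique(m$ref_hits$slice)
      pred_slices <- unique(m$pred_comps$slice)
      tp <- tp + length(det_slices)
      fn <- fn + length(setdiff(tum_slices, det_slices))
      fp <- fp + length(setdiff(pred_slices, det_slices))
    }
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  } else {
    det <- vapply(matches, function(m) any(m$ref_hits$detected), logical(1))
    has_t <- vapply(matches, function(m) nrow(m$ref_hits) > 0, logical(1))
    has_p <- vapply(matches, function(m) nrow(m$pred_comps) > 0, logical(1))
    tp <- sum(det & has_t)
    fn <- sum(has_t & !det)
    fp <- sum(has_p & !det)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  }
  list(sensitivity = sens, precision = prec,
       f1 = if (is.na(sens) || is.na(prec)) NA_real_ else f1(sens, prec))
}

#' F1 score
#'
#' Harmonic mean `2SP / (S + P)` of sensitivity and precision; defined as 0
#' when both are 0.
#'
#' @param sensitivity,precision fractions in `[0, 1]`.
#' @export
f1 <- function(sensitivity, precision) {
  ifelse(sensitivity + precision == 0, 0,
         2 * sensitivity * precision / (sensitivity + precision))
}

# MTD -------------------------------------------------------------------------

# maximum tumor diameter of a labelled volume, in cm: the largest per-slice
# longest axis over all instances and slices, scaled by in-plane spacing
case_mtd_cm <- function(labels, spacing_mm) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(0)
  best <- 0
  for (s in seq_len(dim(labels)[1])) {
    sl <- labels[s, , ]
    for (id in unique(sl[sl > 0])) {
      ax <- longest_axis_px(which(sl == id, arr.ind = TRUE))
      if (ax > best) best <- ax
    }
  }
  px_to_cm(best, spacing_mm)
}

#' Mean absolute error of the maximum tumor diameter
#'
#' For each case, the maximum tumor diameter (MTD) is the largest per-slice
#' longest axis over all instances, converted to cm with the in-plane
#' spacing; the predicted volume is instance-labelled by 26-connectivity. The
#' MAE averages `|MTD_pred - MTD_ref|` over cases.
#'
#' @param pred_masks list of binary prediction volumes.
#' @param ref_labels list of reference instance volumes.
#' @param spacing_mm in-plane pixel spacing in mm.
#' @return MAE in cm.
#' @export
mtd_mae <- function(pred_masks, ref_labels, spacing_mm = 1.4) {
  stopifnot(length(pred_masks) == length(ref_labels))
  err <- vapply(seq_along(pred_masks), function(i) {
    r <- case_mtd_cm(ref_labels[[i]], spacing_mm)
    if (r == 0) stop2("case %d has no reference tumor", i)
    p <- case_mtd_cm(label_components(pred_masks[[i]] != 0), spacing_mm)
    abs(p - r)
  }, numeric(1))
  mean(err)
}

# stratified report -----------------------------------------------------------

size_bin_of <- function(mtd_cm) {
  # left-closed bins over reference MTD
  cut(mtd_cm, breaks = c(-Inf, 2, 3, 5, Inf), right = FALSE,
      labels = c("<2 cm", "2-3 cm", "3-5 cm", ">5 cm"))
}

#' Evaluate a cohort of segmented cases
#'
#' Computes the full metrics report: dice per case, dice global, MTD MAE, and
#' sensitivity/precision/F1 at all four granularities — overall and stratified
#' by reference-MTD size bin (`<2`, `2-3`, `3-5`, `>5` cm, left-closed) and by
#' tumor count (`1`, `>1`). Empty strata are reported with `n = 0`, not
#' errored.
#'
#' @param pred_masks list of binary prediction volumes, one per case.
#' @param ref_labels list of reference instance-label volumes.
#' @param spacing_mm in-plane spacing in mm (default 1.4).
#' @param theta detection overlap threshold (default 0.2).
#' @return an object of class `hfs_metrics_report`: a list of per-stratum
#'   metric blocks plus the per-case table.
#' @export
evaluate_cases <- function(pred_masks, ref_labels, spacing_mm = 1.4,
                           theta = 0.2) {
  stopifnot(length(pred_masks) == length(ref_labels))
  n <- length(pred_masks)
  if (n == 0) stop2("empty case list")
  matches <- lapply(seq_len(n), function(i)
    match_instances(pred_masks[[i]], ref_labels[[i]], theta))
  mtd <- vapply(ref_labels, case_mtd_cm, numeric(1), spacing_mm = spacing_mm)
  ntum <- vapply(ref_labels, function(r)
    length(unique(r[r > 0])), numeric(1))
  cases <- data.frame(
    case = seq_len(n),
    dice = mapply(function(p, r) dice(p != 0, r != 0), pred_masks, ref_labels),
    mtd_ref_cm = mtd,
    n_tumors = ntum,
    size_bin = size_bin_of(mtd),
    count_bin = factor(ifelse(ntum > 1, ">1", "1"), levels = c("1", ">1")))

  block <- function(idx) {
    if (length(idx) == 0)
      return(list(n = 0L))
    gran <- c("per_tumor_volume", "per_tumor_cut", "per_slice", "per_patient")
    det <- lapply(setNames(gran, gran), function(g)
      detection_metrics(matches[idx], g))
    list(n = length(idx),
         dice_per_case = dice_per_case(pred_masks[idx], ref_labels[idx]),
         dice_global = dice_global(pred_masks[idx],
                                   lapply(ref_labels[idx], function(r) r != 0)),
         mtd_mae_cm = if (all(mtd[idx] > 0))
           mtd_mae(pred_masks[idx], ref_labels[idx], spacing_mm) else NA_real_,
         detection = det)
  }

  by_size <- lapply(setNames(levels(cases$size_bin), levels(cases$size_bin)),
                    function(b) block(which(cases$size_bin == b)))
  by_count <- lapply(setNames(levels(cases$count_bin), levels(cases$count_bin)),
                     function(b) block(which(cases$count_bin == b)))
  structure(list(overall = block(seq_len(n)), by_size = by_size,
                 by_count = by_count, cases = cases, theta = theta,
                 spacing_mm = spacing_mm),
            class = "hfs_metrics_report")
}

#' @export
print.hfs_metrics_report <- function(x, digits = 3, ...) {
  cat("HFS-Net metrics report (theta =", x$theta, ")\n")
  ov <- x$overall
  cat(sprintf("  n=%d  dice per case %.1f%%  dice global %.1f%%  MTD MAE %.2f cm\n",
              ov$n, 100 * ov$dice_per_case, 100 * ov$dice_global, ov$mtd_mae_cm))
  for (g in names(ov$detection)) {
    d <- ov$detection[[g]]
    cat(sprintf("  %-17s S %.1f%%  P %.1f%%  F1 %.1f%%\n", g,
                100 * d$sensitivity, 100 * d$precision, 100 * d$f1))
  }
  invisible(x)
}
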