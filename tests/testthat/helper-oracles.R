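# Independent brute-force oracles for the evaluation metrics. These are
# deliberately naive (exhaustive voxel counting, exhaustive matching,
# all-pairs distances) and share no code with the package implementation.

bf_dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

bf_longest_axis <- function(px) {
  if (nrow(px) == 1) return(0)
  best <- 0
  for (i in seq_len(nrow(px) - 1))
    for (j in (i + 1):nrow(px)) {
      d <- sqrt(sum((px[i, ] - px[j, ])^2))
      if (d > best) best <- d
    }
  best
}

# 8-connectivity labelling by repeated flood fill (pure R)
bf_label2 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- v[1] + di; nj <- v[2] + dj
        if (ni < 1 || nj < 1 || ni > nrow(mask) || nj > ncol(mask)) next
        if (mask[ni, nj] && lab[ni, nj] == 0) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# per-slice greedy instance matching; returns per-case summaries equivalent
# to match_instances() but computed independently
bf_match_case <- function(pred, ref, theta = 0.2) {
  ns <- dim(ref)[1]
  ref_rows <- NULL; pred_rows <- NULL
  for (s in seq_len(ns)) {
    rs <- ref[s, , ]; ps <- pred[s, , ] != 0
    pl <- bf_label2(ps)
    rids <- sort(unique(rs[rs > 0]))
    npred <- max(pl)
    if (length(rids) == 0 && npred == 0) next
    pairs <- NULL
    if (length(rids) && npred) {
      for (ri in seq_along(rids)) for (pi in seq_len(npred))
        pairs <- rbind(pairs, c(ri, pi, bf_dice(pl == pi, rs == rids[ri])))
    }
    det <- rep(FALSE, length(rids)); mat <- rep(FALSE, npred)
    if (!is.null(pairs)) {
      pairs <- pairs[order(-pairs[, 3]), , drop = FALSE]
      used_r <- used_p <- integer()
      for (k in seq_len(nrow(pairs))) {
        if (pairs[k, 3] <= theta) break
        if (pairs[k, 1] %in% used_r || pairs[k, 2] %in% used_p) next
        det[pairs[k, 1]] <- TRUE; mat[pairs[k, 2]] <- TRUE
        used_r <- c(used_r, pairs[k, 1]); used_p <- c(used_p, pairs[k, 2])
      }
    }
    if (length(rids))
      ref_rows <- rbind(ref_rows, data.frame(slice = s, ref_id = rids,
                                             detected = det))
    if (npred)
      pred_rows <- rbind(pred_rows, data.frame(slice = s,
                                               comp = seq_len(npred),
                                               matched = mat))
  }
  list(ref = ref_rows %||%
         data.frame(slice = integer(), ref_id = integer(), detected = logical()),
       pred = pred_rows %||%
         data.frame(slice = integer(), comp = integer(), matched = logical()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bf_granularity <- function(case_matches, granularity) {
  if (granularity == "per_tumor_volume") {
    tp <- sum(sapply(case_matches, function(m) sum(m$ref$detected)))
    fn <- sum(sapply(case_matches, function(m) sum(!m$ref$detected)))
    fp <- sum(sapply(case_matches, function(m) sum(!m$pred$matched)))
    c(sens = tp / (tp + fn), prec = tp / (tp + fp))
  } else if (granularity == "per_tumor_cut") {
    sv <- sapply(case_matches, function(m)
      if (nrow(m$ref)) mean(m$ref$detected) else NA)
    pv <- sapply(case_matches, function(m)
      if (nrow(m$pred)) mean(m$pred$matched) else NA)
    c(sens = mean(sv, na.rm = TRUE), prec = mean(pv, na.rm = TRUE))
  } else if (granularity == "per_slice") {
    tp <- fn <- fp <- 0
    for (m in case_matches) {
      ds <- unique(m$ref$slice[m$ref$detected])
      ts <- unique(m$ref$slice)
      pp <- unique(m$pred$slice)
      tp <- tp + length(ds)
      fn <- fn + length(setdiff(ts, ds))
      fp <- fp + length(setdiff(pp, ds))
    }
    c(sens = tp / (tp + fn), prec = tp / (tp + fp))
  } else {
    det <- sapply(case_matches, function(m) any(m$ref$detected))
    ht <- sapply(case_matches, function(m) nrow(m$ref) > 0)
    hp <- sapply(case_matches, function(m) nrow(m$pred) > 0)
    tp <- sum(det & ht); fn <- sum(ht & !det); fp <- sum(hp & !det)
    c(sens = tp / (tp + fn), prec = tp / (tp + fp))
  }
}

# random paired labelings: a few elliptical blobs per volume, prediction is a
# jittered copy of the reference plus occasional spurious blobs
random_labeling_pair <- function(seed, shape = c(4, 16, 16)) {
  set.seed(seed)
  ref <- array(0L, shape); pred <- array(0L, shape)
  n <- sample(0:3, 1)
  id <- 0L
  for (k in seq_len(n)) {
    id <- id + 1L
    ctr <- c(sample(shape[1], 1), sample(3:(shape[2] - 2), 1),
             sample(3:(shape[3] - 2), 1))
    r <- runif(1, 1, 3.5)
    zr <- sample(0:1, 1)
    for (s in max(1, ctr[1] - zr):min(shape[1], ctr[1] + zr))
      for (i in seq_len(shape[2])) for (j in seq_len(shape[3]))
        if ((i - ctr[2])^2 + (j - ctr[3])^2 <= r^2) ref[s, i, j] <- id
    off <- sample(-2:2, 2, replace = TRUE)
    for (s in max(1, ctr[1] - zr):min(shape[1], ctr[1] + zr))
      for (i in seq_len(shape[2])) for (j in seq_len(shape[3])) {
        ii <- i - off[1]; jj <- j - off[2]
        if (ii >= 1 && jj >= 1 && ii <= shape[2] && jj <= shape[3] &&
            (ii - ctr[2])^2 + (jj - ctr[3])^2 <= (r * runif(1, 0.8, 1.2))^2)
          pred[s, i, j] <- 1L
      }
  }
  if (runif(1) < 0.3) {
    ctr <- c(sample(shape[1], 1), sample(shape[2], 1), sample(shape[3], 1))
    pred[ctr[1], ctr[2], ctr[3]] <- 1L
  }
  list(pred = pred, ref = ref)
}
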