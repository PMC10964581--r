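test_that("dice handles identity, disjoint, partial overlap and empties", {
  a <- array(0, c(2, 4, 4)); a[1, 1:2, 1:2] <- 1
  expect_equal(dice(a, a), 1)
  b <- array(0, c(2, 4, 4)); b[2, 3:4, 3:4] <- 1
  expect_equal(dice(a, b), 0)
  # |A| = 4, |B| = 2, overlap 2
  b2 <- array(0, c(2, 4, 4)); b2[1, 1:2, 1] <- 1
  expect_equal(dice(a, b2), 2 * 2 / (4 + 2), tolerance = 1e-12)
  expect_equal(dice(a * 0, b * 0), 1)
  expect_error(dice(a, array(0, c(2, 4, 5))), "shape")
  # symmetry
  expect_equal(dice(a, b2), dice(b2, a))
  # jaccard relation d/(2-d)
  expect_equal(jaccard(a, b2), (2 / 3) / (2 - 2 / 3), tolerance = 1e-12)
})

test_that("dice per case averages and dice global pools", {
  mk <- function(n) { x <- array(0, c(1, 4, 4)); x[1, seq_len(n), 1] <- 1; x }
  # case 1: |A|=4, |B|=2, overlap 2; case 2: identical masks of 10 voxels
  a1 <- array(0, c(1, 4, 4)); a1[1, 1, 1:4] <- 1
  b1 <- array(0, c(1, 4, 4)); b1[1, 1, 1:2] <- 1
  big <- array(0, c(1, 4, 4)); big[1, 2:3, 1:4] <- 1; big[1, 4, 1:2] <- 1
  expect_equal(dice_per_case(list(a1, big), list(b1, big)),
               mean(c(2 / 3, 1)))
  expect_equal(dice_global(list(a1, big), list(b1, big)),
               2 * 12 / (14 + 12), tolerance = 1e-12)
  # single case: global equals per-case dice
  expect_equal(dice_global(list(a1), list(b1)), dice(a1, b1))
  # the two statistics differ in general
  expect_false(isTRUE(all.equal(dice_per_case(list(a1, big), list(b1, big)),
                                dice_global(list(a1, big), list(b1, big)))))
  expect_error(dice_global(list(), list()), "empty")
})

test_that("longest axis measures collinear runs, squares and single pixels", {
  expect_equal(longest_axis_px(cbind(1, 1)), 0)
  expect_equal(longest_axis_px(cbind(5, 10:40)), 30)
  sq <- as.matrix(expand.grid(1:5, 1:5))
  expect_equal(longest_axis_px(sq), 4 * sqrt(2), tolerance = 1e-12)
  expect_equal(longest_axis_px(sq), bf_longest_axis(sq), tolerance = 1e-12)
  expect_error(longest_axis_px(matrix(0, 0, 2)), "empty")
  # convex-hull path agrees with all-pairs on a large blob
  set.seed(8)
  blob <- which(matrix(runif(40 * 40), 40, 40) < 0.4, arr.ind = TRUE)
  expect_equal(longest_axis_px(blob), bf_longest_axis(blob), tolerance = 1e-9)
})

test_that("instance matching applies the theta rule and greedy best-dice pairing", {
  # one ref instance, one pred component, overlap dice 0.25 > theta = 0.2
  ref <- array(0L, c(1, 6, 6)); ref[1, 1:2, 1:2] <- 1L   # 4 px
  pred <- array(0L, c(1, 6, 6)); pred[1, 2:3, 2:3] <- 1L # 4 px, overlap 1
  m <- match_instances(pred, ref, theta = 0.2)
  expect_equal(m$ref_hits$best_dice, 0.25)
  expect_true(m$ref_hits$detected)
  expect_true(all(m$pred_comps$matched))
  # below threshold: FN for the ref, FP for the pred
  m2 <- match_instances(pred, ref, theta = 0.3)
  expect_false(m2$ref_hits$detected)
  expect_false(any(m2$pred_comps$matched))
  # two refs, one pred overlapping both above theta: matched to the
  # higher-dice ref, the other ref is a FN
  ref2 <- array(0L, c(1, 6, 6))
  ref2[1, 1, 1:2] <- 1L       # small ref (2 px)
  ref2[1, 3:4, 1:3] <- 2L     # larger ref (6 px)
  pred2 <- array(0L, c(1, 6, 6)); pred2[1, 1:4, 1:2] <- 1L  # 8 px touches both
  m3 <- match_instances(pred2, ref2, theta = 0.2)
  hit <- m3$ref_hits[order(m3$ref_hits$ref_id), ]
  d1 <- 2 * 2 / (8 + 2); d2 <- 2 * 4 / (8 + 6)
  expect_equal(hit$best_dice, c(d1, d2), tolerance = 1e-12)
  expect_equal(hit$detected, c(d1 > d2, d2 >= d1))
  expect_error(match_instances(pred, ref, theta = 1.2), "theta")
})

test_that("granularity metrics reproduce hand enumerations", {
  mk_case <- function(det_by_slice) {
    # det_by_slice: list slice -> logical vector of instance detections
    ref_hits <- do.call(rbind, lapply(seq_along(det_by_slice), function(s) {
      d <- det_by_slice[[s]]
      if (length(d) == 0) return(NULL)
      data.frame(slice = s, ref_id = seq_along(d), detected = d,
                 best_dice = ifelse(d, 0.5, 0), axis_px = 5)
    }))
    pred_comps <- do.call(rbind, lapply(seq_along(det_by_slice), function(s) {
      d <- det_by_slice[[s]]
      if (!any(d)) return(NULL)
      data.frame(slice = s, comp = seq_len(sum(d)), matched = TRUE)
    }))
    structure(list(ref_hits = ref_hits %||% data.frame(
      slice = integer(), ref_id = integer(), detected = logical(),
      best_dice = numeric(), axis_px = numeric()),
      pred_comps = pred_comps %||% data.frame(
        slice = integer(), comp = integer(), matched = logical()),
      n_slices = length(det_by_slice), theta = 0.2), class = "case_matches")
  }
  # 1 case, 2 slices: slice 1 detected, slice 2 missed
  c1 <- mk_case(list(TRUE, FALSE))
  expect_equal(detection_metrics(list(c1), "per_slice")$sensitivity, 0.5)
  expect_equal(detection_metrics(list(c1), "per_patient")$sensitivity, 1.0)
  # case A: 10 instances all detected; case B: 10 instances none detected
  cA <- mk_case(list(rep(TRUE, 10)))
  cB <- mk_case(list(rep(FALSE, 10)))
  expect_equal(detection_metrics(list(cA, cB), "per_tumor_volume")$sensitivity, 0.5)
  expect_equal(detection_metrics(list(cA, cB), "per_tumor_cut")$sensitivity, 0.5)
  # adding case C with 1/1 detected separates the two granularities
  cC <- mk_case(list(TRUE))
  expect_equal(detection_metrics(list(cA, cB, cC), "per_tumor_volume")$sensitivity,
               11 / 21, tolerance = 1e-12)
  expect_equal(detection_metrics(list(cA, cB, cC), "per_tumor_cut")$sensitivity,
               2 / 3, tolerance = 1e-12)
})

test_that("f1 is the harmonic mean with the degenerate case at zero", {
  expect_equal(f1(0.5, 0.5), 0.5)
  expect_equal(f1(0, 0), 0)
  expect_equal(f1(0.922, 0.932), 2 * 0.922 * 0.932 / (0.922 + 0.932),
               tolerance = 1e-12)
  expect_equal(round(100 * f1(0.727, 0.774), 1), 75.0)
})

test_that("MTD MAE measures per-case maximum diameter differences in cm", {
  # ref: 31-px horizontal run at 1.4 mm/px -> 30 px -> 4.2 cm
  ref <- array(0L, c(2, 40, 40)); ref[1, 20, 5:35] <- 1L
  pred_same <- array(as.integer(ref > 0), dim(ref))
  expect_equal(mtd_mae(list(pred_same), list(ref)), 0)
  # pred finds only a 11-px run (10 px axis = 1.4 cm); ref MTD 4.2 cm
  pred <- array(0L, c(2, 40, 40)); pred[1, 20, 5:15] <- 1L
  expect_equal(mtd_mae(list(pred), list(ref)), 4.2 - 1.4, tolerance = 1e-9)
  expect_error(mtd_mae(list(pred), list(ref * 0L)), "no reference tumor")
})

test_that("stratified evaluation uses left-closed size bins and flags empty strata", {
  # boundary rule is left-closed: an MTD of exactly 2.0 cm is "2-3 cm"
  expect_equal(as.character(hfsnet:::size_bin_of(2.0)), "2-3 cm")
  expect_equal(as.character(hfsnet:::size_bin_of(5.0)), ">5 cm")
  expect_equal(as.character(hfsnet:::size_bin_of(1.99)), "<2 cm")
  mk_run <- function(px) {
    r <- array(0L, c(2, 64, 64)); r[1, 30, 10:(10 + px)] <- 1L; r
  }
  ref1 <- mk_run(15)                     # 2.1 cm MTD
  ref2 <- mk_run(10)                     # 1.4 cm MTD
  rep <- evaluate_cases(list(ref1, ref2), list(ref1, ref2))
  expect_equal(as.character(rep$cases$size_bin), c("2-3 cm", "<2 cm"))
  ns <- sapply(rep$by_size, `[[`, "n")
  expect_equal(sum(ns), 2)
  # single-tumor cohort: the >1 stratum is empty but present
  expect_equal(rep$by_count[[">1"]]$n, 0)
  # perfect predictions: all four sensitivities 1, dice 1
  expect_equal(rep$overall$dice_global, 1)
  for (g in names(rep$overall$detection))
    expect_equal(rep$overall$detection[[g]]$sensitivity, 1)
})

test_that("all metrics agree with brute-force oracles on random volumes", {
  n_vol <- 50
  pairs <- lapply(seq_len(n_vol), function(s) random_labeling_pair(1000 + s))
  preds <- lapply(pairs, `[[`, "pred")
  refs <- lapply(pairs, `[[`, "ref")
  # dice per case / global
  bf_percase <- mean(mapply(bf_dice, preds, refs))
  bf_glob <- {
    i <- sum(mapply(function(p, r) sum(p != 0 & r != 0), preds, refs))
    a <- sum(sapply(preds, function(p) sum(p != 0)))
    b <- sum(sapply(refs, function(r) sum(r != 0)))
    2 * i / (a + b)
  }
  expect_equal(dice_per_case(preds, refs), bf_percase, tolerance = 1e-9)
  expect_equal(dice_global(preds, refs), bf_glob, tolerance = 1e-9)
  # instance matching and every granularity
  m_pkg <- lapply(seq_len(n_vol), function(i)
    match_instances(preds[[i]], refs[[i]], theta = 0.2))
  m_bf <- lapply(seq_len(n_vol), function(i)
    bf_match_case(preds[[i]], refs[[i]], theta = 0.2))
  for (g in c("per_tumor_volume", "per_tumor_cut", "per_slice", "per_patient")) {
    got <- detection_metrics(m_pkg, g)
    want <- bf_granularity(m_bf, g)
    expect_equal(got$sensitivity, unname(want["sens"]), tolerance = 1e-9,
                 label = paste(g, "sensitivity"))
    expect_equal(got$precision, unname(want["prec"]), tolerance = 1e-9,
                 label = paste(g, "precision"))
  }
  # longest axis on every ref component of every slice
  for (i in seq_len(10)) {
    r <- refs[[i]]
    for (s in seq_len(dim(r)[1])) {
      sl <- r[s, , ]
      for (id in unique(sl[sl > 0])) {
        px <- which(sl == id, arr.ind = TRUE)
        expect_equal(longest_axis_px(px), bf_longest_axis(px),
                     tolerance = 1e-9)
      }
    }
  }
})
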