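test_that("a tumor-free spec yields an empty label volume inside a liver", {
  cs <- generate_case(phantom_spec(numeric(), profile = "tiny", seed = 3))
  expect_true(all(cs$tumor_labels == 0))
  expect_gt(sum(cs$liver_mask), 0)
  expect_equal(nrow(cs$manifest), 0)
})

test_that("generation is deterministic given the spec", {
  sp <- phantom_spec(c(2.5, 1.2), profile = "tiny", seed = 21)
  a <- generate_case(sp)
  b <- generate_case(sp)
  expect_identical(a$tumor_labels, b$tumor_labels)
  expect_identical(a$liver_mask, b$liver_mask)
  expect_identical(a$volume$phases, b$volume$phases)
})

test_that("generated lesions hit the requested maximum in-plane diameter", {
  # 2.0 cm at 1.4 mm/px is ~14.3 px; the measured longest in-plane axis of
  # the voxelized lesion must land within one pixel
  cs <- generate_case(phantom_spec(2.0, profile = "tiny", seed = 5))
  vox <- which(cs$tumor_labels == 1L, arr.ind = TRUE)
  ax <- 0
  for (s in unique(vox[, 1])) {
    px <- vox[vox[, 1] == s, 2:3, drop = FALSE]
    ax <- max(ax, bf_longest_axis(px))
  }
  expect_lt(abs(ax - 2.0 / 0.14), 1 + 1e-9)
  # and across a range of sizes and seeds, via the package self-check
  for (seed in 1:4) {
    chk <- self_check_case(generate_case(
      phantom_spec(c(1.5, 3.6), profile = "tiny", seed = seed)))
    expect_true(all(chk$axis_ok))
    expect_true(all(chk$inside_liver_ok))
    expect_true(attr(chk, "ids_consecutive"))
  }
})

test_that("tumors lie inside the liver and phases show the HCC pattern", {
  cs <- generate_case(phantom_spec(c(3.0, 1.5), profile = "tiny", seed = 13))
  expect_equal(sum(cs$tumor_labels > 0 & !cs$liver_mask), 0)
  les <- cs$tumor_labels > 0
  liv <- cs$liver_mask & !les
  art <- cs$volume$phases$arterial
  pv <- cs$volume$phases$portal_venous
  expect_gt(mean(art[les]), mean(art[liv]))  # arterial hyperenhancement
  expect_lt(mean(pv[les]), mean(pv[liv]))    # portal-venous washout
})

test_that("an oversized lesion triggers an explicit placement error", {
  expect_error(generate_case(phantom_spec(12, profile = "tiny", seed = 1)),
               "12\\.00 cm")
})

test_that("the self check flags a tumor voxel moved outside the liver", {
  cs <- generate_case(phantom_spec(2.5, profile = "tiny", seed = 9))
  out_vox <- which(!cs$liver_mask & cs$tumor_labels == 0, arr.ind = TRUE)
  corner <- out_vox[1, ]
  cs$tumor_labels[corner[1], corner[2], corner[3]] <- 1L
  chk <- self_check_case(cs)
  expect_false(chk$inside_liver_ok[chk$id == 1])
  expect_gt(chk$voxels_outside_liver[chk$id == 1], 0)
})

test_that("a voxelized sphere measures its analytic diameter", {
  # sphere of radius 10 px -> reported in-plane axis 20 px (within 1)
  shape <- c(8L, 32L, 32L)
  lab <- array(0L, shape)
  for (i in 1:32) for (j in 1:32)
    if ((i - 16.3)^2 + (j - 16.3)^2 <= 100) lab[4, i, j] <- 1L
  px <- which(lab[4, , ] == 1L, arr.ind = TRUE)
  expect_lt(abs(longest_axis_px(px) - 20), 1 + 1e-9)
})

test_that("cohort manifests follow the size mixture and tumor-count model", {
  # degenerate mixture: every case in the smallest bin
  man <- draw_cohort_manifest(10, size_mixture = c(1, 0, 0, 0), seed = 2)
  expect_true(all(man$diameter_cm < 2))
  # n = 1: manifest has exactly that case's tumors
  man1 <- draw_cohort_manifest(1, seed = 5)
  expect_true(all(man1$case == 1))
  expect_equal(nrow(man1), max(man1$tumor))
  expect_error(draw_cohort_manifest(0), "positive")
  expect_error(draw_cohort_manifest(5, size_mixture = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  # default mixture at n = 100: per-case primary-size bin counts inside the
  # binomial 99% interval of (15.6%, 22.4%, 29.9%, 32.1%)
  man <- draw_cohort_manifest(100, seed = 3)
  prim <- man[man$tumor == 1, ]
  p <- default_size_mixture()
  cnt <- table(factor(prim$bin, levels = names(p)))
  for (k in seq_along(p)) {
    expect_gte(as.integer(cnt[k]), qbinom(0.005, 100, p[k]))
    expect_lte(as.integer(cnt[k]), qbinom(0.995, 100, p[k]))
  }
  # single-tumor fraction near 84%
  single <- mean(tapply(man$tumor, man$case, max) == 1)
  expect_gt(single, 0.84 - 3 * sqrt(0.84 * 0.16 / 100))
  expect_lt(single, 0.84 + 3 * sqrt(0.84 * 0.16 / 100))
})

test_that("rendered cohorts respect their manifests", {
  coh <- generate_cohort(3, seed = 17)
  expect_length(coh$cases, 3)
  for (i in 1:3) {
    cs <- coh$cases[[i]]
    man_i <- coh$manifest[coh$manifest$case == i, ]
    expect_equal(nrow(cs$manifest), nrow(man_i))
    expect_equal(sort(cs$manifest$diameter_cm), sort(man_i$diameter_cm))
    chk <- self_check_case(cs)
    expect_true(all(chk$inside_liver_ok))
  }
})
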