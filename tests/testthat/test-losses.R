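# random normalized probability array + integer target of matching shape
rand_probs <- function(shape, K = 2, seed = 1) {
  set.seed(seed)
  z <- array(rnorm(prod(shape) * K), c(shape, K))
  n <- prod(shape)
  zm <- matrix(z, n, K)
  e <- exp(zm - apply(zm, 1, max))
  list(probs = array(e / rowSums(e), c(shape, K)),
       target = array(sample.int(K, n, replace = TRUE), shape))
}

test_that("cross entropy matches closed forms and hand computations", {
  p <- array(0.5, c(3, 3, 2))
  expect_equal(cross_entropy(p, matrix(1L, 3, 3)), log(2), tolerance = 1e-9)

  # perfect one-hot prediction: zero up to the epsilon clamp
  hot <- array(0, c(2, 2, 2)); hot[, , 2] <- 1
  expect_lt(cross_entropy(hot, matrix(2L, 2, 2)), 1e-6)

  # two voxels with p(true) = 0.5 and 0.25
  p2 <- array(c(0.5, 0.25, 0.5, 0.75), c(2, 1, 2))
  expect_equal(cross_entropy(p2, matrix(1L, 2, 1)),
               -(log(0.5) + log(0.25)) / 2, tolerance = 1e-9)
})

test_that("dice loss matches closed forms and a set-arithmetic oracle", {
  hot <- array(0, c(4, 4, 2)); hot[, , 2] <- 1
  expect_lt(dice_loss(hot, matrix(2L, 4, 4)), 0.05)

  # disjoint hard prediction vs target
  p <- array(0, c(2, 2, 2)); p[, , 2] <- c(1, 0, 0, 0); p[, , 1] <- 1 - p[, , 2]
  t <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  expect_gt(dice_loss(p, t), 0.6)

  # probs 0.5 everywhere on an all-foreground target: 1 - 2*0.5/(0.5+1) = 1/3
  pc <- array(0.5, c(64, 64, 2))
  expect_equal(dice_loss(pc, matrix(2L, 64, 64)), 1 / 3, tolerance = 1e-3)

  # hard 0/1 predictions agree with 1 - bf_dice to within smoothing
  set.seed(5)
  for (i in 1:10) {
    m1 <- matrix(runif(16 * 16) < 0.3, 16, 16)
    m2 <- matrix(runif(16 * 16) < 0.3, 16, 16)
    p <- array(0, c(16, 16, 2)); p[, , 2] <- m1; p[, , 1] <- 1 - m1
    t <- matrix(ifelse(m2, 2L, 1L), 16, 16)
    smooth_free <- dice_loss(p, t, smooth = 1e-12)
    expect_equal(smooth_free, 1 - bf_dice(m1, m2), tolerance = 1e-6)
  }
})

test_that("focal loss generalizes cross entropy and matches hand values", {
  # gamma = 0 identity on random tensors
  for (s in 1:5) {
    rp <- rand_probs(c(6, 6), seed = s)
    expect_equal(focal_loss(rp$probs, rp$target, gamma = 0),
                 cross_entropy(rp$probs, rp$target), tolerance = 1e-6)
  }
  # p_t = 1 everywhere -> 0
  hot <- array(0, c(2, 2, 2)); hot[, , 1] <- 1
  expect_lt(focal_loss(hot, matrix(1L, 2, 2), gamma = 2), 1e-6)
  # single voxel, p_t = 0.5, gamma = 2: 0.25 * ln 2
  p1 <- array(0.5, c(1, 1, 2))
  expect_equal(focal_loss(p1, matrix(2L, 1, 1), gamma = 2), 0.25 * log(2),
               tolerance = 1e-9)
  expect_error(focal_loss(p1, matrix(2L, 1, 1), gamma = -1), "gamma")
})

test_that("median-frequency-balance weights follow the median/frequency rule", {
  expect_equal(mfb_weights(c(0.9, 0.1)), c(0.5 / 0.9, 5), tolerance = 1e-9)
  expect_equal(mfb_weights(c(0.5, 0.5)), c(1, 1))
  expect_equal(mfb_weights(c(0.6, 0.3, 0.1)), c(0.5, 1, 3), tolerance = 1e-9)
  expect_error(mfb_weights(c(0.9, 0.1, 0)), "absent")
})

test_that("compound losses are weighted sums with working identities", {
  rp <- rand_probs(c(8, 8), seed = 3)
  expect_equal(compound_loss(loss_spec("ce"), rp$probs, rp$target),
               cross_entropy(rp$probs, rp$target))
  # {focal, dice} at gamma 0 equals {ce, dice}
  expect_equal(
    compound_loss(loss_spec("focal+dice", focal_gamma = 0), rp$probs, rp$target),
    compound_loss(loss_spec("ce+dice"), rp$probs, rp$target),
    tolerance = 1e-6)
  # perfect prediction: ce+dice near zero
  hot <- array(0, c(4, 4, 2)); hot[, , 2] <- 1
  expect_lt(compound_loss(loss_spec("ce+dice"), hot, matrix(2L, 4, 4)), 0.05)
  expect_error(loss_spec("boundary"), "unknown")
  expect_error(loss_spec(character()), "at least one")
})

test_that("loss gradients agree with finite differences", {
  rp <- rand_probs(c(5, 5), seed = 11)
  for (spec in list(loss_spec("ce"), loss_spec("dice"),
                    loss_spec("focal", focal_gamma = 2),
                    loss_spec("mfb_focal", class_weights = c(0.6, 3)))) {
    lg <- compound_loss(spec, rp$probs, rp$target, grad = TRUE)
    eps <- 1e-6
    set.seed(2)
    for (t in 1:5) {
      i <- sample(length(rp$probs), 1)
      p2 <- rp$probs; p2[i] <- p2[i] + eps
      num <- (compound_loss(spec, p2, rp$target) - lg$value) / eps
      expect_equal(num, lg$grad[i], tolerance = 1e-3)
    }
  }
})
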