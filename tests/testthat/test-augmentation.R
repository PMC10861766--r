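test_that("same-label mixing is an exact convex combination", {
  set.seed(31)
  x1 <- array(stats::rnorm(40), c(4, 10))
  x2 <- array(stats::rnorm(40), c(4, 10))
  expect_identical(mix_same_label(x1, x2, 1), x1)
  expect_identical(mix_same_label(x1, x2, 0), x2)
  expect_equal(mix_same_label(x1, -x1, 0.5), array(0, c(4, 10)))
  # output stays in the elementwise interval hull
  w <- 0.37
  m <- mix_same_label(x1, x2, w)
  expect_true(all(m >= pmin(x1, x2) - 1e-12 & m <= pmax(x1, x2) + 1e-12))
  expect_error(mix_same_label(x1, x2, 0.5, label1 = 0, label2 = 1),
               "label")
  expect_error(mix_same_label(x1, array(0, c(4, 9)), 0.5), "shape")
})

test_that("additive noise has the declared amplitude and seeding", {
  x <- array(0, c(10, 10))
  expect_identical(add_noise(x, 0), x)
  big <- add_noise(array(0, c(1000, 100)), 0.2, seed = 5)
  expect_lt(abs(stats::sd(big) / 0.2 - 1), 0.02)  # 1e5 draws, within 2%
  expect_identical(add_noise(x, 0.1, seed = 9), add_noise(x, 0.1, seed = 9))
  expect_error(add_noise(x, -0.1), "nonnegative")
})

test_that("amplitude scaling is multiplicative and invertible", {
  set.seed(32)
  x <- array(stats::rnorm(60), c(6, 10))
  expect_identical(scale_signal(x, 1), x)
  expect_equal(scale_signal(scale_signal(x, 0.8), 1.25), x,
               tolerance = 1e-12)
  # scaling commutes with mixing (linearity)
  x2 <- array(stats::rnorm(60), c(6, 10))
  expect_equal(scale_signal(mix_same_label(x, x2, 0.3), 1.1),
               mix_same_label(scale_signal(x, 1.1),
                              scale_signal(x2, 1.1), 0.3),
               tolerance = 1e-12)
  expect_error(scale_signal(x, 0), "positive")
})

test_that("batch augmentation preserves labels and batch size", {
  set.seed(33)
  x <- array(stats::rnorm(8 * 3 * 20), c(8, 3, 20))
  labels <- rep(0:1, each = 4)
  # degenerate parameter ranges: the batch passes through unchanged
  pdeg <- augment_params(w_range = c(1, 1), noise_level_range = c(0, 0),
                         scale_range = c(1, 1))
  out <- augment_batch(x, labels, pdeg)
  expect_equal(out$data, x, tolerance = 1e-12)
  expect_identical(out$labels, labels)
  # label invariance and size invariance in general
  p <- augment_params(seed = 17)
  out2 <- augment_batch(x, labels, p)
  expect_identical(out2$labels, labels)
  expect_identical(dim(out2$data), dim(x))
  # seeded reproducibility of the full pipeline
  expect_identical(augment_batch(x, labels, augment_params(seed = 17)),
                   augment_batch(x, labels, augment_params(seed = 17)))
  # singleton class: mixing skipped with a warning
  expect_warning(augment_batch(x[1:3, , , drop = FALSE], c(0L, 0L, 1L),
                               augment_params(seed = 1)), "single")
})

test_that("augmentation preserves class-conditional means", {
  set.seed(34)
  B <- 100L
  x <- array(stats::rnorm(B * 2 * 20), c(B, 2, 20))
  labels <- rep(0:1, each = B / 2)
  # scale fixed at 1 (the scale range is only mean-one at its midpoint)
  p <- augment_params(scale_range = c(1, 1), seed = 55)
  acc <- 0
  reps <- 100L  # 1e4 augmented trial draws in total
  for (r in seq_len(reps)) {
    acc <- acc + augment_batch(x, labels, augment_params(
      scale_range = c(1, 1), seed = 1000L + r))$data
  }
  avg <- acc / reps
  for (k in 0:1) {
    src <- apply(x[labels == k, , , drop = FALSE], c(2, 3), mean)
    aug <- apply(avg[labels == k, , , drop = FALSE], c(2, 3), mean)
    expect_lt(max(abs(src - aug)), 0.05)
  }
})
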