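test_that("temporal kernel length rounds F_s/4 to the nearest power of two", {
  expect_identical(temporal_kernel_length(250), 64L)
  expect_identical(temporal_kernel_length(128), 32L)
  expect_identical(temporal_kernel_length(512), 128L)
  # exact tie (192/4 = 48 is equidistant from 32 and 64): rounds upward
  expect_identical(temporal_kernel_length(192), 64L)
  expect_error(temporal_kernel_length(0), "positive")
  expect_error(temporal_kernel_length(-250), "positive")
})

test_that("temporal convolution preserves length and locality", {
  x <- tiny_trials(B = 2L, C = 3L, T_ = 200L)
  y <- temporal_conv(x, f1 = 4L, kernel = 64L)
  expect_equal(dim(y), c(2L, 4L, 3L, 200L))
  # zero input stays zero (batch-norm shift is zero)
  expect_equal(temporal_conv(array(0, c(1, 2, 100)), f1 = 4L, kernel = 64L),
               array(0, c(1, 4, 2, 100)))
  # impulse response support: same-padded kernel 64 reaches [k-32, k+31]
  xi <- array(0, c(1, 1, 200))
  k0 <- 100L
  xi[1, 1, k0] <- 1
  yi <- temporal_conv(xi, f1 = 2L, kernel = 64L, seed = 3L)
  nz <- which(apply(abs(yi[1, , 1, ]) > 1e-12, 2, any))
  expect_true(all(nz >= k0 - 32 & nz <= k0 + 31))
  expect_error(temporal_conv(array(0, c(1, 1, 10)), kernel = 64L),
               "shorter")
})

test_that("depthwise electrode stage collapses channels and pools time", {
  x <- array(abs(stats::rnorm(2 * 4 * 3 * 64)), c(2, 4, 3, 64))
  y <- depthwise_spatial_conv(x, depth_mult = 2L, pool = 8L)
  expect_equal(dim(y), c(2L, 8L, 1L, 8L))
  # constant-in-time positive input -> constant-in-time output
  xc <- array(rep(abs(stats::rnorm(2 * 4 * 3)), times = 64),
              c(2, 4, 3, 64))
  yc <- depthwise_spatial_conv(xc, depth_mult = 2L, pool = 8L)
  expect_lt(max(apply(yc, c(1, 2, 3), function(v) diff(range(v)))), 1e-12)
})

test_that("the full-scale encoder front yields the 140/70/35 pyramid", {
  x <- tiny_trials(B = 1L, C = 22L, T_ = 1125L)
  dims <- dim(temporal_conv(x, f1 = 16L, kernel = 64L,
                            sampling_rate = 250))
  expect_equal(dims, c(1L, 16L, 22L, 1125L))
  z <- encode(x, encoder_config())
  expect_equal(vapply(z, function(a) dim(a)[2], numeric(1)),
               c(140, 70, 35), ignore_attr = TRUE)
  expect_true(all(vapply(z, function(a) dim(a)[3], numeric(1)) == 32))
})

test_that("CBAM attention weights act multiplicatively in (0,1)", {
  set.seed(5)
  x <- array(stats::rnorm(2 * 8 * 30), c(2, 8, 30))
  # all-zero weights: every sigmoid is 0.5, output = 0.25 * x
  w0 <- list(mlp1 = matrix(0, 2, 8), mlp2 = matrix(0, 8, 2),
             sp = array(0, c(1, 2, 7)), sp_b = 0)
  expect_equal(cbam_attention(x, reduction = 4L, weights = w0), 0.25 * x,
               tolerance = 1e-12)
  # shape preservation, including the singleton-plane form
  y <- cbam_attention(x, reduction = 4L)
  expect_equal(dim(y), dim(x))
  x4 <- array(x, c(2, 8, 1, 30))
  expect_equal(dim(cbam_attention(x4, reduction = 4L)), dim(x4))
})

test_that("CBAM matches a straight-line oracle reimplementation", {
  set.seed(6)
  d <- 8L; B <- 2L; T_ <- 20L
  x <- array(stats::rnorm(B * d * T_), c(B, d, T_))
  w <- list(mlp1 = matrix(stats::rnorm(2 * d, 0, 0.5), 2, d),
            mlp2 = matrix(stats::rnorm(d * 2, 0, 0.5), d, 2),
            sp = array(stats::rnorm(14, 0, 0.5), c(1, 2, 7)),
            sp_b = 0.3)
  got <- cbam_attention(x, reduction = 4L, weights = w)
  sig <- function(v) 1 / (1 + exp(-v))
  for (b in seq_len(B)) {
    xb <- x[b, , ]                       # d x T
    avg <- rowMeans(xb); mx <- apply(xb, 1, max)
    mlp <- function(v) w$mlp2 %*% pmax(w$mlp1 %*% v, 0)
    cw <- sig(mlp(avg) + mlp(mx))
    expect_true(all(cw > 0 & cw < 1))
    x1 <- xb * as.vector(cw)
    sp_in <- rbind(colMeans(x1), apply(x1, 2, max))  # 2 x T
    K <- 7L; pl <- 3L
    sw <- numeric(T_)
    for (t in seq_len(T_)) {
      acc <- w$sp_b
      for (k in seq_len(K)) {
        t0 <- t - pl + k - 1L
        if (t0 >= 1 && t0 <= T_) acc <- acc + sum(w$sp[1, , k] * sp_in[, t0])
      }
      sw[t] <- sig(acc)
    }
    oracle <- x1 * rep(sw, each = d)
    expect_equal(got[b, , ], oracle, tolerance = 1e-10)
  }
})

test_that("later temporal stages pool by two with sigmoid-bounded output", {
  set.seed(7)
  x <- array(stats::rnorm(2 * 8 * 140), c(2, 8, 140))
  y1 <- spatial_conv_stage(x, kernel = 16L, pool = 2L)
  expect_equal(dim(y1)[3], 70L)
  y2 <- spatial_conv_stage(y1, kernel = 16L, pool = 2L)
  expect_equal(dim(y2)[3], 35L)
  expect_true(all(y1 > 0 & y1 < 1))
  x7 <- array(stats::rnorm(1 * 8 * 7), c(1, 8, 7))
  expect_equal(dim(spatial_conv_stage(x7, pool = 2L))[3], 3L)
})

test_that("fast-normalized fusion is a convex combination", {
  w <- c(0.3, 1.2, -0.5)
  co <- fusion_coefficients(w, eps = 1e-4)
  expect_true(all(co >= 0))
  expect_lte(sum(co), 1)
  expect_equal(sum(fusion_coefficients(c(1, 1), eps = 1e-12)), 1,
               tolerance = 1e-9)
  expect_equal(co[3], 0)  # negative weights are clipped out
})

test_that("pyramid fusion preserves shapes and fixes identical inputs", {
  set.seed(8)
  d <- 8L
  # constant-in-time levels survive resampling exactly
  base <- matrix(stats::rnorm(2 * d), 2, d)
  mk <- function(T_) {
    out <- array(0, c(2, d, T_))
    for (t in seq_len(T_)) out[, , t] <- base
    out
  }
  levels <- list(mk(40L), mk(20L), mk(10L))
  eye <- array(0, c(d, d, 1)); eye[, , 1] <- diag(d)
  w <- list(w = list(m2 = c(1, 1), m1 = c(1, 1), o2 = c(1, 1, 1),
                     o3 = c(1, 1)),
            W = list(m2 = eye, m1 = eye, o2 = eye, o3 = eye))
  fused <- bifpn_fuse(levels, eps = 1e-6, weights = w)
  expect_equal(lapply(fused, dim), lapply(levels, dim))
  for (i in 1:3) expect_equal(fused[[i]], levels[[i]], tolerance = 1e-4)
  # full-scale branch lengths pass through unchanged
  lv <- list(array(stats::rnorm(d * 140), c(1, d, 140)),
             array(stats::rnorm(d * 70), c(1, d, 70)),
             array(stats::rnorm(d * 35), c(1, d, 35)))
  expect_equal(vapply(bifpn_fuse(lv), function(a) dim(a)[3], numeric(1)),
               c(140, 70, 35))
  expect_error(bifpn_fuse(list(lv[[1]], lv[[2]], lv[[2]])), "halve")
})

test_that("encoder output lengths follow the pooling floor law", {
  cfg <- tiny_encoder(n_channels = 2L)
  for (T_ in c(96L, 131L, 257L, 400L)) {
    x <- tiny_trials(B = 1L, C = 2L, T_ = T_, seed = T_)
    z <- encode(x, cfg)
    T1 <- T_ %/% 8L
    expect_equal(vapply(z, function(a) dim(a)[2], numeric(1)),
                 c(T1, T1 %/% 2L, T1 %/% 2L %/% 2L), ignore_attr = TRUE)
  }
})

test_that("encoder ablation flags switch blocks off cleanly", {
  cfg_on <- tiny_encoder()
  cfg_off <- tiny_encoder()
  cfg_off$cbam <- FALSE
  cfg_off$bifpn <- FALSE
  x <- tiny_trials(B = 2L, C = 4L, T_ = 128L)
  z_on <- encode(x, cfg_on, seed = 2L)
  z_off <- encode(x, cfg_off, seed = 2L)
  expect_equal(lapply(z_on, dim), lapply(z_off, dim))
  expect_false(isTRUE(all.equal(z_on[[1]], z_off[[1]])))
})

test_that("CBAM rejects a reduction that does not divide the width", {
  x <- array(stats::rnorm(2 * 8 * 10), c(2, 8, 10))
  expect_error(cbam_attention(x, reduction = 3L), "divide")
})
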