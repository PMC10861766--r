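test_that("sliding windows satisfy the length-closure law", {
  z <- matrix(stats::rnorm(140 * 4), 140, 4)
  ws <- make_windows(z, 5)
  expect_length(ws, 5)
  expect_true(all(vapply(ws, nrow, numeric(1)) == 136))
  # identity case
  z10 <- matrix(stats::rnorm(40), 10, 4)
  expect_equal(make_windows(z10, 1)[[1]], z10)
  # every input row appears in at least one window (T_c = 35, n = 5)
  z35 <- matrix(seq_len(35), 35, 1)
  ws35 <- make_windows(z35, 5)
  expect_true(all(vapply(ws35, nrow, numeric(1)) == 31))
  covered <- sort(unique(unlist(ws35)))
  expect_equal(covered, 1:35)
  # closure property over random sizes
  for (i in 1:10) {
    Tc <- sample(5:200, 1)
    n <- sample(seq_len(Tc - 1L), 1)
    w <- make_windows(matrix(0, Tc, 2), n)
    expect_equal(attr(w, "window_length") + n - 1L, Tc)
  }
  expect_error(make_windows(z10, 10), "window count")
  expect_error(make_windows(z10, 0), "window count")
})

test_that("attention scores are row-stochastic and match a loop oracle", {
  # orthogonal queries/keys: uniform rows
  q <- matrix(c(1, 0, 0, 1), 2, 2)
  k <- matrix(0, 2, 2)
  s <- attention_scores(q, k)
  expect_equal(s, matrix(0.5, 2, 2))
  # single time step
  expect_equal(attention_scores(matrix(1, 1, 3), matrix(2, 1, 3)),
               matrix(1, 1, 1))
  # brute-force softmax oracle on random 4 x 8 inputs
  set.seed(11)
  q <- matrix(stats::rnorm(32), 4, 8)
  k <- matrix(stats::rnorm(32), 4, 8)
  s <- attention_scores(q, k)
  oracle <- matrix(0, 4, 4)
  for (a in 1:4) {
    e <- numeric(4)
    for (b in 1:4) e[b] <- exp(sum(q[a, ] * k[b, ]) / sqrt(8))
    oracle[a, ] <- e / sum(e)
  }
  expect_lt(max(abs(s - oracle)), 1e-6)
  expect_equal(rowSums(s), rep(1, 4), tolerance = 1e-6)
  expect_true(all(s > 0 & s < 1))
  expect_error(attention_scores(q, matrix(0, 4, 3)), "d_k")
})

test_that("attention application is a convex combination of value rows", {
  set.seed(12)
  v <- matrix(stats::rnorm(15), 5, 3)
  # uniform scores: every output row is the column mean
  su <- matrix(1 / 5, 5, 5)
  out <- attention_apply(su, v)
  for (a in 1:5) expect_equal(out[a, ], colMeans(v))
  # identity scores: output equals values
  expect_equal(attention_apply(diag(5), v), v)
  # double-loop summation oracle
  s <- attention_scores(matrix(stats::rnorm(20), 5, 4),
                        matrix(stats::rnorm(20), 5, 4))
  got <- attention_apply(s, v)
  oracle <- matrix(0, 5, 3)
  for (a in 1:5) for (b in 1:5) {
    oracle[a, ] <- oracle[a, ] + s[a, b] * v[b, ]
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  # constant values are conserved by any stochastic score matrix
  vc <- matrix(rep(c(2, -1, 0.5), each = 5), 5, 3)
  expect_equal(attention_apply(s, vc), vc, tolerance = 1e-9)
  expect_error(attention_apply(s, matrix(0, 4, 3)), "T x T")
  expect_error(attention_apply(matrix(c(0.9, 0.5, 0.3, 0.5), 2, 2),
                               matrix(0, 2, 1)), "stochastic")
})

test_that("multi-head attention is sensitive to time order", {
  set.seed(13)
  e <- matrix(stats::rnorm(20 * 6), 20, 6)
  y <- multihead_attention(e, n_heads = 2, head_dim = 4, std = 0.5,
                           seed = 4)
  perm <- sample(20)
  yp <- multihead_attention(e[perm, ], n_heads = 2, head_dim = 4,
                            std = 0.5, seed = 4)
  # self-attention is permutation-equivariant: reordering the input
  # reorders the output rows ...
  expect_equal(yp, y[perm, ], tolerance = 1e-9)
  # ... but with non-uniform scores the output itself changes, unlike a
  # pure time-pooling map
  expect_false(isTRUE(all.equal(yp, y)))
  expect_equal(dim(y), dim(e))
})

test_that("a branch concatenates fixed-size window summaries", {
  set.seed(14)
  at <- attention_config(n_heads = 2, head_dim = 4, dropout = 0)
  tc <- tcn_config(n_blocks = 1, kernel = 2, filters = 6, dropout = 0)
  for (Tc in c(30L, 60L)) {
    z <- matrix(stats::rnorm(Tc * 6), Tc, 6)
    v <- branch_forward(z, n_windows = 3, at_cfg = at, tc_cfg = tc)
    expect_length(v, 3 * 6)  # independent of T_c given n
  }
  # n = 1 reduces to plain attention -> TCN on the whole series
  z <- matrix(stats::rnorm(25 * 6), 25, 6)
  expect_length(branch_forward(z, n_windows = 1, at_cfg = at, tc_cfg = tc),
                6)
  # disabled attention still yields an identically shaped vector
  at_off <- attention_config(enabled = FALSE)
  expect_length(branch_forward(z, n_windows = 3, at_cfg = at_off,
                               tc_cfg = tc), 3 * 6)
})
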