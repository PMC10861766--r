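test_that("class-balanced accuracy averages per-class recall", {
  expect_equal(macro_accuracy(diag(c(5, 3, 9))), 1.0)
  cm <- matrix(c(3, 2, 1, 2), 2, 2)  # rows = true: [[3,1],[2,2]]
  expect_equal(macro_accuracy(cm), (3 / 4 + 2 / 4) / 2)
  expect_equal(macro_accuracy(cm), 0.625)
  expect_error(macro_accuracy(matrix(c(1, 0, 1, 0), 2, 2)), "no trials")
  # identical to micro accuracy whenever class sizes are equal
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    H <- sample(5:20, 1)
    cm <- t(vapply(seq_len(n), function(...) {
      as.numeric(stats::rmultinom(1, H, rep(1, n)))
    }, numeric(n)))
    expect_equal(macro_accuracy(cm), micro_accuracy(cm), tolerance = 1e-12)
  }
})

brute_force_kappa <- function(cm) {
  n <- sum(cm)
  pa <- sum(diag(cm)) / n
  pe <- 0
  for (i in seq_len(nrow(cm))) {
    pe <- pe + (sum(cm[i, ]) / n) * (sum(cm[, i]) / n)
  }
  (pa - pe) / (1 - pe)
}

test_that("Cohen's kappa is chance-corrected agreement", {
  expect_equal(cohen_kappa(diag(c(4, 6, 2))), 1.0)
  # independence with matching marginals: expected confusion, kappa 0
  cm0 <- outer(c(60, 40), c(70, 30)) / 100
  expect_equal(cohen_kappa(cm0), 0, tolerance = 1e-12)
  cm <- matrix(c(20, 10, 5, 15), 2, 2)  # [[20,5],[10,15]]
  expect_equal(cohen_kappa(cm), brute_force_kappa(cm), tolerance = 1e-12)
  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2, 2)), "degenerate")
})

test_that("kappa agrees with brute force and an independent library", {
  set.seed(42)
  has_e1071 <- requireNamespace("e1071", quietly = TRUE)
  for (i in 1:100) {
    n <- sample(2:5, 1)
    cm <- matrix(stats::rpois(n * n, 6) + 1, n, n)
    k <- cohen_kappa(cm)
    expect_lt(abs(k - brute_force_kappa(cm)), 1e-10)
    if (has_e1071) {
      expect_lt(abs(k - e1071::classAgreement(cm)$kappa), 1e-10)
    }
    # kappa never exceeds the raw agreement when P_e > 0
    expect_lte(k, sum(diag(cm)) / sum(cm) + 1e-12)
  }
})

test_that("metrics are invariant under class relabeling", {
  set.seed(43)
  cm <- matrix(stats::rpois(16, 5) + 1, 4, 4)
  perm <- sample(4)
  cmp <- cm[perm, perm]
  expect_equal(macro_accuracy(cm), macro_accuracy(cmp))
  expect_equal(cohen_kappa(cm), cohen_kappa(cmp))
})

test_that("metrics reports assemble confusion counts correctly", {
  true <- c(0L, 0L, 1L, 1L, 2L, 2L)
  pred <- c(0L, 1L, 1L, 1L, 2L, 0L)
  r <- metrics_report(true, pred)
  expect_s3_class(r, "mi_metrics")
  expect_equal(sum(r$confusion), 6)
  expect_equal(r$n_trials, 6)
  expect_equal(r$per_class_recall, c(0.5, 1, 0.5), ignore_attr = TRUE)
  expect_equal(r$acc, mean(c(0.5, 1, 0.5)))
  expect_output(print(r), "kappa")
  path <- tempfile(fileext = ".json")
  write_metrics_json(r, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$acc, r$acc)
  expect_equal(back$kappa, r$kappa)
  unlink(path)
})

test_that("subject summaries match the mean/STD table layout", {
  r1 <- metrics_report(c(0L, 0L, 1L, 1L, 1L), c(0L, 0L, 1L, 1L, 0L))
  expect_equal(subject_summary(list(S1 = r1))$acc[2], r1$acc)  # mean row
  expect_equal(subject_summary(list(S1 = r1))$acc[3], 0)       # STD row
  fake <- function(acc, kappa) {
    structure(list(acc = acc, kappa = kappa), class = "mi_metrics")
  }
  tab <- subject_summary(list(A = fake(0.8, 0.7), B = fake(0.9, 0.8)))
  expect_equal(tab$acc[tab$subject == "MEAN"], 0.85)
  expect_equal(tab$acc[tab$subject == "STD"], 0.05)
  expect_equal(tab$kappa[tab$subject == "MEAN"], 0.75)
  # CSV round trip preserves columns and values
  path <- tempfile(fileext = ".csv")
  write_subject_csv(tab, path)
  back <- read_subject_csv(path)
  expect_equal(names(back), names(tab))
  expect_equal(back$acc, tab$acc)
  unlink(path)
  expect_error(subject_summary(list()), "at least one")
})
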