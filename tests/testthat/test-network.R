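test_that("model construction is deterministic and flag-monotone", {
  cfg <- tiny_config()
  m1 <- build_model(cfg, seed = 3)
  m2 <- build_model(cfg, seed = 3)
  expect_identical(lapply(m1$params, function(p) p$value),
                   lapply(m2$params, function(p) p$value))
  n_full <- count_params(build_model(tiny_config()))
  n_nocbam <- count_params(build_model(tiny_config(use_cbam = FALSE)))
  n_nofpn <- count_params(build_model(tiny_config(use_bifpn = FALSE)))
  n_none <- count_params(build_model(tiny_config(use_cbam = FALSE,
                                                 use_bifpn = FALSE)))
  expect_gt(n_full, n_nocbam)
  expect_gt(n_full, n_nofpn)
  expect_gt(n_nocbam, n_none)
  expect_gt(n_nofpn, n_none)
  n_noat <- count_params(build_model(tiny_config(use_attention = FALSE)))
  n_notc <- count_params(build_model(tiny_config(use_tcn = FALSE)))
  expect_gt(n_full, n_noat)
  expect_gt(n_full, n_notc)
})

test_that("forward passes emit probability rows and are deterministic", {
  m <- build_model(tiny_config(), seed = 5)
  x <- tiny_trials()
  p1 <- model_forward(m, x)
  p2 <- model_forward(m, x)
  expect_equal(rowSums(p1), rep(1, nrow(p1)), tolerance = 1e-9)
  expect_true(all(p1 >= 0))
  expect_identical(p1, p2)  # evaluation mode has no randomness
})

test_that("weight initialization matches the declared distribution", {
  cfg <- model_config()  # full-size model: > 1e4 conv/dense weights
  m <- build_model(cfg, seed = 11, init_std = 0.01)
  is_weight <- !grepl("\\.(gamma|beta|b|w)$", names(m$params))
  wvals <- unlist(lapply(m$params[is_weight], function(p) p$value))
  expect_gt(length(wvals), 1e4)
  expect_lt(abs(stats::sd(wvals) / 0.01 - 1), 0.05)
  se <- 0.01 / sqrt(length(wvals))
  expect_lt(abs(mean(wvals)), 3 * se)
  # biases zero, batch-norm scale one, fusion scalars one
  expect_true(all(unlist(lapply(m$params[grepl("\\.(beta|b)$",
                                               names(m$params))],
                                function(p) p$value)) == 0))
  expect_true(all(unlist(lapply(m$params[grepl("\\.(gamma|w)$",
                                               names(m$params))],
                                function(p) p$value)) == 1))
  # identical draw under the same seed
  m2 <- build_model(cfg, seed = 11, init_std = 0.01)
  expect_identical(m$params[["enc.conv1.W"]]$value,
                   m2$params[["enc.conv1.W"]]$value)
  init_weights(m2, std = 0.02, seed = 4)
  init_weights(m, std = 0.02, seed = 4)
  expect_identical(m$params[["fc1.W"]]$value, m2$params[["fc1.W"]]$value)
})

test_that("every enabled block receives gradient", {
  m <- build_model(tiny_config(), seed = 6)
  x <- tiny_trials(B = 4L)
  g <- model_gradients(m, x, labels = c(0L, 1L, 2L, 0L))
  expect_true(all(!vapply(g, is.null, logical(1))))
  gmax <- vapply(g, function(a) max(abs(a)), numeric(1))
  expect_true(all(gmax > 0))
})

test_that("zero learning rate leaves parameters untouched", {
  m <- build_model(tiny_config(), seed = 7)
  before <- lapply(m$params, function(p) p$value)
  x <- tiny_trials(B = 6L)
  train_model(m, x, labels = rep(0:2, 2),
              train_config(lr = 0, epochs = 2, batch_size = 4, seed = 1))
  after <- lapply(m$params, function(p) p$value)
  expect_identical(before, after)
})

test_that("training reduces the loss on a separable problem", {
  spec <- tiny_synth(n_per_class = 6L, n_channels = 4L, T_ = 192L,
                     n_classes = 2L, seed = 3L)
  ds <- simulate_mi_eeg(spec)
  cfg <- tiny_config(n_classes = 2L, n_channels = 4L)
  fit <- bfatcnet(ds, config = cfg,
                  train = train_config(epochs = 8, batch_size = 12,
                                       seed = 2))
  h <- fit$loss_history
  expect_length(h, 8)
  expect_lt(h[length(h)], h[1])
})

test_that("fixed seeds give bit-identical training runs", {
  spec <- tiny_synth(n_per_class = 4L, n_channels = 4L, T_ = 160L,
                     n_classes = 2L, seed = 5L)
  ds <- simulate_mi_eeg(spec)
  cfg <- tiny_config(n_classes = 2L, n_channels = 4L)
  tcfg <- train_config(epochs = 3, batch_size = 8, seed = 123)
  f1 <- bfatcnet(ds, config = cfg, train = tcfg,
                 augment = augment_params())
  f2 <- bfatcnet(ds, config = cfg, train = tcfg,
                 augment = augment_params())
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(predict(f1, ds$data, type = "prob"),
                   predict(f2, ds$data, type = "prob"))
})

test_that("permuting the output layer permutes class probabilities", {
  m <- build_model(tiny_config(), seed = 8)
  x <- tiny_trials(B = 2L)
  p <- model_forward(m, x)
  perm <- c(3L, 1L, 2L)
  m$params[["fc3.W"]]$value <- m$params[["fc3.W"]]$value[perm, ]
  m$params[["fc3.b"]]$value <- m$params[["fc3.b"]]$value[perm]
  p2 <- model_forward(m, x)
  expect_equal(p2, p[, perm], tolerance = 1e-12)
})

test_that("degenerate training inputs are rejected", {
  m <- build_model(tiny_config(), seed = 9)
  x <- tiny_trials(B = 2L)
  expect_error(train_model(m, x, labels = c(0L, 5L)), "n_classes")
  expect_error(train_model(m, x[0, , , drop = FALSE], labels = integer(0)),
               "empty")
})

test_that("checkpoints round-trip the fitted model exactly", {
  spec <- tiny_synth(n_per_class = 3L, n_channels = 4L, T_ = 160L,
                     n_classes = 2L, seed = 8L)
  ds <- simulate_mi_eeg(spec)
  cfg <- tiny_config(n_classes = 2L, n_channels = 4L)
  fit <- bfatcnet(ds, config = cfg,
                  train = train_config(epochs = 1, batch_size = 6,
                                       seed = 3))
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  expect_identical(predict(fit, ds$data, type = "prob"),
                   predict(fit2, ds$data, type = "prob"))
  expect_identical(fit$loss_history, fit2$loss_history)
  unlink(path)
})

test_that("configuration YAML mirrors the config objects field-for-field", {
  cfg <- tiny_config(n_classes = 2L)
  tcfg <- train_config(epochs = 7, seed = 42)
  path <- tempfile(fileext = ".yaml")
  write_config_yaml(cfg, tcfg, path)
  back <- read_config_yaml(path)
  expect_equal(back$model, cfg)
  expect_equal(back$train, tcfg)
  unlink(path)
})

test_that("fit objects expose the standard S3 surface", {
  spec <- tiny_synth(n_per_class = 3L, n_channels = 4L, T_ = 160L,
                     n_classes = 2L, seed = 9L)
  ds <- simulate_mi_eeg(spec)
  fit <- bfatcnet(ds, config = tiny_config(n_classes = 2L),
                  train = train_config(epochs = 1, batch_size = 6,
                                       seed = 2))
  expect_output(print(fit), "parameters")
  expect_output(s <- summary(fit), "Parameters by block")
  expect_true(is.list(coef(fit)))
  expect_identical(count_params(fit), sum(lengths(coef(fit))))
  cl <- predict(fit, ds)
  expect_true(all(cl %in% 0:1))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("the full model can memorize random labels (capacity sanity)", {
  set.seed(123)
  B <- 32L; C <- 22L; T_ <- 320L
  x <- array(stats::rnorm(B * C * T_), c(B, C, T_))
  y <- sample(0:3, B, replace = TRUE)
  model <- build_model(model_config(), seed = 1)
  epochs_done <- 0L
  acc <- 0
  while (epochs_done < 200L && acc < 1) {
    train_model(model, x, y,
                train_config(epochs = 25, batch_size = 32,
                             seed = 100L + epochs_done))
    epochs_done <- epochs_done + 25L
    acc <- mean(max.col(model_forward(model, x)) - 1L == y)
  }
  expect_equal(acc, 1)  # 100% training accuracy within 200 epochs
})
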