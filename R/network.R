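# Full network: encoder -> three attention/TCN branches -> fully connected
# head with softmax, plus weight initialization, AdamW training loop and
# ablation flags.

#' Model configuration
#'
#' Bundles every architectural hyperparameter. The ablation flags replace
#' the named block with an identity map of matching shape and remove its
#' parameters.
#'
#' @param encoder An [encoder_config()].
#' @param at An [attention_config()].
#' @param tc A [tcn_config()].
#' @param n_windows Sliding windows per branch.
#' @param fc_dims Widths of the two hidden fully connected layers.
#' @param n_classes Number of output classes.
#' @param dropout Dropout probability used in the attention, TCN and fully
#'   connected blocks.
#' @param use_bifpn,use_cbam,use_attention,use_tcn Ablation flags.
#' @return Object of class `model_config`.
#' @export
model_config <- function(encoder = encoder_config(),
                         at = attention_config(),
                         tc = tcn_config(),
                         n_windows = 5L, fc_dims = c(128L, 64L),
                         n_classes = 4L, dropout = 0.12,
                         use_bifpn = TRUE, use_cbam = TRUE,
                         use_attention = TRUE, use_tcn = TRUE) {
  stopifnot(n_windows >= 1, length(fc_dims) == 2, n_classes >= 2,
            dropout >= 0, dropout < 1)
  encoder$bifpn <- isTRUE(use_bifpn)
  encoder$cbam <- isTRUE(use_cbam)
  at$enabled <- isTRUE(use_attention)
  tc$enabled <- isTRUE(use_tcn)
  at$dropout <- dropout
  tc$dropout <- dropout
  structure(list(encoder = encoder, at = at, tc = tc,
                 n_windows = as.integer(n_windows),
                 fc_dims = as.integer(fc_dims),
                 n_classes = as.integer(n_classes),
                 dropout = dropout),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the tuned recipe: AdamW with learning rate 1.795e-3,
#' decoupled weight decay 5.015e-8, batch size 128, 50 epochs, and weight
#' initialization N(0, 0.01^2).
#'
#' @param lr Learning rate.
#' @param weight_decay Decoupled weight-decay rate.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param seed RNG seed controlling initialization, shuffling, dropout and
#'   augmentation draws.
#' @param init_std Standard deviation of the initial weight draw.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 1.795e-3, weight_decay = 5.015e-8,
                         batch_size = 128L, epochs = 50L, seed = 1L,
                         init_std = 0.01) {
  stopifnot(lr >= 0, weight_decay >= 0, batch_size >= 1, epochs >= 1,
            init_std > 0)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 init_std = init_std),
            class = "train_config")
}

branch_pooled_dim <- function(cfg) {
  if (cfg$tc$enabled) cfg$tc$filters else cfg$encoder$fused_dim
}

fc_input_dim <- function(cfg) {
  3L * cfg$n_windows * branch_pooled_dim(cfg)
}

#' Build the network
#'
#' Deterministically constructs all parameters (weights N(0, std^2),
#' biases 0, batch-norm scale 1 / shift 0, pyramid fusion scalars 1) for a
#' given configuration and seed; the parameter count is a pure function of
#' the configuration.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the initial weight draw.
#' @param init_std Standard deviation of the weight draw.
#' @return Object of class `bfatcnet_model` (parameters, batch-norm
#'   states and configuration).
#' @export
build_model <- function(cfg = model_config(), seed = 1L, init_std = 0.01) {
  d <- cfg$encoder$fused_dim
  build <- function() {
    ep <- encoder_params(cfg$encoder, init_std)
    P <- ep$P
    S <- ep$S
    for (i in 1:3) {
      pre <- paste0("br", i)
      P <- c(P, branch_params(pre, d, cfg$at, cfg$tc, init_std))
      S <- c(S, branch_states(pre, cfg$tc))
    }
    fin <- fc_input_dim(cfg)
    dims <- c(fin, cfg$fc_dims, cfg$n_classes)
    for (j in 1:3) {
      P[[paste0("fc", j, ".W")]] <- new_param(
        param_normal(c(dims[j + 1], dims[j]), init_std),
        paste0("fc", j, ".W"))
      P[[paste0("fc", j, ".b")]] <- new_param(numeric(dims[j + 1]),
                                              paste0("fc", j, ".b"))
      if (j < 3) {
        r <- add_bn(P, S, paste0("fc.bn", j), dims[j + 1], init_std)
        P <- r$P; S <- r$S
      }
    }
    list(P = P, S = S)
  }
  ps <- with_seeded_params(seed, build)
  structure(list(config = cfg, params = ps$P, states = ps$S,
                 seed = as.integer(seed)),
            class = "bfatcnet_model")
}

#' Number of learnable parameters
#'
#' @param model A `bfatcnet_model` or fitted `bfatcnet` object.
#' @return Integer total parameter count.
#' @export
count_params <- function(model) {
  if (inherits(model, "bfatcnet")) model <- model$model
  as.integer(sum(vapply(model$params, function(p) length(p$value),
                        numeric(1))))
}

#' Re-initialize model weights
#'
#' Draws every convolution/projection/dense weight from N(0, std^2), sets
#' biases and batch-norm shifts to zero, batch-norm scales and pyramid
#' fusion scalars to one, and resets batch-norm running statistics.
#'
#' @param model A `bfatcnet_model`.
#' @param std Standard deviation of the weight draw.
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @return The model, modified in place and returned invisibly.
#' @export
init_weights <- function(model, std = 0.01, seed = 1L) {
  stopifnot(inherits(model, "bfatcnet_model"))
  with_seeded_params(seed, function() {
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      if (grepl("\\.gamma$", nm) || grepl("\\.w$", nm)) {
        p$value <- rep(1, length(p$value))
      } else if (grepl("\\.(beta|b)$", nm)) {
        p$value <- rep(0, length(p$value))
      } else {
        dm <- dim(p$value)
        v <- stats::rnorm(length(p$value), 0, std)
        if (!is.null(dm)) dim(v) <- dm
        p$value <- v
      }
      p$grad <- NULL
    }
    NULL
  })
  for (st in model$states) {
    st$running_mean <- 0 * st$running_mean
    st$running_var <- 0 * st$running_var + 1
  }
  invisible(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build the full forward graph; returns logits node (+ loss when labels
# are supplied).
model_forward_tape <- function(model, x, training, tape, labels = NULL) {
  cfg <- model$config
  P <- model$params
  S <- model$states
  levels <- encoder_forward_tape(tape, P, S, x, cfg$encoder, training)
  feats <- lapply(1:3, function(i) {
    branch_forward_tape(tape, P, S, levels[[i]], cfg$n_windows, cfg$at,
                        cfg$tc, training, paste0("br", i))
  })
  h <- op_concat_features(tape, feats)
  for (j in 1:2) {
    h <- op_linear_cols(tape, h, leafp(tape, P, paste0("fc", j, ".W")),
                        leafp(tape, P, paste0("fc", j, ".b")))
    h <- bn_tape(tape, P, S, paste0("fc.bn", j), h, training)
    h <- op_elu(tape, h)
    h <- op_dropout(tape, h, cfg$dropout, training)
  }
  logits <- op_linear_cols(tape, h, leafp(tape, P, "fc3.W"),
                           leafp(tape, P, "fc3.b"))
  out <- list(logits = logits)
  if (!is.null(labels)) {
    out$loss <- op_softmax_ce(tape, logits, as.integer(labels))
  }
  out
}

#' Forward pass through the network
#'
#' Evaluation-mode forward passes are deterministic (dropout inactive,
#' batch-norm running statistics); each returned probability row is
#' nonnegative and sums to one.
#'
#' @param model A `bfatcnet_model`.
#' @param x Numeric array (trials, channels, time).
#' @param training Use batch statistics and active dropout.
#' @return Matrix (trials x n_classes) of class probabilities.
#' @export
model_forward <- function(model, x, training = FALSE) {
  check_trials_array(x)
  tape <- ag_tape()
  fw <- model_forward_tape(model, x, training, tape)
  t(softmax_cols(fw$logits$value))
}

#' Gradients of the training loss for one batch
#'
#' Runs a training-mode forward and backward pass and returns the gradient
#' of the mean cross-entropy loss with respect to every parameter.
#'
#' @param model A `bfatcnet_model`.
#' @param x Numeric array (trials, channels, time).
#' @param labels Integer labels in `[0, n_classes)`.
#' @return Named list of gradient arrays.
#' @export
model_gradients <- function(model, x, labels) {
  check_trials_array(x)
  zero_grads(model$params)
  tape <- ag_tape()
  fw <- model_forward_tape(model, x, training = TRUE, tape,
                           labels = labels)
  ag_backward(tape, fw$loss)
  out <- lapply(model$params, function(p) p$grad)
  zero_grads(model$params)
  out
}

adamw_init <- function(params) {
  lapply(params, function(p) {
    e <- new.env(parent = emptyenv())
    e$m <- 0 * p$value
    e$v <- 0 * p$value
    e
  })
}

adamw_step <- function(params, opt, lr, wd, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st <- opt[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p$value <- p$value - lr * (mhat / (sqrt(vhat) + eps) + wd * p$value)
  }
  invisible(NULL)
}

#' Train a built model
#'
#' AdamW (decoupled weight decay) on the categorical cross-entropy loss
#' with seeded per-epoch shuffling and optional online per-batch
#' augmentation. A fixed seed gives a bit-identical loss history on one
#' device.
#'
#' @param model A `bfatcnet_model`; updated in place.
#' @param x Numeric array (trials, channels, time).
#' @param labels Integer labels in `[0, n_classes)`.
#' @param tcfg A [train_config()].
#' @param augment Optional [augment_params()] applied online per batch.
#' @param verbose Print per-epoch loss.
#' @return The model, with a numeric `loss_history` attribute of one mean
#'   loss per epoch.
#' @export
train_model <- function(model, x, labels, tcfg = train_config(),
                        augment = NULL, verbose = FALSE) {
  check_trials_array(x)
  B <- dim(x)[1]
  if (B == 0) stop("empty dataset")
  labels <- as.integer(labels)
  if (length(labels) != B) stop("labels must match the number of trials")
  K <- model$config$n_classes
  if (any(labels < 0 | labels >= K)) {
    stop("labels must lie in [0, n_classes)")
  }
  set.seed(tcfg$seed)
  params <- model$params
  opt <- adamw_init(params)
  history <- numeric(tcfg$epochs)
  step <- 0L
  for (ep in seq_len(tcfg$epochs)) {
    idx <- sample.int(B)
    starts <- seq(1, B, by = tcfg$batch_size)
    losses <- numeric(length(starts))
    for (s in seq_along(starts)) {
      bi <- idx[starts[s]:min(starts[s] + tcfg$batch_size - 1L, B)]
      xb <- x[bi, , , drop = FALSE]
      yb <- labels[bi]
      if (!is.null(augment)) {
        ab <- augment_batch(xb, yb, augment)
        xb <- ab$data
      }
      zero_grads(params)
      tape <- ag_tape()
      fw <- model_forward_tape(model, xb, training = TRUE, tape,
                               labels = yb)
      lv <- fw$loss$value
      if (!is.finite(lv)) stop("training diverged (non-finite loss)")
      ag_backward(tape, fw$loss)
      step <- step + 1L
      adamw_step(params, opt, tcfg$lr, tcfg$weight_decay, step)
      losses[s] <- lv
    }
    history[ep] <- mean(losses)
    if (verbose) {
      message(sprintf("epoch %3d/%d  loss %.4f", ep, tcfg$epochs,
                      history[ep]))
    }
  }
  calibrate_bn(model, x, batch_size = tcfg$batch_size)
  attr(model, "loss_history") <- history
  invisible(model)
}

#' Re-estimate batch-norm statistics over a dataset
#'
#' Replaces every batch-norm layer's running mean and variance with the
#' exact statistics of the final weights over `x` (one forward sweep with
#' batch statistics and inactive dropout). Called automatically at the end
#' of [train_model()] so that evaluation-mode forwards use statistics that
#' match the trained weights rather than a lagging moving average.
#'
#' @param model A `bfatcnet_model`; states updated in place.
#' @param x Numeric array (trials, channels, time).
#' @param batch_size Trials per sweep batch.
#' @return The model, invisibly.
#' @export
calibrate_bn <- function(model, x, batch_size = 128L) {
  for (st in model$states) {
    st$calib <- TRUE
    st$acc_n <- 0
    st$acc_s1 <- 0
    st$acc_s2 <- 0
  }
  on.exit(for (st in model$states) st$calib <- FALSE)
  mcal <- model
  mcal$config$dropout <- 0
  mcal$config$at$dropout <- 0
  mcal$config$tc$dropout <- 0
  B <- dim(x)[1]
  for (s in seq(1, B, by = batch_size)) {
    bi <- s:min(s + batch_size - 1L, B)
    tape <- ag_tape()
    model_forward_tape(mcal, x[bi, , , drop = FALSE], training = TRUE,
                       tape)
  }
  for (st in model$states) {
    if (st$acc_n > 0) {
      m <- st$acc_s1 / st$acc_n
      st$running_mean <- m
      st$running_var <- pmax(st$acc_s2 / st$acc_n - m^2, 0)
    }
  }
  invisible(model)
}

#' Fit the motor-imagery EEG classifier
#'
#' Builds the attention-based bidirectional-feature-pyramid temporal
#' convolutional network and trains it on epoched EEG trials with AdamW
#' and the categorical cross-entropy loss.
#'
#' @param x An `epoched_eeg` dataset (see [epoched_eeg()]) or a numeric
#'   array (trials, channels, time).
#' @param labels Integer class labels in `[0, n_classes)`; taken from `x`
#'   when it is an `epoched_eeg` object.
#' @param config A [model_config()].
#' @param train A [train_config()].
#' @param augment Optional [augment_params()] for online per-batch
#'   augmentation.
#' @param verbose Print per-epoch training loss.
#' @return Object of class `bfatcnet` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods.
#' @examples
#' \donttest{
#' spec <- synth_spec(n_trials_per_class = 8, trial_seconds = 2)
#' ds <- simulate_mi_eeg(spec)
#' fit <- bfatcnet(ds, train = train_config(epochs = 2, batch_size = 16))
#' predict(fit, ds$data[1:4, , ])
#' }
#' @export
bfatcnet <- function(x, labels = NULL, config = model_config(),
                     train = train_config(), augment = NULL,
                     verbose = FALSE) {
  if (inherits(x, "epoched_eeg")) {
    labels <- x$labels
    x <- x$data
  }
  check_trials_array(x)
  if (is.null(labels)) stop("labels are required")
  model <- build_model(config, seed = train$seed,
                       init_std = train$init_std)
  model <- train_model(model, x, labels, train, augment = augment,
                       verbose = verbose)
  structure(list(model = model, config = config, train = train,
                 loss_history = attr(model, "loss_history"),
                 n_trials = dim(x)[1], input_dim = dim(x)[2:3],
                 call = match.call()),
            class = "bfatcnet")
}

#' @export
print.bfatcnet <- function(x, ...) {
  cfg <- x$config
  cat("Attention-based bidirectional feature pyramid TCN (MI-EEG)\n")
  cat(sprintf("  input        : %d channels x %d samples, %d trials\n",
              x$input_dim[1], x$input_dim[2], x$n_trials))
  cat(sprintf("  classes      : %d\n", cfg$n_classes))
  cat(sprintf("  blocks       : CBAM=%s Bi-FPN=%s attention=%s TCN=%s\n",
              cfg$encoder$cbam, cfg$encoder$bifpn, cfg$at$enabled,
              cfg$tc$enabled))
  cat(sprintf("  parameters   : %d\n", count_params(x)))
  cat(sprintf("  epochs       : %d, final loss %.4f\n",
              length(x$loss_history), tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
summary.bfatcnet <- function(object, ...) {
  p <- object$model$params
  groups <- sub("\\..*$", "", names(p))
  sizes <- vapply(p, function(q) length(q$value), numeric(1))
  tab <- tapply(sizes, groups, sum)
  out <- list(parameters = count_params(object),
              parameters_by_block = tab,
              loss_history = object$loss_history,
              config = object$config)
  print(object)
  cat("\nParameters by block:\n")
  print(tab)
  invisible(out)
}

#' @export
coef.bfatcnet <- function(object, ...) {
  lapply(object$model$params, function(p) p$value)
}

#' Predict class labels or probabilities
#'
#' @param object A fitted `bfatcnet` object.
#' @param newdata An `epoched_eeg` dataset or array (trials, channels,
#'   time).
#' @param type `"class"` for 0-based integer labels, `"prob"` for the
#'   probability matrix.
#' @param batch_size Trials per evaluation batch.
#' @param ... Unused.
#' @export
predict.bfatcnet <- function(object, newdata, type = c("class", "prob"),
                             batch_size = 64L, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "epoched_eeg")) newdata <- newdata$data
  check_trials_array(newdata)
  B <- dim(newdata)[1]
  probs <- matrix(0, B, object$config$n_classes)
  for (s in seq(1, B, by = batch_size)) {
    bi <- s:min(s + batch_size - 1L, B)
    probs[bi, ] <- model_forward(object$model,
                                 newdata[bi, , , drop = FALSE])
  }
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' @export
plot.bfatcnet <- function(x, ...) {
  plot(seq_along(x$loss_history), x$loss_history, type = "b",
       xlab = "epoch", ylab = "mean training loss",
       main = "Training loss", ...)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file embedding the full model and training
#' configuration alongside all parameter values, batch-norm running
#' statistics and the loss history.
#'
#' @param object A fitted `bfatcnet` object.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `bfatcnet` object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "bfatcnet"))
  payload <- list(
    format = "bfatcnet-checkpoint-1",
    config = object$config, train = object$train,
    params = lapply(object$model$params, function(p) p$value),
    states = lapply(object$model$states, function(st) {
      list(running_mean = st$running_mean, running_var = st$running_var,
           momentum = st$momentum, eps = st$eps)
    }),
    loss_history = object$loss_history,
    n_trials = object$n_trials, input_dim = object$input_dim
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "bfatcnet-checkpoint-1")) {
    stop("not a bfatcnet checkpoint")
  }
  model <- build_model(payload$config)
  for (nm in names(payload$params)) {
    model$params[[nm]]$value <- payload$params[[nm]]
  }
  for (nm in names(payload$states)) {
    st <- model$states[[nm]]
    st$running_mean <- payload$states[[nm]]$running_mean
    st$running_var <- payload$states[[nm]]$running_var
  }
  structure(list(model = model, config = payload$config,
                 train = payload$train,
                 loss_history = payload$loss_history,
                 n_trials = payload$n_trials,
                 input_dim = payload$input_dim,
                 call = quote(load_checkpoint())),
            class = "bfatcnet")
}

#' Read / write model and training configuration as YAML
#'
#' The YAML file mirrors [model_config()] and [train_config()]
#' field-for-field under top-level keys `model` and `train`.
#'
#' @param config A [model_config()].
#' @param train A [train_config()].
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, train, path) {
  enc <- unclass(config$encoder)
  payload <- list(
    model = list(encoder = enc, at = unclass(config$at),
                 tc = unclass(config$tc), n_windows = config$n_windows,
                 fc_dims = config$fc_dims, n_classes = config$n_classes,
                 dropout = config$dropout),
    train = unclass(train)
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  m <- y$model
  enc <- do.call(encoder_config, m$encoder)
  at <- do.call(attention_config, m$at)
  tc <- do.call(tcn_config, m$tc)
  cfg <- model_config(encoder = enc, at = at, tc = tc,
                      n_windows = m$n_windows, fc_dims = m$fc_dims,
                      n_classes = m$n_classes, dropout = m$dropout,
                      use_bifpn = enc$bifpn, use_cbam = enc$cbam,
                      use_attention = at$enabled, use_tcn = tc$enabled)
  list(model = cfg, train = do.call(train_config, y$train))
}
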