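# Temporal feature encoder: EEGNet-style temporal + depthwise electrode
# convolutions, CBAM attention, two further temporal stages, and a
# bidirectional feature pyramid producing three band-limited time series
# (nominally 4-32, 4-16 and 4-8 Hz).

#' Encoder configuration
#'
#' Architectural hyperparameters of the temporal feature block. The default
#' wiring gives `f1 * depth_mult` = `fused_dim` feature maps after the
#' depthwise electrode convolution, so all pyramid levels share `fused_dim`
#' channels.
#'
#' @param n_channels Number of EEG electrodes C.
#' @param sampling_rate Sampling rate in Hz.
#' @param f1 Number of temporal filters in the first convolution.
#' @param depth_mult Depth multiplier D of the depthwise electrode
#'   convolution (number of spatial filters learned per temporal map).
#' @param temporal_kernel Temporal kernel length in samples; by default
#'   derived from the sampling rate via [temporal_kernel_length()].
#' @param spatial_kernel Kernel length of the two later temporal stages.
#' @param pool_sizes Ordered average-pooling kernels of stages 2-4. Their
#'   product is the total temporal downsampling of the coarsest branch.
#' @param cbam Enable the convolutional block attention module.
#' @param cbam_reduction Channel-attention MLP reduction ratio (must divide
#'   `fused_dim`).
#' @param cbam_spatial_kernel Kernel length of the spatial-attention
#'   convolution along time.
#' @param bifpn Enable the bidirectional feature pyramid fusion.
#' @param bifpn_eps Stabilizer of the fast-normalized fusion weights.
#' @param fused_dim Channel count d shared by all three branch outputs.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(n_channels = 22L, sampling_rate = 250,
                           f1 = 16L, depth_mult = 2L,
                           temporal_kernel = NULL, spatial_kernel = 16L,
                           pool_sizes = c(8L, 2L, 2L),
                           cbam = TRUE, cbam_reduction = 8L,
                           cbam_spatial_kernel = 7L,
                           bifpn = TRUE, bifpn_eps = 1e-4,
                           fused_dim = 32L) {
  if (n_channels < 1) stop("n_channels must be positive")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (length(pool_sizes) != 3 || any(pool_sizes < 1)) {
    stop("pool_sizes must be three positive integers")
  }
  if (is.null(temporal_kernel)) {
    temporal_kernel <- temporal_kernel_length(sampling_rate)
  }
  if (f1 * depth_mult != fused_dim) {
    stop("f1 * depth_mult must equal fused_dim in the default wiring")
  }
  if (fused_dim %% cbam_reduction != 0) {
    stop("cbam_reduction must divide fused_dim")
  }
  structure(list(
    n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
    f1 = as.integer(f1), depth_mult = as.integer(depth_mult),
    temporal_kernel = as.integer(temporal_kernel),
    spatial_kernel = as.integer(spatial_kernel),
    pool_sizes = as.integer(pool_sizes),
    cbam = isTRUE(cbam), cbam_reduction = as.integer(cbam_reduction),
    cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
    bifpn = isTRUE(bifpn), bifpn_eps = bifpn_eps,
    fused_dim = as.integer(fused_dim)
  ), class = "encoder_config")
}

#' Temporal kernel length from the sampling rate
#'
#' The first convolution uses filters spanning a quarter second, rounded to
#' the nearest power of two (ties upward) so the kernel has a standard
#' length; this keeps activity above 4 Hz within the filter span. At 250 Hz
#' the quarter-second span is 62.5 samples and the selected length is 64.
#'
#' @param sampling_rate Sampling rate in Hz (positive).
#' @return Integer kernel length in samples.
#' @examples
#' temporal_kernel_length(250) # 64
#' temporal_kernel_length(128) # 32
#' @export
temporal_kernel_length <- function(sampling_rate) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number")
  }
  v <- sampling_rate / 4
  lo <- 2^floor(log2(v))
  hi <- 2^ceiling(log2(v))
  as.integer(if (v - lo < hi - v) lo else hi)
}

band_labels <- c("4-32 Hz", "4-16 Hz", "4-8 Hz")

param_normal <- function(dims, std) {
  array(stats::rnorm(prod(dims), 0, std), dims)
}

bn_state <- function(C, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(C)
  e$running_var <- rep(1, C)
  e$momentum <- momentum
  e$eps <- eps
  e
}

add_bn <- function(P, S, name, C, std) {
  P[[paste0(name, ".gamma")]] <- new_param(rep(1, C), paste0(name, ".gamma"))
  P[[paste0(name, ".beta")]] <- new_param(numeric(C), paste0(name, ".beta"))
  S[[name]] <- bn_state(C)
  list(P = P, S = S)
}

# Create all encoder parameters (named list of ag_param) and batch-norm
# state environments. Weight draws come from the current RNG stream.
encoder_params <- function(cfg, std = 0.01) {
  P <- list()
  S <- list()
  d <- cfg$fused_dim
  P[["enc.conv1.W"]] <- new_param(
    param_normal(c(cfg$f1, 1, cfg$temporal_kernel), std), "enc.conv1.W")
  r <- add_bn(P, S, "enc.bn1", cfg$f1, std); P <- r$P; S <- r$S
  P[["enc.dw.W"]] <- new_param(
    param_normal(c(cfg$n_channels, cfg$depth_mult, cfg$f1), std), "enc.dw.W")
  r <- add_bn(P, S, "enc.bn2", d, std); P <- r$P; S <- r$S
  if (cfg$cbam) {
    hid <- d %/% cfg$cbam_reduction
    P[["enc.cbam.mlp1.W"]] <- new_param(param_normal(c(hid, d), std),
                                        "enc.cbam.mlp1.W")
    P[["enc.cbam.mlp2.W"]] <- new_param(param_normal(c(d, hid), std),
                                        "enc.cbam.mlp2.W")
    P[["enc.cbam.sp.W"]] <- new_param(
      param_normal(c(1, 2, cfg$cbam_spatial_kernel), std), "enc.cbam.sp.W")
    P[["enc.cbam.sp.b"]] <- new_param(numeric(1), "enc.cbam.sp.b")
  }
  P[["enc.conv3.W"]] <- new_param(
    param_normal(c(d, d, cfg$spatial_kernel), std), "enc.conv3.W")
  r <- add_bn(P, S, "enc.bn3", d, std); P <- r$P; S <- r$S
  P[["enc.conv4.W"]] <- new_param(
    param_normal(c(d, d, cfg$spatial_kernel), std), "enc.conv4.W")
  r <- add_bn(P, S, "enc.bn4", d, std); P <- r$P; S <- r$S
  if (cfg$bifpn) {
    for (nm in c("m2", "m1", "o2", "o3")) {
      nw <- if (nm == "o2") 3 else 2
      P[[paste0("enc.fpn.", nm, ".w")]] <- new_param(
        rep(1, nw), paste0("enc.fpn.", nm, ".w"))
      P[[paste0("enc.fpn.", nm, ".W")]] <- new_param(
        param_normal(c(d, d, 1), std), paste0("enc.fpn.", nm, ".W"))
      r <- add_bn(P, S, paste0("enc.fpn.", nm, ".bn"), d, std)
      P <- r$P; S <- r$S
    }
  }
  list(P = P, S = S)
}

leafp <- function(tape, P, name) ag_leaf(tape, P[[name]])

bn_tape <- function(tape, P, S, name, h, training) {
  op_bn(tape, h, leafp(tape, P, paste0(name, ".gamma")),
        leafp(tape, P, paste0(name, ".beta")), S[[name]], training)
}

cbam_forward_tape <- function(tape, P, S, h, cfg, training) {
  avg <- op_global_avg_time(tape, h)
  mx <- op_global_max_time(tape, h)
  mlp <- function(v) {
    v <- op_linear_cols(tape, v, leafp(tape, P, "enc.cbam.mlp1.W"))
    v <- op_relu(tape, v)
    op_linear_cols(tape, v, leafp(tape, P, "enc.cbam.mlp2.W"))
  }
  cw <- op_sigmoid(tape, op_add(tape, mlp(avg), mlp(mx)))
  h <- op_mul_bcast_channel(tape, h, cw)
  cm <- op_channel_mean(tape, h)
  cx <- op_channel_max(tape, h)
  st <- op_stack2(tape, cm, cx)
  sw <- op_conv1d(tape, st, leafp(tape, P, "enc.cbam.sp.W"),
                  leafp(tape, P, "enc.cbam.sp.b"),
                  pad = same_pad(cfg$cbam_spatial_kernel))
  sw <- op_sigmoid(tape, sw)
  op_mul_bcast_time(tape, h, sw)
}

fpn_node <- function(tape, P, S, name, inputs, eps, training) {
  f <- op_fuse(tape, inputs, leafp(tape, P, paste0("enc.fpn.", name, ".w")),
               eps)
  f <- op_conv1d(tape, f, leafp(tape, P, paste0("enc.fpn.", name, ".W")))
  bn_tape(tape, P, S, paste0("enc.fpn.", name, ".bn"), f, training)
}

bifpn_forward_tape <- function(tape, P, S, levels, cfg, training) {
  l1 <- levels[[1]]; l2 <- levels[[2]]; l3 <- levels[[3]]
  T1 <- dim(l1$value)[2]; T2 <- dim(l2$value)[2]
  eps <- cfg$bifpn_eps
  m2 <- fpn_node(tape, P, S, "m2",
                 list(l2, op_resample_time(tape, l3, T2)), eps, training)
  m1 <- fpn_node(tape, P, S, "m1",
                 list(l1, op_resample_time(tape, m2, T1)), eps, training)
  o2 <- fpn_node(tape, P, S, "o2",
                 list(l2, m2, op_avgpool_time(tape, m1, 2L)), eps, training)
  o3 <- fpn_node(tape, P, S, "o3",
                 list(l3, op_avgpool_time(tape, o2, 2L)), eps, training)
  list(m1, o2, o3)
}

# Full encoder graph. x: numeric array (trials B, channels C, time T).
# Returns a list of three nodes with values (d, T_level, B).
encoder_forward_tape <- function(tape, P, S, x, cfg, training) {
  dx <- dim(x)
  B <- dx[1]; C <- dx[2]; T_ <- dx[3]
  if (C != cfg$n_channels) stop("input channel count does not match config")
  K <- cfg$temporal_kernel
  if (T_ < K) stop("trial length is shorter than the temporal kernel")
  xi <- aperm(x, c(3, 2, 1))
  dim(xi) <- c(T_, C * B)
  # stages 1-2 run as one fused operator: temporal conv + batch norm
  # (layer 1 is linear, as in the EEGNet lineage) + depthwise conv
  h <- op_front(tape, xi, leafp(tape, P, "enc.conv1.W"),
                leafp(tape, P, "enc.bn1.gamma"),
                leafp(tape, P, "enc.bn1.beta"),
                leafp(tape, P, "enc.dw.W"), S[["enc.bn1"]], training)
  h <- bn_tape(tape, P, S, "enc.bn2", h, training)
  h <- op_elu(tape, h)
  h <- op_avgpool_time(tape, h, cfg$pool_sizes[1])
  if (cfg$cbam) h <- cbam_forward_tape(tape, P, S, h, cfg, training)
  l1 <- h
  stage <- function(h, conv, bn, pool) {
    h <- op_conv1d(tape, h, leafp(tape, P, conv),
                   pad = same_pad(cfg$spatial_kernel))
    h <- bn_tape(tape, P, S, bn, h, training)
    h <- op_sigmoid(tape, h)
    op_avgpool_time(tape, h, pool)
  }
  l2 <- stage(l1, "enc.conv3.W", "enc.bn3", cfg$pool_sizes[2])
  l3 <- stage(l2, "enc.conv4.W", "enc.bn4", cfg$pool_sizes[3])
  levels <- list(l1, l2, l3)
  if (cfg$bifpn) {
    levels <- bifpn_forward_tape(tape, P, S, levels, cfg, training)
  }
  levels
}

with_seeded_params <- function(seed, builder) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  builder()
}

check_trials_array <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3) {
    stop("x must be a 3-d array (trials x channels x time)")
  }
}

#' Encode EEG trials into three band-limited time series
#'
#' Runs the temporal feature block: temporal convolution, depthwise
#' electrode convolution with pooling, optional CBAM attention, two further
#' temporal stages, and optional bidirectional feature pyramid fusion. The
#' three outputs are progressively downsampled time series with nominal
#' band labels 4-32, 4-16 and 4-8 Hz; one step at each level corresponds to
#' `prod(pool_sizes[1:k])` samples of the raw signal.
#'
#' @param x Numeric array (trials, channels, time).
#' @param cfg An [encoder_config()].
#' @param params Optional parameter list from a built model; if `NULL`,
#'   fresh weights are drawn with standard deviation `std` under `seed`.
#' @param std,seed Weight initialization used when `params` is `NULL`.
#' @return List of three arrays (trials, T_level, fused_dim) with a
#'   `band` attribute.
#' @export
encode <- function(x, cfg = encoder_config(), params = NULL,
                   std = 0.01, seed = 1L) {
  check_trials_array(x)
  ps <- if (is.null(params)) {
    with_seeded_params(seed, function() encoder_params(cfg, std))
  } else params
  tape <- ag_tape()
  levels <- encoder_forward_tape(tape, ps$P, ps$S, x, cfg, training = FALSE)
  out <- lapply(seq_along(levels), function(i) {
    v <- levels[[i]]$value  # (d, T, B)
    z <- aperm(v, c(3, 2, 1))
    attr(z, "band") <- band_labels[i]
    z
  })
  names(out) <- band_labels
  out
}

#' Temporal convolution stage
#'
#' First encoder stage: `f1` temporal filters of length `kernel` applied
#' per electrode with same-padding, followed by batch normalization
#' (evaluation-mode statistics for this standalone call).
#'
#' @param x Numeric array (trials, channels, time).
#' @param f1 Number of temporal filters.
#' @param kernel Kernel length; default derived from `sampling_rate`.
#' @param sampling_rate Sampling rate in Hz used when `kernel` is `NULL`.
#' @param weights Optional list with element `W` (f1 x 1 x kernel).
#' @param std,seed Initialization used when `weights` is `NULL`.
#' @return Array (trials, f1, channels, time).
#' @export
temporal_conv <- function(x, f1 = 16L, kernel = NULL, sampling_rate = 250,
                          weights = NULL, std = 0.01, seed = 1L) {
  check_trials_array(x)
  if (is.null(kernel)) kernel <- temporal_kernel_length(sampling_rate)
  dx <- dim(x)
  B <- dx[1]; C <- dx[2]; T_ <- dx[3]
  if (T_ < kernel) stop("trial length is shorter than the temporal kernel")
  W <- if (!is.null(weights)) weights$W else {
    with_seeded_params(seed, function() param_normal(c(f1, 1, kernel), std))
  }
  stopifnot(all(dim(W) == c(f1, 1, kernel)))
  xi <- aperm(x, c(3, 2, 1))
  dim(xi) <- c(1, T_, C * B)
  y <- cpp_conv1d_fwd(xi, 1L, T_, C * B, W, as.integer(f1),
                      as.integer(kernel), 1L, same_pad(kernel)[1],
                      same_pad(kernel)[2])
  st <- bn_state(f1)
  y <- cpp_bn_apply(y, as.integer(f1), st$running_mean,
                    1 / sqrt(st$running_var + st$eps), rep(1, f1),
                    numeric(f1))
  # (f1, T, C*B) -> (B, f1, C, T)
  dim(y) <- c(f1, T_, C, B)
  aperm(y, c(4, 1, 3, 2))
}

#' Depthwise electrode convolution stage
#'
#' Collapses the electrode axis with `depth_mult` spatial filters per
#' temporal map, applies batch normalization (evaluation-mode here), an ELU
#' nonlinearity and average pooling along time.
#'
#' @param x Numeric array (trials, f1, channels, time).
#' @param depth_mult Spatial filters per temporal map (D).
#' @param pool Average-pooling kernel along time.
#' @param weights Optional list with element `W` (channels x D x f1).
#' @param std,seed Initialization used when `weights` is `NULL`.
#' @return Array (trials, f1 * depth_mult, 1, floor(time / pool)).
#' @export
depthwise_spatial_conv <- function(x, depth_mult = 2L, pool = 8L,
                                   weights = NULL, std = 0.01, seed = 1L) {
  if (!is.array(x) || length(dim(x)) != 4) {
    stop("x must be a 4-d array (trials x f1 x channels x time)")
  }
  dx <- dim(x)
  B <- dx[1]; F1 <- dx[2]; C <- dx[3]; T_ <- dx[4]
  W <- if (!is.null(weights)) weights$W else {
    with_seeded_params(seed, function() {
      param_normal(c(C, depth_mult, F1), std)
    })
  }
  if (!all(dim(W) == c(C, depth_mult, F1))) {
    stop("weights$W must have dims (channels, depth_mult, f1)")
  }
  xi <- aperm(x, c(2, 4, 3, 1))  # (F1, T, C, B)
  dim(xi) <- c(F1, T_, C * B)
  y <- cpp_dwconv_fwd(xi, F1, T_, C, B, W, as.integer(depth_mult))
  d <- F1 * depth_mult
  st <- bn_state(d)
  y <- cpp_bn_apply(y, as.integer(d), st$running_mean,
                    1 / sqrt(st$running_var + st$eps), rep(1, d), numeric(d))
  y <- cpp_elu_fwd(y, 1)
  tape <- ag_tape()
  y <- op_avgpool_time(tape, ag_const(tape, y), as.integer(pool))$value
  T2 <- dim(y)[2]
  aperm(array(y, c(d, T2, 1, B)), c(4, 1, 3, 2))
}

#' Convolutional block attention (CBAM)
#'
#' Sequential channel-then-time multiplicative attention. Channel weights
#' are `sigmoid(MLP(avgpool) + MLP(maxpool))` with a shared
#' reduction-ratio MLP; time weights come from a small convolution over the
#' stacked channel-average and channel-maximum descriptors. All attention
#' coefficients lie strictly in (0, 1) and the output shape equals the
#' input shape.
#'
#' @param x Numeric array (trials, d, time) or (trials, d, 1, time).
#' @param reduction Channel MLP reduction ratio; must divide d.
#' @param spatial_kernel Kernel length of the time-attention convolution.
#' @param weights Optional list with `mlp1` (d/r x d), `mlp2` (d x d/r),
#'   `sp` (1 x 2 x spatial_kernel), `sp_b` (scalar).
#' @param std,seed Initialization used when `weights` is `NULL`.
#' @return Array with the same shape as `x`.
#' @export
cbam_attention <- function(x, reduction = 8L, spatial_kernel = 7L,
                           weights = NULL, std = 0.01, seed = 1L) {
  was4d <- length(dim(x)) == 4
  if (was4d) {
    stopifnot(dim(x)[3] == 1)
    x <- array(x[, , 1, ], dim(x)[c(1, 2, 4)])
  }
  check_trials_array(x)
  dx <- dim(x)
  B <- dx[1]; d <- dx[2]; T_ <- dx[3]
  if (d %% reduction != 0) stop("reduction must divide the channel count")
  hid <- d %/% reduction
  ws <- if (!is.null(weights)) weights else with_seeded_params(seed, {
    function() list(mlp1 = param_normal(c(hid, d), std),
                    mlp2 = param_normal(c(d, hid), std),
                    sp = param_normal(c(1, 2, spatial_kernel), std),
                    sp_b = 0)
  })
  cfg <- list(cbam_spatial_kernel = as.integer(spatial_kernel))
  P <- list(
    "enc.cbam.mlp1.W" = new_param(ws$mlp1),
    "enc.cbam.mlp2.W" = new_param(ws$mlp2),
    "enc.cbam.sp.W" = new_param(ws$sp),
    "enc.cbam.sp.b" = new_param(ws$sp_b)
  )
  tape <- ag_tape()
  h <- ag_const(tape, aperm(x, c(2, 3, 1)))
  out <- cbam_forward_tape(tape, P, list(), h, cfg, training = FALSE)
  y <- aperm(out$value, c(3, 1, 2))
  if (was4d) y <- aperm(array(y, c(B, d, T_, 1)), c(1, 2, 4, 3))
  y
}

#' Later temporal convolution stage
#'
#' Same-padded temporal convolution, batch normalization (evaluation-mode
#' here), sigmoid activation and average pooling; applied twice in the
#' encoder this produces the two coarser pyramid levels.
#'
#' @param x Numeric array (trials, d, time).
#' @param kernel Convolution kernel length.
#' @param pool Average-pooling kernel.
#' @param weights Optional list with element `W` (d x d x kernel).
#' @param std,seed Initialization used when `weights` is `NULL`.
#' @return Array (trials, d, floor(time / pool)).
#' @export
spatial_conv_stage <- function(x, kernel = 16L, pool = 2L, weights = NULL,
                               std = 0.01, seed = 1L) {
  check_trials_array(x)
  dx <- dim(x)
  B <- dx[1]; d <- dx[2]; T_ <- dx[3]
  if (T_ < pool) stop("time length must be at least the pooling kernel")
  W <- if (!is.null(weights)) weights$W else {
    with_seeded_params(seed, function() param_normal(c(d, d, kernel), std))
  }
  y <- cpp_conv1d_fwd(aperm(x, c(2, 3, 1)), as.integer(d), T_, B,
                      W, as.integer(d), as.integer(kernel), 1L,
                      same_pad(kernel)[1], same_pad(kernel)[2])
  st <- bn_state(d)
  y <- cpp_bn_apply(y, as.integer(d), st$running_mean,
                    1 / sqrt(st$running_var + st$eps), rep(1, d), numeric(d))
  y <- 1 / (1 + exp(-y))
  tape <- ag_tape()
  y <- op_avgpool_time(tape, ag_const(tape, y), as.integer(pool))$value
  aperm(y, c(3, 1, 2))
}

#' Bidirectional feature pyramid fusion
#'
#' One top-down then bottom-up pass over three pyramid levels with
#' fast-normalized fusion `O = sum_i relu(w_i) I_i / (eps + sum_j relu(w_j))`,
#' linear upsampling, average-pool downsampling, and a 1x1 convolution with
#' batch normalization (evaluation-mode here) at each fusion node. Output
#' lengths and channel counts equal the input ones.
#'
#' @param levels List of three arrays (trials, d, T1), (trials, d, T2),
#'   (trials, d, T3) with T2 = floor(T1/2), T3 = floor(T2/2).
#' @param eps Fusion stabilizer.
#' @param weights Optional list with `w` (list of 4 fusion-weight vectors
#'   named m2, m1, o2, o3) and `W` (list of 4 d x d x 1 conv kernels).
#' @param std,seed Initialization used when `weights` is `NULL`.
#' @return List of three fused arrays with the input shapes.
#' @export
bifpn_fuse <- function(levels, eps = 1e-4, weights = NULL,
                       std = 0.01, seed = 1L) {
  if (length(levels) != 3) stop("levels must contain three arrays")
  for (l in levels) check_trials_array(l)
  d <- dim(levels[[1]])[2]
  Ts <- vapply(levels, function(l) dim(l)[3], numeric(1))
  if (Ts[2] != Ts[1] %/% 2 || Ts[3] != Ts[2] %/% 2) {
    stop("pyramid levels must halve in length (floor) from fine to coarse")
  }
  nodes <- c("m2", "m1", "o2", "o3")
  ws <- if (!is.null(weights)) weights else with_seeded_params(seed, {
    function() list(
      w = list(m2 = rep(1, 2), m1 = rep(1, 2), o2 = rep(1, 3),
               o3 = rep(1, 2)),
      W = stats::setNames(lapply(nodes, function(nm) {
        param_normal(c(d, d, 1), std)
      }), nodes)
    )
  })
  P <- list()
  S <- list()
  for (nm in nodes) {
    P[[paste0("enc.fpn.", nm, ".w")]] <- new_param(ws$w[[nm]])
    P[[paste0("enc.fpn.", nm, ".W")]] <- new_param(ws$W[[nm]])
    r <- add_bn(P, S, paste0("enc.fpn.", nm, ".bn"), d, std)
    P <- r$P; S <- r$S
  }
  tape <- ag_tape()
  lv <- lapply(levels, function(l) ag_const(tape, aperm(l, c(2, 3, 1))))
  out <- bifpn_forward_tape(tape, P, S, lv,
                            list(bifpn_eps = eps), training = FALSE)
  lapply(out, function(n) aperm(n$value, c(3, 1, 2)))
}

#' Fast-normalized fusion coefficients
#'
#' Returns `relu(w) / (eps + sum(relu(w)))`; nonnegative and summing to at
#' most 1, approaching 1 as `eps` goes to 0.
#'
#' @param w Numeric vector of learned fusion scalars.
#' @param eps Stabilizer.
#' @return Numeric vector of coefficients.
#' @export
fusion_coefficients <- function(w, eps = 1e-4) {
  u <- pmax(w, 0)
  u / (eps + sum(u))
}
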