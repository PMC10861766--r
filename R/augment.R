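# Data enhancement operators: same-label mixing, additive Gaussian noise
# and amplitude scaling, applied online per batch during training (or
# offline through the command-line interface).

#' Augmentation parameters
#'
#' Ranges for the three enhancement operators. All draws are uniform
#' within their range: the mixing weight `w` in (0, 1), the noise level in
#' (0, 0.3) and the amplitude scale in (0.8, 1.2).
#'
#' @param w_range Mixing-weight range, inside (0, 1).
#' @param noise_level_range Noise-level range, inside (0, 0.3).
#' @param scale_range Amplitude-scale range, inside (0.8, 1.2).
#' @param apply_probability Per-trial probability of augmenting.
#' @param seed Optional seed; when `NULL` the surrounding RNG stream is
#'   used (so seeded training remains reproducible end to end).
#' @return Object of class `augment_params`.
#' @export
augment_params <- function(w_range = c(0, 1),
                           noise_level_range = c(0, 0.3),
                           scale_range = c(0.8, 1.2),
                           apply_probability = 1.0, seed = NULL) {
  chk <- function(r, lo, hi, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      stop(sprintf("%s must be an ordered pair within (%g, %g)",
                   nm, lo, hi))
    }
  }
  chk(w_range, 0, 1, "w_range")
  chk(noise_level_range, 0, 0.3, "noise_level_range")
  chk(scale_range, 0.8, 1.2, "scale_range")
  stopifnot(apply_probability >= 0, apply_probability <= 1)
  structure(list(w_range = w_range,
                 noise_level_range = noise_level_range,
                 scale_range = scale_range,
                 apply_probability = apply_probability,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "augment_params")
}

#' Mix two same-label trials
#'
#' Elementwise convex combination `w * x1 + (1 - w) * x2`. The output lies
#' in the elementwise interval hull of the two trials.
#'
#' @param x1,x2 Numeric arrays of identical shape (one trial each).
#' @param w Mixing weight in `[0, 1]`.
#' @param label1,label2 Optional labels; mixing trials with different
#'   labels is an error.
#' @return The mixed trial.
#' @export
mix_same_label <- function(x1, x2, w, label1 = NULL, label2 = NULL) {
  if (!identical(dim(x1), dim(x2)) || length(x1) != length(x2)) {
    stop("x1 and x2 must share shape")
  }
  if (!is.null(label1) && !is.null(label2) && !identical(label1, label2)) {
    stop("trials must share the same label")
  }
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  w * x1 + (1 - w) * x2
}

#' Add scaled Gaussian noise
#'
#' Returns `x + noise_level * n` with `n` i.i.d. standard normal of the
#' same shape as `x`.
#'
#' @param x Numeric array (one trial).
#' @param noise_level Nonnegative noise amplitude.
#' @param seed Optional seed for a reproducible draw.
#' @return The noised trial.
#' @export
add_noise <- function(x, noise_level, seed = NULL) {
  if (noise_level < 0) stop("noise_level must be nonnegative")
  if (noise_level == 0) return(x)
  draw <- function() {
    n <- stats::rnorm(length(x))
    dim(n) <- dim(x)
    x + noise_level * n
  }
  if (is.null(seed)) draw() else with_seeded_params(seed, draw)
}

#' Scale a trial's amplitude
#'
#' Elementwise multiplication by a positive factor.
#'
#' @param x Numeric array (one trial).
#' @param s Positive scale factor.
#' @return The scaled trial.
#' @export
scale_signal <- function(x, s) {
  if (s <= 0) stop("scale must be positive")
  x * s
}

#' Augment a labeled batch of trials
#'
#' For each selected trial: mix with a uniformly drawn same-label partner
#' (excluding itself), add Gaussian noise, then scale, with `w`,
#' `noise_level` and `scale` drawn uniformly from their configured ranges.
#' Labels and batch size are unchanged. Trials whose class has no partner
#' skip the mixing step (with a warning).
#'
#' @param x Numeric array (trials, channels, time).
#' @param labels Integer label vector.
#' @param params An [augment_params()].
#' @return List with augmented `data` and unchanged `labels`.
#' @export
augment_batch <- function(x, labels, params = augment_params()) {
  check_trials_array(x)
  B <- dim(x)[1]
  if (length(labels) != B) stop("labels must match the number of trials")
  run <- function() {
    out <- x
    singleton_seen <- FALSE
    apply_mask <- stats::runif(B) < params$apply_probability
    for (i in seq_len(B)) {
      if (!apply_mask[i]) next
      xi <- x[i, , ]
      mates <- which(labels == labels[i])
      mates <- mates[mates != i]
      if (length(mates) == 0) {
        singleton_seen <- TRUE
      } else {
        j <- mates[sample.int(length(mates), 1)]
        w <- stats::runif(1, params$w_range[1], params$w_range[2])
        xi <- mix_same_label(xi, x[j, , ], w)
      }
      nl <- stats::runif(1, params$noise_level_range[1],
                         params$noise_level_range[2])
      xi <- xi + nl * array(stats::rnorm(length(xi)), dim(xi))
      s <- stats::runif(1, params$scale_range[1], params$scale_range[2])
      out[i, , ] <- xi * s
    }
    if (singleton_seen) {
      warning("some classes had a single trial; mixing skipped for those")
    }
    list(data = out, labels = labels)
  }
  if (is.null(params$seed)) run() else with_seeded_params(params$seed, run)
}
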