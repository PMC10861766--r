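# Temporal convolutional (TC) block: stacked residual blocks of two
# dilated causal convolutions each (dilation doubling per block), with
# batch normalization, ELU and dropout. Causal left-padding keeps the
# sequence length and guarantees outputs depend only on current and past
# inputs.

#' Temporal convolution block configuration
#'
#' @param n_blocks Number of residual blocks L; block l uses dilation
#'   `2^(l-1)` in both of its convolutions.
#' @param kernel Convolution kernel size K_T.
#' @param filters Channel count of every convolution.
#' @param dropout Dropout probability after each convolution.
#' @param enabled If `FALSE` the block is an identity map (ablation).
#' @return Object of class `tcn_config`.
#' @export
tcn_config <- function(n_blocks = 2L, kernel = 4L, filters = 32L,
                       dropout = 0.12, enabled = TRUE) {
  stopifnot(n_blocks >= 1, kernel >= 1, filters >= 1,
            dropout >= 0, dropout < 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 kernel = as.integer(kernel),
                 filters = as.integer(filters),
                 dropout = dropout, enabled = isTRUE(enabled)),
            class = "tcn_config")
}

#' Receptive field size of the temporal convolution block
#'
#' With kernel size K_T and L residual blocks (two dilated causal
#' convolutions per block, dilation doubling per block), one output element
#' depends on `1 + 2 (K_T - 1)(2^L - 1)` past sequence elements. The
#' default configuration (K_T = 4, L = 2) has a receptive field of 19.
#'
#' @param kernel Convolution kernel size K_T (>= 1).
#' @param n_blocks Number of residual blocks L (>= 1).
#' @return Integer receptive field size in sequence elements.
#' @examples
#' receptive_field_size(4, 2) # 19
#' @export
receptive_field_size <- function(kernel, n_blocks) {
  if (kernel < 1 || n_blocks < 1) stop("kernel and n_blocks must be >= 1")
  as.integer(1 + 2 * (kernel - 1) * (2^n_blocks - 1))
}

tcn_params <- function(prefix, d_in, cfg, std) {
  P <- list()
  fin <- d_in
  for (l in seq_len(cfg$n_blocks)) {
    for (j in 1:2) {
      key <- paste0(prefix, ".tc.b", l, ".conv", j, ".W")
      P[[key]] <- new_param(
        param_normal(c(cfg$filters, if (j == 1) fin else cfg$filters,
                       cfg$kernel), std), key)
      bkey <- paste0(prefix, ".tc.b", l, ".bn", j)
      P[[paste0(bkey, ".gamma")]] <- new_param(rep(1, cfg$filters),
                                               paste0(bkey, ".gamma"))
      P[[paste0(bkey, ".beta")]] <- new_param(numeric(cfg$filters),
                                              paste0(bkey, ".beta"))
    }
    if (fin != cfg$filters) {
      key <- paste0(prefix, ".tc.b", l, ".proj.W")
      P[[key]] <- new_param(param_normal(c(cfg$filters, fin, 1), std), key)
    }
    fin <- cfg$filters
  }
  P
}

tcn_forward_tape <- function(tape, P, S, x, cfg, training, prefix) {
  h <- x
  fin <- dim(x$value)[1]
  for (l in seq_len(cfg$n_blocks)) {
    dil <- 2L^(l - 1L)
    res <- h
    for (j in 1:2) {
      h <- op_conv1d(tape, h,
                     leafp(tape, P, paste0(prefix, ".tc.b", l, ".conv", j,
                                           ".W")),
                     dilation = dil, pad = causal_pad(cfg$kernel, dil))
      h <- bn_tape(tape, P, S, paste0(prefix, ".tc.b", l, ".bn", j), h,
                   training)
      h <- op_elu(tape, h)
      h <- op_dropout(tape, h, cfg$dropout, training)
    }
    if (fin != cfg$filters) {
      res <- op_conv1d(tape, res,
                       leafp(tape, P, paste0(prefix, ".tc.b", l, ".proj.W")))
    }
    h <- op_add(tape, res, h)
    fin <- cfg$filters
  }
  h
}

#' Run the temporal convolution block on one sequence
#'
#' Evaluation-mode forward pass of the dilated causal residual stack: the
#' output at time `t` depends only on inputs at times `<= t`, and on at
#' most [receptive_field_size()] of them.
#'
#' @param x Numeric matrix (T x filters_in).
#' @param cfg A [tcn_config()].
#' @param weights Optional named list of weight arrays, as produced by the
#'   internal parameter builder: elements `tc.b<l>.conv<j>.W`
#'   (filters x in x kernel), `tc.b<l>.bn<j>.gamma` / `.beta`, and
#'   `tc.b<l>.proj.W` when `filters_in != filters`.
#' @param std,seed Initialization used when `weights` is `NULL`.
#' @return Numeric matrix (T x filters).
#' @export
tcn_forward <- function(x, cfg = tcn_config(), weights = NULL,
                        std = 0.01, seed = 1L) {
  if (!is.matrix(x)) stop("x must be a matrix (time x features)")
  fin <- ncol(x)
  P <- if (is.null(weights)) {
    with_seeded_params(seed, function() tcn_params("br", fin, cfg, std))
  } else {
    ps <- list()
    for (nm in names(weights)) {
      ps[[paste0("br.", nm)]] <- new_param(weights[[nm]])
    }
    ps
  }
  S <- branch_states("br", cfg)
  tape <- ag_tape()
  xn <- ag_const(tape, array(t(x), c(fin, nrow(x), 1)))
  out <- tcn_forward_tape(tape, P, S, xn, cfg, training = FALSE,
                          prefix = "br")
  t(matrix(out$value, cfg$filters, nrow(x)))
}
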