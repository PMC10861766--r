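# Small configurations used across tests to keep runtimes down; the
# acceptance tests use the full default configuration.

tiny_encoder <- function(n_channels = 4L) {
  encoder_config(n_channels = n_channels, sampling_rate = 128,
                 f1 = 4L, depth_mult = 2L, fused_dim = 8L,
                 cbam_reduction = 4L, spatial_kernel = 5L)
}

tiny_config <- function(n_classes = 3L, n_channels = 4L, ...) {
  model_config(encoder = tiny_encoder(n_channels),
               at = attention_config(n_heads = 2L, head_dim = 4L),
               tc = tcn_config(n_blocks = 2L, kernel = 3L, filters = 8L),
               n_windows = 3L, fc_dims = c(6L, 5L), n_classes = n_classes,
               ...)
}

tiny_trials <- function(B = 3L, C = 4L, T_ = 160L, seed = 1L) {
  set.seed(seed)
  array(stats::rnorm(B * C * T_), c(B, C, T_))
}

tiny_synth <- function(n_per_class = 12L, n_channels = 8L, T_ = 320L,
                       snr = 2, seed = 7L, n_classes = 4L) {
  synth_spec(n_classes = n_classes, n_trials_per_class = n_per_class,
             n_channels = n_channels, sampling_rate = 250,
             trial_seconds = T_ / 250, snr = snr, seed = seed)
}

# stratified split: n_test trials per class
split_by_class <- function(labels, n_test, seed = 99L) {
  set.seed(seed)
  test_i <- unlist(lapply(sort(unique(labels)), function(k) {
    i <- which(labels == k)
    sample(i, n_test)
  }))
  list(train = setdiff(seq_along(labels), test_i), test = test_i)
}
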