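# Shared fixtures: small cohorts and synthetic feature matrices built in
# code at test time.

tiny_config <- function(..., seed = 1) {
  sim_config(n_participants = 2, n_sessions = 1, n_sets_per_session = 1,
             seed = seed, ...)
}

# feature matrix with fabricated values: `channels` single-channel
# columns, optional planted channel separating the two classes
synthetic_fm <- function(n_per_class = 12, channels = LETTERS[1:5],
                         planted = NULL, effect = 2, seed = 1,
                         labels = c("0-back", "3-back")) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(labels, each = n_per_class)
  vals <- matrix(rnorm(n * length(channels)), n, length(channels))
  if (!is.null(planted)) {
    i <- match(planted, channels)
    vals[lab == labels[2], i] <- vals[lab == labels[2], i] + effect
  }
  blocks <- list(list(
    values = vals,
    descriptors = feature_descriptors(modality = "eeg-psd", band = "alpha",
                                      channel = channels, window = "w0+40")))
  meta <- data.frame(participant = rep(1:2, length.out = n),
                     session = 1, series = 1)
  assemble_features(blocks, lab, meta)
}

# band-limited noise for estimator tests
bl_noise <- function(n, rate, low, high, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n)
  butter_filter(x, "bandpass", c(low, high), 3, rate = rate)
}
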