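# Spectral building blocks: Welch periodogram averaging and the
# analytic-signal phase. These back the band-power, coherence and
# phase-locking estimators.

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Segment start indices for Welch averaging at a given overlap.
welch_starts <- function(n, seg_len, overlap = 0.5) {
  hop <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  if (!length(starts)) starts <- 1L
  starts
}

# One-sided windowed segment FFTs. x: channels x samples matrix (or a
# vector). Returns list(freq, X = array n_freq x n_seg x n_chan, scale)
# where sum over freq of |X|^2 * scale gives the Welch PSD estimate
# normalisation (density, power per Hz).
welch_segments <- function(x, rate, seg_len = NULL, overlap = 0.5) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (is.null(seg_len)) seg_len <- min(n, round(2 * rate))
  seg_len <- min(seg_len, n)
  w <- hann_window(seg_len)
  starts <- welch_starts(n, seg_len, overlap)
  n_freq <- floor(seg_len / 2) + 1L
  X <- array(0i, dim = c(n_freq, length(starts), nrow(x)))
  for (ci in seq_len(nrow(x))) {
    for (si in seq_along(starts)) {
      seg <- x[ci, starts[si]:(starts[si] + seg_len - 1L)] * w
      X[, si, ci] <- stats::fft(seg)[seq_len(n_freq)]
    }
  }
  freq <- (seq_len(n_freq) - 1L) * rate / seg_len
  # density scaling: one-sided doubling applied downstream
  scale <- 1 / (rate * sum(w^2))
  list(freq = freq, X = X, scale = scale, seg_len = seg_len,
       n_seg = length(starts))
}

# Welch auto power spectral density. Returns list(freq, psd) with psd a
# channels x n_freq matrix in power-per-Hz units (one-sided).
welch_psd <- function(x, rate, seg_len = NULL, overlap = 0.5) {
  ws <- welch_segments(x, rate, seg_len, overlap)
  n_freq <- length(ws$freq)
  n_chan <- dim(ws$X)[3]
  psd <- matrix(0, n_chan, n_freq)
  for (ci in seq_len(n_chan)) {
    P <- rowMeans(Mod(ws$X[, , ci, drop = FALSE])^2, dims = 1)
    psd[ci, ] <- P * ws$scale
  }
  # one-sided: double everything except DC (and Nyquist when present)
  dbl <- rep(2, n_freq); dbl[1] <- 1
  if (ws$seg_len %% 2 == 0) dbl[n_freq] <- 1
  psd <- sweep(psd, 2, dbl, `*`)
  rownames(psd) <- rownames(x)
  list(freq = ws$freq, psd = psd)
}

# Analytic signal by frequency-domain construction; x a numeric vector.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Instantaneous phase of each row of a (band-limited) matrix.
instantaneous_phase <- function(x) {
  if (!is.matrix(x)) return(Arg(analytic_signal(x)))
  t(apply(x, 1, function(r) Arg(analytic_signal(r))))
}
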