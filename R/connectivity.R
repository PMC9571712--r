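#' Pearson correlation between two channel series
#'
#' Linear time-domain interdependence, the sample version of
#' `E[(x - mu_x)(y - mu_y)] / (sigma_x sigma_y)`.
#'
#' @param x,y equal-length numeric series.
#' @return correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(x, y)
}

#' Magnitude-squared coherence averaged over a band
#'
#' Welch-averaged coherence `|Sxy(f)|^2 / (Sxx(f) Syy(f))`, reduced to a
#' scalar by the mean over frequency bins inside the band. Coherence is
#' identically 1 from a single segment, so at least two averaging
#' segments are required.
#'
#' @param x,y equal-length series.
#' @param rate sampling rate in Hz.
#' @param band a [band_spec()].
#' @param n_segments number of Welch segments (>= 2), 50% overlap.
#' @return scalar coherence in \[0, 1\].
#' @export
msc <- function(x, y, rate, band, n_segments = 8) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (n_segments < 2) stop("coherence needs at least 2 averaging segments")
  n <- length(x)
  seg_len <- max(8L, floor(2 * n / (n_segments + 1)))
  ws <- welch_segments(rbind(x, y), rate, seg_len = seg_len, overlap = 0.5)
  msc_from_segments(ws, band, 1L, 2L)
}

msc_from_segments <- function(ws, band, i, j) {
  Xi <- ws$X[, , i]; Xj <- ws$X[, , j]
  if (is.null(dim(Xi))) { Xi <- matrix(Xi, ncol = 1); Xj <- matrix(Xj, ncol = 1) }
  Sxy <- rowMeans(Xi * Conj(Xj))
  Sxx <- rowMeans(Mod(Xi)^2)
  Syy <- rowMeans(Mod(Xj)^2)
  coh <- Mod(Sxy)^2 / pmax(Sxx * Syy, .Machine$double.eps)
  sel <- ws$freq >= band$low & ws$freq <= band$high
  if (!any(sel)) stop("no frequency bins inside the band; window too short")
  mean(coh[sel])
}

#' Histogram mutual information between two series
#'
#' Plug-in estimate from an equal-width joint histogram: each series is
#' discretised over its own range into `n_bins` bins; entropies use the
#' convention `0 log 0 = 0`. Zero iff the binned variables are
#' independent; a nonlinear time-domain dependence measure.
#'
#' @param x,y equal-length series.
#' @param n_bins bins per axis (>= 2); default `ceiling(sqrt(N))`
#'   capped at 32.
#' @param base logarithm base (2 = bits).
#' @return mutual information (>= 0) in `log base` units.
#' @export
mutual_information <- function(x, y, n_bins = NULL, base = 2) {
  if (!length(x) || length(x) != length(y))
    stop("series must be non-empty and of equal length")
  if (is.null(n_bins)) n_bins <- min(32L, ceiling(sqrt(length(x))))
  if (n_bins < 2) stop("n_bins must be >= 2")
  ix <- discretize_series(x, n_bins)
  iy <- discretize_series(y, n_bins)
  mi_from_joint(joint_counts(ix, iy, n_bins), base)
}

# Equal-width binning over the series' own range; constant series land
# in bin 1 (zero entropy).
discretize_series <- function(x, n_bins) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  i <- floor((x - r[1]) / (r[2] - r[1]) * n_bins) + 1L
  pmin(i, n_bins)
}

joint_counts <- function(ix, iy, n_bins) {
  matrix(tabulate((ix - 1L) + n_bins * (iy - 1L) + 1L, n_bins * n_bins),
         n_bins, n_bins)
}

entropy_from_counts <- function(counts, base = 2) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p, base))
}

mi_from_joint <- function(joint, base = 2) {
  hx <- entropy_from_counts(rowSums(joint), base)
  hy <- entropy_from_counts(colSums(joint), base)
  hxy <- entropy_from_counts(joint, base)
  max(0, hx + hy - hxy)
}

#' Phase-locking value between two band-limited series
#'
#' Magnitude of the mean unit phasor of the instantaneous phase
#' difference, `|mean(exp(i (phi_x - phi_y)))|`. Phases come from the
#' analytic (Hilbert) signal after band-pass filtering; 10% of samples
#' are trimmed from each edge before averaging to suppress end effects.
#'
#' @param x,y equal-length series.
#' @param rate sampling rate in Hz.
#' @param band a [band_spec()]; the series are filtered to this band
#'   before phase extraction unless `filtered = TRUE`.
#' @param filtered set `TRUE` if `x`/`y` are already band-limited.
#' @return phase-locking value in \[0, 1\]; 1 means strict phase
#'   synchronisation.
#' @export
plv <- function(x, y, rate, band, filtered = FALSE) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3 * rate / band$low)
    stop("window shorter than 3 cycles of the band's low edge")
  if (!filtered) {
    x <- butter_filter(x, "bandpass", c(band$low, band$high), 3, rate = rate)
    y <- butter_filter(y, "bandpass", c(band$low, band$high), 3, rate = rate)
  }
  px <- Arg(analytic_signal(x))
  py <- Arg(analytic_signal(y))
  plv_from_phase(px, py)
}

plv_from_phase <- function(px, py, trim = 0.1) {
  n <- length(px)
  keep <- (floor(n * trim) + 1L):(n - floor(n * trim))
  Mod(mean(exp(1i * (px[keep] - py[keep]))))
}

#' Functional connectivity matrix of a segment
#'
#' Applies one estimator (PCC, MSC, MI or PLV) to every unordered
#' channel pair of the band-filtered segment and fills a symmetric
#' channels-by-channels matrix. Diagonals follow the estimator's
#' self-similarity convention: 1 for PCC/MSC/PLV, the per-channel
#' binned entropy H(x) for MI.
#'
#' @param seg a [segment()] (broadband; filtering to `band` happens
#'   here) with at least two channels.
#' @param estimator `"pcc"`, `"msc"`, `"mi"` or `"plv"`.
#' @param band a [band_spec()].
#' @param n_bins MI histogram bins (default as in
#'   [mutual_information()]).
#' @return object of class `connectivity_matrix`: list with `values`
#'   (symmetric matrix), `estimator`, `band`, `channels`.
#' @export
connectivity_matrix <- function(seg, estimator = c("pcc", "msc", "mi", "plv"),
                                band, n_bins = NULL) {
  estimator <- match.arg(estimator)
  if (nrow(seg$data) < 2) stop("connectivity needs at least 2 channels")
  vals <- fbc_matrix(seg$data, seg$rate, band, estimator, n_bins)
  structure(list(values = vals, estimator = estimator, band = band$name,
                 channels = seg$channels,
                 window = c(start = seg$start, length = seg$length)),
            class = "connectivity_matrix")
}

# All-pairs estimator core on a channels x samples matrix. Channels are
# band-filtered once per band; pairwise statistics reuse the shared
# per-channel transforms (phases, segment FFTs, bin indices). Returns a
# named list of symmetric matrices, one per requested estimator.
fbc_matrices <- function(data, rate, band, estimators, n_bins = NULL) {
  C <- nrow(data)
  dn <- list(rownames(data), rownames(data))
  out <- list()
  need_filt <- any(estimators %in% c("pcc", "plv", "mi"))
  if (need_filt)
    filt <- butter_filter(data, "bandpass", c(band$low, band$high), 3,
                          rate = rate)
  if ("pcc" %in% estimators) {
    sds <- apply(filt, 1, stats::sd)
    if (any(sds == 0)) stop("correlation undefined for constant channel")
    M <- stats::cor(t(filt))
    out$pcc <- (M + t(M)) / 2
  }
  if ("plv" %in% estimators) {
    ph <- instantaneous_phase(filt)
    n <- ncol(ph)
    keep <- (floor(n * 0.1) + 1L):(n - floor(n * 0.1))
    Z <- exp(1i * t(ph[, keep, drop = FALSE]))
    M <- Mod(crossprod(Conj(Z), Z)) / length(keep)
    out$plv <- (M + t(M)) / 2  # exact symmetry against rounding order
  }
  if ("mi" %in% estimators) {
    n <- ncol(filt)
    nb <- if (is.null(n_bins)) min(32L, ceiling(sqrt(n))) else n_bins
    bins <- apply(filt, 1, discretize_series, n_bins = nb)  # n x C
    M <- matrix(0, C, C)
    for (i in seq_len(C)) for (j in i:C)
      M[i, j] <- M[j, i] <-
        mi_from_joint(joint_counts(bins[, i], bins[, j], nb))
    out$mi <- M
  }
  if ("msc" %in% estimators) {
    n <- ncol(data)
    seg_len <- max(8L, floor(2 * n / 9))  # 8 segments at 50% overlap
    ws <- welch_segments(data, rate, seg_len = seg_len, overlap = 0.5)
    sel <- which(ws$freq >= band$low & ws$freq <= band$high)
    if (!length(sel)) stop("no frequency bins inside the band; window too short")
    coh_sum <- matrix(0, C, C)
    Sauto <- matrix(0, length(sel), C)
    for (ci in seq_len(C))
      Sauto[, ci] <- rowMeans(Mod(ws$X[sel, , ci, drop = FALSE])^2, dims = 1)
    for (fi in seq_along(sel)) {
      Xf <- matrix(ws$X[sel[fi], , ], nrow = ws$n_seg)  # n_seg x C
      Sxy <- crossprod(Conj(Xf), Xf) / ws$n_seg         # C x C cross-spectra
      denom <- pmax(outer(Sauto[fi, ], Sauto[fi, ]), .Machine$double.eps)
      coh_sum <- coh_sum + Mod(Sxy)^2 / denom
    }
    M <- coh_sum / length(sel)
    out$msc <- (M + t(M)) / 2  # exact symmetry against rounding order
  }
  lapply(out[estimators], function(M) { dimnames(M) <- dn; M })
}

fbc_matrix <- function(data, rate, band, estimator, n_bins = NULL) {
  fbc_matrices(data, rate, band, estimator, n_bins)[[estimator]]
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s / %s band: %d x %d channels\n",
              x$estimator, x$band, nrow(x$values), ncol(x$values)))
  invisible(x)
}
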