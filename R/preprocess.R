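#' Zero-phase Butterworth filtering
#'
#' Designs a Butterworth filter and applies it forward-backward
#' (zero-phase), preserving phase relationships for downstream
#' phase-locking estimation. The canonical settings are a third-order
#' 1-45 Hz bandpass for EEG and a third-order 0.04 Hz low-pass for
#' fNIRS concentration signals.
#'
#' @param rec a [recording()] or numeric matrix/vector.
#' @param kind `"lowpass"` or `"bandpass"`.
#' @param edges cutoff (low-pass) or `c(low, high)` (bandpass), Hz.
#' @param order filter order (>= 1).
#' @param rate sampling rate in Hz; taken from `rec` when it is a
#'   recording.
#' @return filtered object of the same shape and class.
#' @export
butter_filter <- function(rec, kind = c("lowpass", "bandpass"), edges,
                          order = 3, rate = NULL) {
  kind <- match.arg(kind)
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  is_rec <- inherits(rec, "recording")
  if (is_rec) rate <- rec$rate
  if (is.null(rate) || rate <= 0) stop("a positive sampling rate is required")
  nyq <- rate / 2
  if (kind == "lowpass") {
    if (length(edges) != 1L) stop("lowpass takes a single cutoff")
    if (edges <= 0 || edges >= nyq) stop("cutoff must lie in (0, Nyquist)")
    bf <- signal::butter(order, edges / nyq, type = "low")
  } else {
    if (length(edges) != 2L || edges[1] >= edges[2])
      stop("bandpass takes c(low, high) with low < high")
    if (edges[1] <= 0 || edges[2] >= nyq)
      stop("band edges must lie in (0, Nyquist)")
    bf <- signal::butter(order, edges / nyq, type = "pass")
  }
  low_edge <- edges[1]
  filt1 <- function(x) zero_phase(bf, x, rate, low_edge)
  if (is_rec) {
    out <- rec
    out$data <- t(apply(rec$data, 1, filt1))
    dimnames(out$data) <- dimnames(rec$data)
    return(out)
  }
  if (is.matrix(rec)) {
    out <- t(apply(rec, 1, filt1))
    dimnames(out) <- dimnames(rec)
    return(out)
  }
  filt1(rec)
}

# Forward-backward filtering with odd-reflection padding at both ends,
# so edge transients settle inside the padding and the operation
# commutes with time reversal to numerical precision.
zero_phase <- function(bf, x, rate, low_edge) {
  n <- length(x)
  L <- min(n - 1L, max(300L, ceiling(10 * rate / low_edge)))
  pre <- 2 * x[1] - x[(L + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - L)]
  z <- c(pre, x, post)
  z <- signal::filter(bf, z)
  z <- rev(signal::filter(bf, rev(z)))
  z[(L + 1L):(L + n)]
}

#' Resample a recording
#'
#' Rational-ratio polyphase resampling with anti-alias filtering on
#' downsampling; the EEG pathway standardises recordings to 200 Hz.
#'
#' @param rec a [recording()] or numeric vector/matrix.
#' @param target target rate in Hz (> 0).
#' @param rate input rate when `rec` is not a recording.
#' @return resampled object; duration preserved within one sample.
#' @export
resample_recording <- function(rec, target, rate = NULL) {
  if (target <= 0) stop("target rate must be positive")
  is_rec <- inherits(rec, "recording")
  if (is_rec) rate <- rec$rate
  if (is.null(rate) || rate <= 0) stop("a positive input rate is required")
  if (isTRUE(all.equal(rate, target))) return(rec)
  res1 <- function(x) {
    n <- length(x)
    if (target < rate) {  # anti-alias before decimating
      bf <- signal::butter(4, 0.9 * target / rate, type = "low")
      x <- zero_phase(bf, x, rate, 0.45 * target)
    }
    n_out <- round(n * target / rate)
    t_in <- (seq_len(n) - 1) / rate
    t_out <- (seq_len(n_out) - 1) / target
    stats::spline(t_in, x, xout = t_out, method = "fmm")$y
  }
  if (is_rec) {
    out <- rec
    out$data <- t(apply(rec$data, 1, res1))
    rownames(out$data) <- rownames(rec$data)
    out$rate <- target
    return(out)
  }
  if (is.matrix(rec)) return(t(apply(rec, 1, res1)))
  res1(rec)
}

#' Modified Beer-Lambert conversion of optical density to HbO/HbR
#'
#' Solves, per channel and sample, the 2x2 linear system
#' `dOD_lambda = (eps_HbO,lambda * dHbO + eps_HbR,lambda * dHbR) * d * DPF_lambda`
#' for the two chromophore concentration changes.
#'
#' Default extinction coefficients are textbook values for 760/850 nm in
#' 1/(mM cm); source-detector distance 3 cm, differential pathlength
#' factor 6 at both wavelengths. All are configurable.
#'
#' @param od1,od2 optical-density [recording()]s (or matrices) at the
#'   first and second wavelength, channels x samples.
#' @param extinction 2x2 matrix, rows = wavelengths, columns =
#'   c(HbO, HbR), units 1/(mM cm).
#' @param distance source-detector distance in cm.
#' @param dpf length-2 differential pathlength factors.
#' @return list with `hbo` and `hbr` (same container type as the input).
#' @export
mbll <- function(od1, od2,
                 extinction = matrix(c(0.1486, 0.3843,
                                       0.2526, 0.1798),
                                     nrow = 2, byrow = TRUE,
                                     dimnames = list(c("760nm", "850nm"),
                                                     c("HbO", "HbR"))),
                 distance = 3, dpf = c(6, 6)) {
  if (distance <= 0 || any(dpf <= 0)) stop("distance and dpf must be positive")
  A <- extinction * distance * dpf
  det_a <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det_a) < 1e-12) stop("extinction matrix is singular")
  m1 <- if (inherits(od1, "recording")) od1$data else as.matrix(od1)
  m2 <- if (inherits(od2, "recording")) od2$data else as.matrix(od2)
  if (!identical(dim(m1), dim(m2))) stop("wavelength matrices must match")
  Ainv <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2, 2) / det_a
  hbo <- Ainv[1, 1] * m1 + Ainv[1, 2] * m2
  hbr <- Ainv[2, 1] * m1 + Ainv[2, 2] * m2
  if (inherits(od1, "recording")) {
    ro <- od1; ro$data <- hbo; ro$modality <- "hbo"
    rr <- od1; rr$data <- hbr; rr$modality <- "hbr"
    return(list(hbo = ro, hbr = rr))
  }
  list(hbo = hbo, hbr = hbr)
}

#' Ocular-artifact removal hook
#'
#' Placeholder stage in the EEG pathway where a blind-source artifact
#' rejection algorithm would run; the default is an identity
#' pass-through so pipelines keep the same shape with or without an
#' external cleaner.
#'
#' @param rec a [recording()].
#' @param method `"none"` (identity) or a function `recording ->
#'   recording`.
#' @return a [recording()].
#' @export
remove_artifacts <- function(rec, method = "none") {
  if (is.function(method)) return(method(rec))
  if (!identical(method, "none")) stop("unknown artifact-removal method")
  rec
}

#' Median-baseline correction of a segment
#'
#' Subtracts, per channel, the median of a pre-stimulus baseline
#' interval from the segment, removing intra-individual offsets in the
#' hemodynamic signals.
#'
#' @param seg a [segment()].
#' @param rec the [recording()] the segment came from.
#' @param task_onset task onset in seconds within `rec`.
#' @param baseline_interval `c(from, to)` in seconds relative to the
#'   task onset, default -5..0 s.
#' @return the corrected [segment()].
#' @export
baseline_correct <- function(seg, rec, task_onset,
                             baseline_interval = c(-5, 0)) {
  if (diff(baseline_interval) <= 0) stop("empty baseline interval")
  i0 <- floor((task_onset + baseline_interval[1]) * rec$rate) + 1L
  i1 <- floor((task_onset + baseline_interval[2]) * rec$rate)
  if (i0 < 1 || i1 > ncol(rec$data) || i1 < i0)
    stop("baseline interval outside the recording")
  med <- apply(rec$data[seg$channels, i0:i1, drop = FALSE], 1, stats::median)
  seg$data <- seg$data - med
  seg
}

#' Candidate window start offsets
#'
#' Starts spaced by `step` within `offset_range` (seconds, half-open
#' windows `[start, start + win_len)`).
#'
#' @param win_len,step window length and stride, seconds.
#' @param offset_range `c(first, last)` permissible starts, seconds.
#' @return numeric vector of window starts.
#' @export
window_starts <- function(win_len, step, offset_range) {
  if (offset_range[2] < offset_range[1]) stop("empty offset range")
  seq(offset_range[1], offset_range[2], by = step)
}

#' Sliding-window segmentation around task events
#'
#' Cuts one [segment()] per (task, window start); the canonical fNIRS
#' augmentation uses 5 s windows stepped by 1 s through the 40 s task
#' period. Window starts are relative to each task onset; windows that
#' would run past the end of the recording are skipped with a warning.
#'
#' @param rec a [recording()].
#' @param events event table rows for this recording (session-relative
#'   `onset` seconds).
#' @param win_len,step window length and stride in seconds.
#' @param offset_range `c(first, last)` window starts in seconds
#'   relative to task onset; default covers the 40 s task with the
#'   given window length.
#' @param channels optional channel subset.
#' @return list of [segment()]s.
#' @export
sliding_segments <- function(rec, events, win_len = 5, step = 1,
                             offset_range = NULL, channels = NULL) {
  if (win_len <= 0) stop("win_len must be positive")
  if (is.null(offset_range))
    offset_range <- c(0, max(0, events$duration[1] - win_len))
  starts <- window_starts(win_len, step, offset_range)
  if (is.null(channels)) channels <- rec$channels
  segs <- list()
  n <- ncol(rec$data)
  dropped <- 0L
  for (ti in seq_len(nrow(events))) {
    for (st in starts) {
      t0 <- events$onset[ti] + st
      i0 <- round(t0 * rec$rate) + 1L
      i1 <- i0 + round(win_len * rec$rate) - 1L
      if (i0 < 1 || i1 > n) { dropped <- dropped + 1L; next }
      segs[[length(segs) + 1L]] <- segment(
        rec$data[channels, i0:i1, drop = FALSE], rec$rate,
        start = st, length = win_len, label = events$label[ti],
        participant = events$participant[ti], session = events$session[ti],
        series = events$series[ti], channels = channels)
    }
  }
  if (dropped > 0L)
    warning(sprintf("%d window(s) exceeded the recording and were skipped",
                    dropped))
  segs
}
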