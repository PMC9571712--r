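#' Band power of a segment
#'
#' Welch power spectral density (Hann windows, 2 s segments capped at
#' the window length, 50% overlap) integrated over a frequency band.
#'
#' @param seg a [segment()] or channels x samples matrix.
#' @param band a [band_spec()].
#' @param rate sampling rate when `seg` is a plain matrix.
#' @return named per-channel power vector (uV^2 for EEG).
#' @export
band_power <- function(seg, band, rate = NULL) {
  data <- if (inherits(seg, "segment")) seg$data else as.matrix(seg)
  if (inherits(seg, "segment")) rate <- seg$rate
  if (is.null(rate)) stop("a sampling rate is required")
  if (band$low > 0 && ncol(data) / rate < 2 / band$low)
    stop("window too short for the band's low edge")
  ps <- welch_psd(data, rate)
  sel <- ps$freq >= band$low & ps$freq <= band$high
  if (!any(sel)) stop("no frequency bins inside the band")
  df <- ps$freq[2] - ps$freq[1]
  pw <- rowSums(ps$psd[, sel, drop = FALSE]) * df
  names(pw) <- rownames(data)
  pw
}

#' Windowed fNIRS feature
#'
#' Per-channel mean of a (baseline-corrected) hemodynamic window; the
#' scalar that enters the fNIRS feature columns.
#'
#' @param seg a [segment()] or channels x samples matrix.
#' @return named per-channel mean (concentration units).
#' @export
fnirs_window_feature <- function(seg) {
  data <- if (inherits(seg, "segment")) seg$data else as.matrix(seg)
  if (!ncol(data)) stop("empty window")
  rowMeans(data)
}

#' Feature descriptor table
#'
#' One row per feature column: modality (`eeg-psd`, `eeg-fbc`,
#' `fnirs-hbo`, `fnirs-hbr`), band, channel (and second channel for
#' pairs, with `channel < channel_b` in montage order), estimator, and
#' window identifier.
#'
#' @param modality,band,channel,channel_b,estimator,window per-feature
#'   vectors (recycled).
#' @return data.frame of class `feature_descriptors`.
#' @export
feature_descriptors <- function(modality, band = NA, channel = NA,
                                channel_b = NA, estimator = NA, window = NA) {
  d <- data.frame(modality = unname(modality), band = unname(band),
                  channel = unname(channel), channel_b = unname(channel_b),
                  estimator = unname(estimator), window = unname(window),
                  stringsAsFactors = FALSE, row.names = NULL)
  class(d) <- c("feature_descriptors", "data.frame")
  d
}

descriptor_key <- function(d) {
  paste(d$modality, d$band, d$channel, d$channel_b, d$estimator, d$window,
        sep = "|")
}

#' Assemble a feature matrix
#'
#' Binds per-descriptor feature blocks into a samples x features matrix
#' with a deterministic column order (modality, band, channel/pair,
#' window, estimator — lexicographic) and attaches labels and sample
#' provenance.
#'
#' @param blocks list of lists, each with `values` (samples x columns
#'   matrix) and `descriptors` ([feature_descriptors()] with one row per
#'   column).
#' @param labels per-sample class labels.
#' @param meta data.frame with per-sample `participant`, `session`,
#'   `series`.
#' @return object of class `feature_matrix`.
#' @export
assemble_features <- function(blocks, labels, meta = NULL) {
  vals <- list(); descs <- list()
  n <- NULL
  for (b in blocks) {
    v <- as.matrix(b$values)
    if (nrow(b$descriptors) != ncol(v))
      stop("descriptor count must equal column count")
    if (is.null(n)) n <- nrow(v)
    if (nrow(v) != n) stop("ragged sample counts across blocks")
    vals[[length(vals) + 1L]] <- v
    descs[[length(descs) + 1L]] <- b$descriptors
  }
  values <- do.call(cbind, vals)
  descriptors <- do.call(rbind, descs)
  if (length(labels) != n) stop("one label per sample required")
  ord <- order(descriptors$modality, descriptors$band, descriptors$channel,
               descriptors$channel_b, descriptors$window,
               descriptors$estimator, method = "radix", na.last = TRUE)
  values <- values[, ord, drop = FALSE]
  descriptors <- descriptors[ord, , drop = FALSE]
  rownames(descriptors) <- NULL
  colnames(values) <- descriptor_key(descriptors)
  if (!all(is.finite(values))) stop("feature values must be finite")
  structure(list(values = values, descriptors = descriptors,
                 labels = factor(labels), meta = meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$descriptors$modality)),
                            table(x$descriptors$modality)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix
#'
#' @param fm a [assemble_features()] result.
#' @param samples,columns index vectors (logical or integer).
#' @return a `feature_matrix`.
#' @export
fm_subset <- function(fm, samples = NULL, columns = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(fm$values))
  if (is.null(columns)) columns <- seq_len(ncol(fm$values))
  structure(list(values = fm$values[samples, columns, drop = FALSE],
                 descriptors = fm$descriptors[columns, , drop = FALSE],
                 labels = droplevels(fm$labels[samples]),
                 meta = if (!is.null(fm$meta))
                   fm$meta[samples, , drop = FALSE] else NULL),
            class = "feature_matrix")
}

#' Column-bind two feature matrices over the same samples
#' @param a,b `feature_matrix` objects with identical sample order.
#' @return a `feature_matrix`.
#' @export
fm_cbind <- function(a, b) {
  if (nrow(a$values) != nrow(b$values)) stop("sample counts differ")
  if (!identical(as.character(a$labels), as.character(b$labels)))
    stop("label vectors differ between the two matrices")
  d <- rbind(a$descriptors, b$descriptors)
  if (anyDuplicated(descriptor_key(d)))
    stop("duplicate feature descriptors after binding")
  rownames(d) <- NULL
  structure(list(values = cbind(a$values, b$values), descriptors = d,
                 labels = a$labels, meta = a$meta),
            class = "feature_matrix")
}

# order pairs so channel precedes channel_b in montage order
pair_index <- function(channels) {
  C <- length(channels)
  i <- rep(seq_len(C - 1), times = (C - 1):1)
  j <- unlist(lapply(seq_len(C - 1), function(k) (k + 1):C))
  data.frame(a = channels[i], b = channels[j], ai = i, bi = j,
             stringsAsFactors = FALSE)
}

#' Extract the per-task EEG/fNIRS feature blocks of one session
#'
#' EEG: the session is band-passed 1-45 Hz (third-order, zero-phase),
#' one `eeg_win_len`-second window per task is cut from the task onset,
#' and per-band Welch band power plus the requested connectivity
#' estimators over all channel pairs are computed. fNIRS: the chosen
#' chromophore recording is low-passed at 0.04 Hz, windows of
#' `fnirs_win_len` seconds are cut at `fnirs_win_starts` (seconds from
#' task onset), median-baseline-corrected against the 5 s pre-onset
#' interval, and reduced to per-channel means.
#'
#' @param sess a [simulate_session()] result (or list with `eeg`,
#'   `hbo`, `hbr`, `events`).
#' @param eeg_channels channel subset for EEG features (default: the
#'   28-channel accounting set when available, else all).
#' @param bands list of [band_spec()]s.
#' @param estimators connectivity estimators to compute
#'   (subset of `"pcc"`, `"msc"`, `"mi"`, `"plv"`; `character(0)`
#'   skips FBC).
#' @param eeg_win_len EEG window length in seconds (canonically 40).
#' @param eeg_win_start EEG window start relative to task onset.
#' @param fnirs_win_len fNIRS window length in seconds (canonically 5).
#' @param fnirs_win_starts window starts in seconds from task onset
#'   (canonically ten 1 s-stepped starts; default 3..12 s, bracketing
#'   the 6 s hemodynamic peak).
#' @param chromophore `"hbr"` or `"hbo"`.
#' @param baseline_interval fNIRS baseline `c(from, to)` seconds
#'   relative to task onset (default -5..0 s; clipped to the recording
#'   start for the first task of a session).
#' @param prefilter apply the 1-45 Hz EEG prefilter / 0.04 Hz fNIRS
#'   low-pass (disable for already-filtered input).
#' @return list of feature blocks suitable for [assemble_features()],
#'   plus `labels` and `meta`.
#' @export
extract_session_features <- function(sess,
                                     eeg_channels = NULL,
                                     bands = default_bands(),
                                     estimators = "mi",
                                     eeg_win_len = 40,
                                     eeg_win_start = 0,
                                     fnirs_win_len = 5,
                                     fnirs_win_starts = 3:12,
                                     chromophore = c("hbr", "hbo"),
                                     baseline_interval = c(-5, 0),
                                     prefilter = TRUE) {
  chromophore <- match.arg(chromophore)
  ev <- sess$events
  n_task <- nrow(ev)
  labels <- ev$label
  meta <- ev[, c("participant", "session", "series")]

  blocks <- list()

  if (!is.null(sess$eeg)) {
    eeg <- sess$eeg
    if (is.null(eeg_channels)) {
      acct <- setdiff(eeg$channels, c("T7", "T8"))
      eeg_channels <- if (length(acct) >= 2) acct else eeg$channels
    }
    if (prefilter)
      eeg <- butter_filter(eeg, "bandpass", c(1, 45), 3)
    segs <- sliding_segments(eeg, ev, win_len = eeg_win_len, step = 1,
                             offset_range = c(eeg_win_start, eeg_win_start),
                             channels = eeg_channels)
    if (length(segs) != n_task) stop("EEG window missing for some task")
    C <- length(eeg_channels)
    band_names <- vapply(bands, `[[`, "", "name")

    psd_vals <- matrix(0, n_task, C * length(bands))
    psd_desc <- NULL
    for (bi in seq_along(bands)) {
      cols <- (bi - 1) * C + seq_len(C)
      for (ti in seq_len(n_task))
        psd_vals[ti, cols] <- band_power(segs[[ti]], bands[[bi]])
      psd_desc <- rbind(psd_desc, feature_descriptors(
        modality = "eeg-psd", band = band_names[bi], channel = eeg_channels,
        window = sprintf("w%g+%g", eeg_win_start, eeg_win_len)))
    }
    blocks$psd <- list(values = psd_vals, descriptors = psd_desc)

    if (length(estimators)) {
      pi_tab <- pair_index(eeg_channels)
      n_pair <- nrow(pi_tab)
      fbc_vals <- matrix(0, n_task,
                         n_pair * length(bands) * length(estimators))
      fbc_desc <- NULL
      col0 <- 0L
      for (bi in seq_along(bands)) {
        for (ti in seq_len(n_task)) {
          Ms <- fbc_matrices(segs[[ti]]$data, eeg$rate, bands[[bi]],
                             estimators)
          for (ei in seq_along(estimators))
            fbc_vals[ti, col0 + (ei - 1L) * n_pair + seq_len(n_pair)] <-
              Ms[[estimators[ei]]][cbind(pi_tab$ai, pi_tab$bi)]
        }
        for (est in estimators)
          fbc_desc <- rbind(fbc_desc, feature_descriptors(
            modality = "eeg-fbc", band = band_names[bi],
            channel = pi_tab$a, channel_b = pi_tab$b, estimator = est,
            window = sprintf("w%g+%g", eeg_win_start, eeg_win_len)))
        col0 <- col0 + n_pair * length(estimators)
      }
      blocks$fbc <- list(values = fbc_vals, descriptors = fbc_desc)
    }
  }

  fn <- sess[[chromophore]]
  if (!is.null(fn)) {
    if (prefilter) fn <- butter_filter(fn, "lowpass", 0.04, 3)
    Cf <- length(fn$channels)
    fn_vals <- matrix(0, n_task, Cf * length(fnirs_win_starts))
    fn_desc <- NULL
    for (wi in seq_along(fnirs_win_starts)) {
      st <- fnirs_win_starts[wi]
      segs <- sliding_segments(fn, ev, win_len = fnirs_win_len, step = 1,
                               offset_range = c(st, st))
      if (length(segs) != n_task) stop("fNIRS window missing for some task")
      cols <- (wi - 1) * Cf + seq_len(Cf)
      for (ti in seq_len(n_task)) {
        bi <- c(max(baseline_interval[1], -ev$onset[ti]),
                baseline_interval[2])
        seg <- baseline_correct(segs[[ti]], fn, ev$onset[ti],
                                baseline_interval = bi)
        fn_vals[ti, cols] <- fnirs_window_feature(seg)
      }
      fn_desc <- rbind(fn_desc, feature_descriptors(
        modality = paste0("fnirs-", chromophore), channel = fn$channels,
        window = sprintf("w%g+%g", st, fnirs_win_len)))
    }
    blocks$fnirs <- list(values = fn_vals, descriptors = fn_desc)
  }

  list(blocks = blocks, labels = labels, meta = meta)
}

#' Per-task feature matrix for a simulated (sub)cohort
#'
#' Runs [extract_session_features()] over every session of a
#' [simulate_dataset()] and assembles one row per task.
#'
#' @param dataset a `sim_dataset`.
#' @param ... passed to [extract_session_features()].
#' @return a [assemble_features()] `feature_matrix`.
#' @export
workload_features <- function(dataset, ...) {
  stopifnot(inherits(dataset, "sim_dataset"))
  per <- lapply(dataset$sessions, extract_session_features, ...)
  block_names <- names(per[[1]]$blocks)
  blocks <- lapply(block_names, function(bn) {
    list(values = do.call(rbind, lapply(per, function(x) x$blocks[[bn]]$values)),
         descriptors = per[[1]]$blocks[[bn]]$descriptors)
  })
  labels <- unlist(lapply(per, `[[`, "labels"))
  meta <- do.call(rbind, lapply(per, `[[`, "meta"))
  rownames(meta) <- NULL
  assemble_features(blocks, labels, meta)
}
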