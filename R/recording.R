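#' Multichannel recording container
#'
#' A `recording` holds a channels-by-samples matrix together with its
#' sampling rate, modality tag, channel labels and 2-D montage positions.
#' EEG data are in microvolts; HbO/HbR in concentration-change units;
#' raw fNIRS in optical density.
#'
#' @param data numeric matrix, channels x samples.
#' @param rate sampling rate in Hz (> 0).
#' @param modality one of `"eeg"`, `"hbo"`, `"hbr"`, `"od"`.
#' @param channels character vector of channel labels, one per row.
#' @param montage data.frame with `label`, `x`, `y` covering `channels`.
#' @return an object of class `recording`.
#' @export
recording <- function(data, rate, modality = c("eeg", "hbo", "hbr", "od"),
                      channels, montage = NULL) {
  modality <- match.arg(modality)
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("recording data must be finite numeric")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  channels <- as.character(channels)
  if (length(channels) != nrow(data))
    stop("one channel label per data row required")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!is.null(montage)) {
    check_montage(montage)
    if (!all(channels %in% montage$label))
      stop("every channel must appear in the montage")
    montage <- montage[match(channels, montage$label), , drop = FALSE]
    rownames(montage) <- NULL
  }
  rownames(data) <- channels
  structure(list(data = data, rate = rate, modality = modality,
                 channels = channels, montage = montage),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$modality, nrow(x$data), ncol(x$data), x$rate,
              ncol(x$data) / x$rate))
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

#' Duration of a recording in seconds
#' @param rec a [recording()].
#' @return length in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$rate

#' Frequency band specification
#'
#' The canonical analysis bands are delta (0.5-4 Hz), theta (4-7 Hz) and
#' alpha (8-15 Hz); [default_bands()] returns all three.
#'
#' @param name band name.
#' @param low,high band edges in Hz, `0 <= low < high`.
#' @return an object of class `band_spec`.
#' @export
band_spec <- function(name, low, high) {
  if (!(is.numeric(low) && is.numeric(high) && low >= 0 && low < high))
    stop("band edges must satisfy 0 <= low < high")
  structure(list(name = as.character(name), low = low, high = high),
            class = "band_spec")
}

#' @rdname band_spec
#' @export
default_bands <- function() {
  list(delta = band_spec("delta", 0.5, 4),
       theta = band_spec("theta", 4, 7),
       alpha = band_spec("alpha", 8, 15))
}

#' Windowed slice of a recording tied to one task
#'
#' @param data channels x samples matrix slice.
#' @param rate sampling rate in Hz.
#' @param start window start in seconds relative to its series onset.
#' @param length window length in seconds.
#' @param label task label.
#' @param participant,session,series provenance identifiers.
#' @param channels channel labels.
#' @return an object of class `segment`.
#' @export
segment <- function(data, rate, start, length, label,
                    participant, session, series, channels = rownames(data)) {
  structure(list(data = as.matrix(data), rate = rate, start = start,
                 length = length, label = label, participant = participant,
                 session = session, series = series,
                 channels = channels),
            class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment> %s: %d ch x %d samples, start %gs, len %gs (p%s s%s r%s)\n",
              as.character(x$label), nrow(x$data), ncol(x$data), x$start,
              x$length, x$participant, x$session, x$series))
  invisible(x)
}
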