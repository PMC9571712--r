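#' Topographic interpolation of a per-channel scalar map
#'
#' Inverse-distance-weighted (power 2) interpolation of channel values
#' onto a regular grid over the 2-D montage, masked to the convex hull
#' of the sensors. Grid points coinciding with a sensor take that
#' sensor's value exactly; all interpolated values lie inside the
#' channel value range.
#'
#' @param values named per-channel scalars.
#' @param montage data.frame `label`, `x`, `y` covering `names(values)`.
#' @param grid_n grid resolution per axis.
#' @return list with `x`, `y` grid axes and `z` (grid_n x grid_n matrix,
#'   `NA` outside the hull), class `topomap`.
#' @export
topomap <- function(values, montage, grid_n = 64) {
  ch <- names(values)
  if (length(ch) < 3) stop("at least three channels required")
  m <- montage[match(ch, montage$label), , drop = FALSE]
  if (anyNA(m$x)) stop("montage is missing some channels")
  if (anyDuplicated(m[, c("x", "y")])) stop("duplicate channel positions")
  gx <- seq(min(m$x), max(m$x), length.out = grid_n)
  gy <- seq(min(m$y), max(m$y), length.out = grid_n)
  hull <- grDevices::chull(m$x, m$y)
  hx <- m$x[hull]; hy <- m$y[hull]
  z <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    for (j in seq_len(grid_n)) {
      if (!point_in_polygon(gx[i], gy[j], hx, hy)) next
      d2 <- (m$x - gx[i])^2 + (m$y - gy[j])^2
      hit <- which(d2 < 1e-12)
      if (length(hit)) { z[i, j] <- values[hit[1]]; next }
      w <- 1 / d2
      z[i, j] <- sum(w * values) / sum(w)
    }
  }
  structure(list(x = gx, y = gy, z = z, channels = ch, values = values),
            class = "topomap")
}

# ray-casting with boundary tolerance
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    # on-edge check
    dx <- vx[j] - vx[i]; dy <- vy[j] - vy[i]
    t <- if (dx == 0 && dy == 0) 0 else
      ((px - vx[i]) * dx + (py - vy[i]) * dy) / (dx * dx + dy * dy)
    t <- min(1, max(0, t))
    if ((px - (vx[i] + t * dx))^2 + (py - (vy[i] + t * dy))^2 < 1e-18)
      return(TRUE)
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' @export
print.topomap <- function(x, ...) {
  cat(sprintf("<topomap> %d x %d grid over %d channels, range [%.3g, %.3g]\n",
              length(x$x), length(x$y), length(x$channels),
              min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE)))
  invisible(x)
}

#' Image plot of a topographic map
#' @param x a [topomap()].
#' @param ... passed to [graphics::image()].
#' @export
plot.topomap <- function(x, ...) {
  graphics::image(x$x, x$y, x$z, xlab = "x", ylab = "y",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  m <- x
  invisible(m)
}

# columns of fm belonging to one channel (single-channel descriptors)
channel_columns <- function(fm, channel) {
  d <- fm$descriptors
  which(!is.na(d$channel) & d$channel == channel & is.na(d$channel_b))
}

#' Per-channel classification accuracy map
#'
#' Cross-validated accuracy of the binary task using only each
#' channel's own feature columns (e.g. its three band powers, or its
#' fNIRS window means), as a per-channel scalar map for topographic
#' display.
#'
#' @param fm a `feature_matrix` (single-channel descriptors).
#' @param pair binary task pair.
#' @param channels channels to map (default: all present in the
#'   descriptors).
#' @param classifier,seed passed to [crossval()].
#' @param n_rep repeated cross-validation runs averaged per channel
#'   (distinct fold shuffles); > 1 stabilises small-sample maps.
#' @return named per-channel accuracy vector (percent).
#' @export
per_channel_accuracy <- function(fm, pair, channels = NULL,
                                 classifier = "svm", seed = 1, n_rep = 1) {
  d <- fm$descriptors
  if (is.null(channels))
    channels <- unique(d$channel[!is.na(d$channel) & is.na(d$channel_b)])
  if (!length(channels)) stop("no single-channel feature columns found")
  fmn <- normalize_per_participant(fm)
  sub_rows <- which(fmn$labels %in% pair)
  acc <- vapply(channels, function(ch) {
    cols <- channel_columns(fm, ch)
    if (!length(cols)) stop(sprintf("no feature columns for channel %s", ch))
    sub <- fm_subset(fmn, samples = sub_rows, columns = cols)
    mean(vapply(seq_len(n_rep), function(r)
      crossval(sub, classifier = classifier,
               seed = seed + (r - 1L) * 1000L)$accuracy, 0))
  }, 0)
  names(acc) <- channels
  acc
}

#' Channel-pair classification accuracy heat map
#'
#' Cross-validated accuracy of the binary task using each channel
#' pair's connectivity feature (one estimator, one band) as sole input;
#' returned as a symmetric channels x channels matrix with `NA` on the
#' diagonal.
#'
#' @param fm a `feature_matrix` containing `eeg-fbc` columns.
#' @param pair binary task pair.
#' @param estimator,band select which connectivity columns to use.
#' @param classifier,seed passed to [crossval()].
#' @return symmetric accuracy matrix (percent), `NA` diagonal.
#' @export
pair_accuracy_heatmap <- function(fm, pair, estimator = "mi", band = "alpha",
                                  classifier = "svm", seed = 1) {
  d <- fm$descriptors
  sel <- which(d$modality == "eeg-fbc" & d$estimator == estimator &
                 d$band == band)
  if (!length(sel)) stop("no connectivity columns for that estimator/band")
  chans <- unique(c(d$channel[sel], d$channel_b[sel]))
  M <- matrix(NA_real_, length(chans), length(chans),
              dimnames = list(chans, chans))
  fmn <- normalize_per_participant(fm)
  sub_rows <- which(fmn$labels %in% pair)
  for (cc in sel) {
    rep <- crossval(fm_subset(fmn, samples = sub_rows, columns = cc),
                    classifier = classifier, seed = seed)
    M[d$channel[cc], d$channel_b[cc]] <- rep$accuracy
    M[d$channel_b[cc], d$channel[cc]] <- rep$accuracy
  }
  M
}
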