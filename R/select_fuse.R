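#' One-way ANOVA F statistics, vectorised over feature columns
#'
#' Classic between/within mean-square ratio for each column of `x`
#' grouped by `g`, with p-values from the F distribution on
#' `(g - 1, n - g)` degrees of freedom. A column with zero within-group
#' variance but unequal group means reports `F = Inf, p = 0`; an
#' all-constant column reports `NA` (undefined) and is ranked last by
#' [select_top_k()].
#'
#' @param x numeric vector or samples x features matrix.
#' @param g grouping factor (>= 2 groups, >= 2 values per group).
#' @return data.frame with columns `F` and `p`, one row per feature.
#' @export
anova_f <- function(x, g) {
  x <- as.matrix(x)
  g <- factor(g)
  if (nlevels(g) < 2) stop("at least two groups required")
  if (any(table(g) < 2)) stop("each group needs at least two values")
  n <- nrow(x)
  k <- nlevels(g)
  grand <- colMeans(x)
  ss_total <- colSums(sweep(x, 2, grand)^2)
  ss_between <- numeric(ncol(x))
  for (lev in levels(g)) {
    idx <- g == lev
    m <- colMeans(x[idx, , drop = FALSE])
    ss_between <- ss_between + sum(idx) * (m - grand)^2
  }
  ss_within <- ss_total - ss_between
  df1 <- k - 1
  df2 <- n - k
  Fst <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  # degenerate columns
  zero_w <- ss_within <= .Machine$double.eps * pmax(ss_total, 1)
  zero_b <- ss_between <= .Machine$double.eps * pmax(ss_total, 1)
  Fst[zero_w & !zero_b] <- Inf
  p[zero_w & !zero_b] <- 0
  Fst[zero_w & zero_b] <- NA_real_
  p[zero_w & zero_b] <- NA_real_
  data.frame(F = unname(Fst), p = unname(p))
}

#' Select the top-k features by ANOVA p-value
#'
#' Ranks columns by smallest p-value (ties broken by larger F, then by
#' lower column index; undefined columns last) and keeps the first `k`.
#'
#' @param fm a `feature_matrix` (or plain matrix).
#' @param labels grouping labels; defaults to `fm$labels`.
#' @param k number of features to keep.
#' @return object of class `selection_result`: `ranking` (column
#'   indices, length `k`), `F`, `p` (per original column), `k`,
#'   `descriptors` of the selected columns (when available).
#' @export
select_top_k <- function(fm, labels = NULL, k = 10) {
  values <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (is.null(labels) && inherits(fm, "feature_matrix")) labels <- fm$labels
  if (k > ncol(values)) stop("k exceeds the number of feature columns")
  stat <- anova_f(values, labels)
  ord <- order(stat$p, -stat$F, seq_len(ncol(values)),
               method = "radix", na.last = TRUE)
  ranking <- ord[seq_len(k)]
  structure(list(
    ranking = ranking,
    F = stat$F, p = stat$p, k = k,
    descriptors = if (inherits(fm, "feature_matrix"))
      fm$descriptors[ranking, , drop = FALSE] else NULL
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> top %d of %d features; best p = %.3g\n",
              x$k, length(x$p), min(x$p, na.rm = TRUE)))
  invisible(x)
}

#' Fuse EEG and fNIRS feature selections into a hybrid matrix
#'
#' Column-concatenates the selected EEG features and the selected fNIRS
#' features (canonically 5 + 5 = 10 hybrid features), EEG first, each
#' block in rank order. The two source matrices must cover the same
#' samples and carry disjoint descriptors.
#'
#' @param eeg_fm,fnirs_fm `feature_matrix` objects over identical
#'   samples.
#' @param eeg_sel,fnirs_sel [select_top_k()] results on those matrices.
#' @return a hybrid `feature_matrix`.
#' @export
fuse_features <- function(eeg_fm, eeg_sel, fnirs_fm, fnirs_sel) {
  a <- fm_subset(eeg_fm, columns = eeg_sel$ranking)
  b <- fm_subset(fnirs_fm, columns = fnirs_sel$ranking)
  fm_cbind(a, b)
}
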