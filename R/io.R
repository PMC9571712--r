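# Plain-text serialisation: delimited matrices with JSON sidecars.

#' Write / read a recording as delimited text plus a JSON sidecar
#'
#' The data matrix (rows = channels, columns = samples) is written as
#' tab-separated text; rate, modality, channel labels and montage
#' coordinates go into `<path>.json`.
#'
#' @param rec a [recording()].
#' @param path data file path (the sidecar adds `.json`).
#' @return `write_recording` the path, invisibly; `read_recording` a
#'   [recording()].
#' @export
write_recording <- function(rec, path) {
  utils::write.table(rec$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  side <- list(rate_hz = rec$rate, modality = rec$modality,
               channel_labels = rec$channels)
  if (!is.null(rec$montage))
    side$montage_xy <- rec$montage
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(data) <- NULL
  montage <- if (!is.null(side$montage_xy))
    as.data.frame(side$montage_xy) else NULL
  recording(data, side$rate_hz, side$modality, side$channel_labels, montage)
}

#' Write / read an event table
#' @param events event data.frame.
#' @param path file path (tab-separated, header row).
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write / read a feature matrix
#'
#' Values as a tab-separated table; descriptors, labels and provenance
#' as a JSON manifest in `<path>.json`.
#'
#' @param fm a `feature_matrix`.
#' @param path data file path.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.table(fm$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(descriptors = fm$descriptors,
                            labels = as.character(fm$labels),
                            meta = fm$meta),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(values) <- NULL
  d <- as.data.frame(man$descriptors)
  class(d) <- c("feature_descriptors", "data.frame")
  blocks <- list(list(values = values, descriptors = d))
  meta <- if (!is.null(man$meta)) as.data.frame(man$meta) else NULL
  assemble_features(blocks, man$labels, meta)
}

#' Write a connectivity matrix as a square delimited table
#' @param cm a [connectivity_matrix()].
#' @param path file path.
#' @export
write_connectivity <- function(cm, path) {
  utils::write.table(cm$values, path, sep = "\t",
                     row.names = TRUE, col.names = NA, quote = FALSE)
  invisible(path)
}

#' Write a cross-validation report as JSON
#' @param rep a [crossval()] `cv_report`.
#' @param path output path; ROC points go to `<path>.roc.tsv`.
#' @export
write_cv_report <- function(rep, path) {
  out <- list(classifier = rep$classifier, k = rep$k, seed = rep$seed,
              accuracy = rep$accuracy, fold_accuracy = rep$fold_accuracy,
              confusion = as.list(rep$confusion),
              metrics = as.list(rep$metrics), auc = rep$auc,
              positive = rep$positive)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(rep$roc))
    utils::write.table(rep$roc, paste0(path, ".roc.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sweep curve as a delimited table plus JSON summary
#' @param sc a [position_sweep()] / [size_sweep()] `sweep_curve`.
#' @param path output path for the table; the summary adds `.json`.
#' @export
write_sweep_curve <- function(sc, path) {
  utils::write.table(sc$curve, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  best <- sc$curve[[1]][which.max(sc$curve$accuracy)]
  jsonlite::write_json(
    list(mode = sc$mode, modality = sc$modality, pair = sc$pair,
         best = best, top10 = sc$top10),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a feature selection as a ranked table
#' @param sel a [select_top_k()] `selection_result`.
#' @param path output path (tab-separated: rank, descriptor fields, F, p).
#' @export
write_selection <- function(sel, path) {
  tab <- data.frame(rank = seq_along(sel$ranking), column = sel$ranking,
                    F = sel$F[sel$ranking], p = sel$p[sel$ranking])
  if (!is.null(sel$descriptors))
    tab <- cbind(tab[, 1:2], sel$descriptors, tab[, c("F", "p")])
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
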