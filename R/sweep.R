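# Window-position and window-size sensitivity analyses.

# Pre-filter every session once so per-window extraction can skip it.
prefilter_dataset <- function(dataset, modality = c("fnirs", "eeg"),
                              chromophore = "hbr") {
  modality <- match.arg(modality)
  ds <- dataset
  ds$sessions <- lapply(dataset$sessions, function(sess) {
    out <- list(events = sess$events, truth = sess$truth)
    if (modality == "fnirs") {
      out$eeg <- NULL
      out[[chromophore]] <- butter_filter(sess[[chromophore]],
                                          "lowpass", 0.04, 3)
    } else {
      out$eeg <- butter_filter(sess$eeg, "bandpass", c(1, 45), 3)
    }
    out
  })
  ds
}

sweep_accuracy <- function(fm, pair, k, classifier, seed) {
  sel <- select_top_k(fm, k = min(k, ncol(fm$values)))
  sub <- fm_subset(fm, columns = sel$ranking)
  sub <- normalize_per_participant(sub)
  rep <- crossval(fm_subset(sub, samples = which(sub$labels %in% pair)),
                  classifier = classifier, seed = seed)
  c(accuracy = rep$accuracy, spread = stats::sd(rep$fold_accuracy))
}

#' Window-position sweep for fNIRS features
#'
#' Slides a fixed-length window through the task cycle (instruction +
#' task + stop + rest, canonically 63 s), and for each start position
#' extracts the per-channel fNIRS window features, runs the standard
#' ANOVA selection and cross-validated classification, and records the
#' mean accuracy. Window starts are measured in seconds from each
#' cycle's instruction onset (the task itself starts 2 s in under the
#' default layout).
#'
#' @param dataset a `sim_dataset`.
#' @param pair binary task pair, e.g. `c("0-back", "3-back")`.
#' @param win_len,step window length and stride, seconds.
#' @param chromophore `"hbr"` or `"hbo"`.
#' @param k features kept by the ANOVA ranking at each position.
#' @param classifier,seed passed to [crossval()].
#' @return object of class `sweep_curve`: data.frame `curve`
#'   (`start`, `accuracy`, `spread`), `top10` best starts (by accuracy,
#'   earlier start on ties), plus sweep metadata.
#' @export
position_sweep <- function(dataset, pair = c("0-back", "3-back"),
                           win_len = 5, step = 1, chromophore = "hbr",
                           k = 10, classifier = "svm", seed = 1) {
  cf <- dataset$config
  cyc <- cycle_duration(cf)
  if (win_len > cyc) stop("window exceeds the task cycle")
  instr <- unname(cf$block_layout["instruction"])
  starts <- window_starts(win_len, step, c(0, cyc - win_len))
  ds <- prefilter_dataset(dataset, "fnirs", chromophore)
  res <- vapply(starts, function(st) {
    fm <- workload_features(ds, estimators = character(0),
                            fnirs_win_len = win_len,
                            fnirs_win_starts = st - instr,
                            chromophore = chromophore, prefilter = FALSE)
    sweep_accuracy(fm, pair, k, classifier, seed)
  }, c(accuracy = 0, spread = 0))
  curve <- data.frame(start = starts, accuracy = res["accuracy", ],
                      spread = res["spread", ])
  ord <- order(-curve$accuracy, curve$start)
  structure(list(curve = curve,
                 top10 = curve$start[ord[seq_len(min(10, nrow(curve)))]],
                 mode = "position", modality = "fnirs", pair = pair,
                 win_len = win_len),
            class = "sweep_curve")
}

#' Window-size sweep for EEG or fNIRS features
#'
#' Accuracy as a function of window length. EEG windows start at the
#' task onset (the effects are sustained through the 40 s task);
#' fNIRS windows of each size are placed at their best position found
#' on a 2 s grid over the cycle, mirroring the position-then-size
#' procedure.
#'
#' @param dataset a `sim_dataset`.
#' @param sizes window lengths in seconds; each must fit the task
#'   (EEG) or cycle (fNIRS).
#' @param modality `"eeg"` or `"fnirs"`.
#' @param pair binary task pair.
#' @param chromophore,k,classifier,seed as in [position_sweep()].
#' @return a `sweep_curve` whose abscissa is window size.
#' @export
size_sweep <- function(dataset, sizes = c(5, 10, 20, 40),
                       modality = c("eeg", "fnirs"),
                       pair = c("0-back", "3-back"), chromophore = "hbr",
                       k = 10, classifier = "svm", seed = 1) {
  modality <- match.arg(modality)
  cf <- dataset$config
  task_len <- unname(cf$block_layout["task"])
  instr <- unname(cf$block_layout["instruction"])
  cyc <- cycle_duration(cf)
  if (modality == "eeg" && any(sizes > task_len))
    stop("EEG window size exceeds the task duration")
  if (modality == "fnirs" && any(sizes > cyc))
    stop("fNIRS window size exceeds the task cycle")
  ds <- prefilter_dataset(dataset, modality, chromophore)
  res <- vapply(sizes, function(sz) {
    if (modality == "eeg") {
      fm <- workload_features(ds, estimators = character(0),
                              eeg_win_len = sz, prefilter = FALSE)
      fm <- fm_subset(fm, columns = which(fm$descriptors$modality == "eeg-psd"))
      sweep_accuracy(fm, pair, k, classifier, seed)
    } else {
      pos <- window_starts(sz, 2, c(0, cyc - sz))
      accs <- vapply(pos, function(st) {
        fm <- workload_features(ds, estimators = character(0),
                                fnirs_win_len = sz,
                                fnirs_win_starts = st - instr,
                                chromophore = chromophore,
                                prefilter = FALSE)
        sweep_accuracy(fm, pair, k, classifier, seed)
      }, c(accuracy = 0, spread = 0))
      accs[, which.max(accs["accuracy", ])]
    }
  }, c(accuracy = 0, spread = 0))
  structure(list(curve = data.frame(size = sizes,
                                    accuracy = res["accuracy", ],
                                    spread = res["spread", ]),
                 mode = "size", modality = modality, pair = pair),
            class = "sweep_curve")
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf("<sweep_curve> %s sweep, %s, %s vs %s\n",
              x$mode, x$modality, x$pair[1], x$pair[2]))
  print(x$curve, row.names = FALSE)
  invisible(x)
}
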