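#' Per-participant min-max normalisation to \[-1, 1\]
#'
#' For each participant and each feature column, linearly maps the
#' participant's own minimum to -1 and maximum to +1, reducing
#' between-individual offset and scale differences before
#' classification. A column constant within a participant maps to 0.
#'
#' @param fm a `feature_matrix` whose `meta` carries `participant`.
#' @return the normalised `feature_matrix`.
#' @export
normalize_per_participant <- function(fm) {
  if (is.null(fm$meta) || is.null(fm$meta$participant))
    stop("feature matrix lacks participant identifiers")
  v <- fm$values
  for (p in unique(fm$meta$participant)) {
    idx <- fm$meta$participant == p
    if (sum(idx) < 2) stop("each participant needs at least two samples")
    sub <- v[idx, , drop = FALSE]
    lo <- apply(sub, 2, min)
    hi <- apply(sub, 2, max)
    rng <- hi - lo
    const <- rng == 0
    rng[const] <- 1
    sub <- sweep(sweep(sub, 2, lo), 2, rng, `/`) * 2 - 1
    sub[, const] <- 0
    v[idx, ] <- sub
  }
  fm$values <- v
  fm
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity and specificity (percent) from true/false
#' positive/negative counts. A zero denominator yields `NA` for that
#' metric rather than an error.
#'
#' @param counts named vector or list with `TP`, `TN`, `FP`, `FN`.
#' @return named vector `c(Accu, Sens, Spec)` in percent.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  tot <- tp + tn + fp + fn
  c(Accu = if (tot > 0) 100 * (tp + tn) / tot else NA_real_,
    Sens = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    Spec = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the unique scores (ties stepped
#' simultaneously), accumulating the true positive rate against the
#' false positive rate; the area is the trapezoid integral. Higher
#' scores must indicate the positive class.
#'
#' @param scores per-sample decision values.
#' @param labels binary labels; `positive` marks the positive class.
#' @param positive positive-class label (default: last factor level).
#' @return list with `roc` (data.frame `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("ROC needs exactly two classes present")
  if (is.null(positive)) positive <- levels(labels)[2]
  y <- labels == positive
  P <- sum(y); N <- sum(!y)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # step at each distinct score (ties advance together)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

svm_gamma <- function(x) {
  v <- stats::var(as.vector(x))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(x) * v)
}

fit_predict <- function(train_x, train_y, test_x, classifier, positive,
                        cost = 1, knn_k = 5) {
  if (classifier == "svm") {
    fit <- e1071::svm(train_x, train_y, kernel = "radial", cost = cost,
                      gamma = svm_gamma(train_x), scale = FALSE)
    pr <- predict(fit, test_x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 orients decision values towards the first class in its header
    flip <- if (grepl(paste0("^", positive, "/"), colnames(dv)[1])) 1 else -1
    list(pred = pr, score = flip * dv[, 1])
  } else if (classifier == "knn") {
    pr <- class::knn(train_x, test_x, train_y, k = knn_k, prob = TRUE)
    p_win <- attr(pr, "prob")
    score <- ifelse(pr == positive, p_win, 1 - p_win)
    list(pred = pr, score = score)
  } else if (classifier == "lda") {
    fit <- MASS::lda(train_x, grouping = train_y)
    pr <- predict(fit, test_x)
    list(pred = pr$class, score = pr$posterior[, positive])
  } else if (classifier == "tree") {
    df <- data.frame(y = train_y, train_x)
    fit <- rpart::rpart(y ~ ., df, method = "class",
                        control = rpart::rpart.control(maxdepth = 5))
    nd <- data.frame(test_x)
    colnames(nd) <- colnames(df)[-1]
    pp <- predict(fit, nd, type = "prob")
    cls <- factor(colnames(pp)[max.col(pp, ties.method = "first")],
                  levels = levels(train_y))
    list(pred = cls, score = pp[, positive])
  } else stop("unknown classifier")
}

#' Stratified k-fold cross-validated classification
#'
#' Binary workload classification with a seeded stratified partition:
#' each class is shuffled and dealt round-robin into `k` folds (fold
#' sizes differ by at most one per class), every fold serving once as
#' the 20% test split under the canonical `k = 5`. The default
#' classifier is an RBF-kernel SVM (`cost = 1`,
#' `gamma = 1/(n_features * var)`); KNN (k = 5), a depth-limited
#' decision tree, and LDA are available as comparators. Decision
#' scores are pooled across folds for the ROC.
#'
#' @param fm a `feature_matrix` or samples x features matrix.
#' @param labels binary labels (defaults to `fm$labels`).
#' @param classifier `"svm"`, `"knn"`, `"tree"` or `"lda"`.
#' @param k number of folds.
#' @param seed integer seed for the fold shuffle.
#' @param positive positive-class label (default: last factor level,
#'   i.e. the higher workload).
#' @param folds `"stratified"` (sample-wise, the default) or
#'   `"participant"` (subject-wise: folds never split a participant,
#'   one participant per fold up to `k`; requires `fm$meta`). The
#'   subject-wise mode sidesteps the within-participant label-balance
#'   artifact of block-balanced designs.
#' @return object of class `cv_report`: per-fold accuracies, mean
#'   accuracy, pooled confusion counts, `Accu`/`Sens`/`Spec` (percent),
#'   ROC points, AUC, classifier name and seed.
#' @export
crossval <- function(fm, labels = NULL, classifier = c("svm", "knn", "tree", "lda"),
                     k = 5, seed = 1, positive = NULL,
                     folds = c("stratified", "participant")) {
  classifier <- match.arg(classifier)
  folds <- match.arg(folds)
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (is.null(labels) && inherits(fm, "feature_matrix")) labels <- fm$labels
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("crossval expects a binary task")
  if (is.null(positive)) positive <- levels(labels)[2]
  counts <- table(labels)

  set.seed(seed)
  if (folds == "participant") {
    if (!inherits(fm, "feature_matrix") || is.null(fm$meta$participant))
      stop("subject-wise folds need participant identifiers")
    part <- fm$meta$participant
    up <- sample(unique(part))
    k <- min(k, length(up))
    fold <- match(part, up) %% k + 1L
  } else {
    if (k > min(counts))
      stop("more folds than samples in the smallest class")
    fold <- integer(length(labels))
    for (lev in levels(labels)) {
      idx <- sample(which(labels == lev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  }

  pred <- factor(rep(NA, length(labels)), levels = levels(labels))
  score <- numeric(length(labels))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    fp <- fit_predict(x[!te, , drop = FALSE], labels[!te],
                      x[te, , drop = FALSE], classifier, positive)
    pred[te] <- fp$pred
    score[te] <- fp$score
    fold_acc[f] <- 100 * mean(fp$pred == labels[te])
  }

  is_pos <- labels == positive
  conf <- c(TP = sum(pred == positive & is_pos),
            TN = sum(pred != positive & !is_pos),
            FP = sum(pred == positive & !is_pos),
            FN = sum(pred != positive & is_pos))
  roc <- roc_auc(score, labels, positive)
  structure(list(
    fold_accuracy = fold_acc,
    accuracy = mean(fold_acc),
    confusion = conf,
    metrics = confusion_metrics(conf),
    roc = roc$roc, auc = roc$auc,
    classifier = classifier, k = k, seed = seed, positive = positive
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d-fold: Accu %.1f%% (folds %s), AUC %.3f\n",
              x$classifier, x$k, x$accuracy,
              paste(sprintf("%.0f", x$fold_accuracy), collapse = "/"),
              x$auc))
  invisible(x)
}

#' Hybrid selection + classification pipeline for one task pair
#'
#' Replicates the canonical ordering: three-class ANOVA feature ranking
#' on the full sample set, top-k selection per modality, 5 + 5 fusion,
#' per-participant normalisation, then stratified cross-validation on
#' the requested binary task.
#'
#' @param fm a `feature_matrix` holding both modalities.
#' @param pair length-2 character vector of task labels, e.g.
#'   `c("0-back", "3-back")`.
#' @param k_each features kept per modality before fusion.
#' @param eeg_pool `"all"` (PSD + FBC columns) or `"psd_only"`.
#' @param classifier,seed passed to [crossval()].
#' @param nested_selection if `TRUE`, rank features inside each
#'   training fold only, with fold-fitted normalisation (leakage-free
#'   variant); the default `FALSE` replicates whole-set selection.
#' @param folds fold scheme, as in [crossval()].
#' @return a [crossval()] `cv_report` with the selected descriptors
#'   attached as `$selected`.
#' @export
hybrid_pipeline <- function(fm, pair, k_each = 5,
                            eeg_pool = c("all", "psd_only"),
                            classifier = "svm", seed = 1,
                            nested_selection = FALSE,
                            folds = "stratified") {
  eeg_pool <- match.arg(eeg_pool)
  eeg_cols <- if (eeg_pool == "all")
    fm$descriptors$modality %in% c("eeg-psd", "eeg-fbc")
  else fm$descriptors$modality == "eeg-psd"
  fn_cols <- startsWith(fm$descriptors$modality, "fnirs")
  if (!any(eeg_cols) || !any(fn_cols))
    stop("both EEG and fNIRS feature columns are required")
  eeg_fm <- fm_subset(fm, columns = which(eeg_cols))
  fn_fm <- fm_subset(fm, columns = which(fn_cols))
  if (nested_selection) {
    # selection inside the CV folds: select on training labels only
    sub <- fm$labels %in% pair
    return(nested_hybrid_cv(fm_subset(fm, samples = which(sub)),
                            eeg_cols, fn_cols, k_each, classifier, seed,
                            folds))
  }
  eeg_sel <- select_top_k(eeg_fm, k = k_each)
  fn_sel <- select_top_k(fn_fm, k = k_each)
  hybrid <- fuse_features(eeg_fm, eeg_sel, fn_fm, fn_sel)
  hybrid <- normalize_per_participant(hybrid)
  sub <- hybrid$labels %in% pair
  rep <- crossval(fm_subset(hybrid, samples = which(sub)),
                  classifier = classifier, seed = seed, folds = folds)
  rep$selected <- hybrid$descriptors
  rep
}

nested_hybrid_cv <- function(fm, eeg_cols, fn_cols, k_each, classifier, seed,
                             folds = "stratified") {
  labels <- droplevels(fm$labels)
  set.seed(seed)
  k <- 5
  if (folds == "participant") {
    up <- sample(unique(fm$meta$participant))
    k <- min(k, length(up))
    fold <- match(fm$meta$participant, up) %% k + 1L
  } else {
    fold <- integer(length(labels))
    for (lev in levels(labels)) {
      idx <- sample(which(labels == lev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    tr_v <- fm$values[!te, , drop = FALSE]
    sel_e <- select_top_k(tr_v[, eeg_cols, drop = FALSE],
                          labels[!te], k_each)
    sel_f <- select_top_k(tr_v[, fn_cols, drop = FALSE],
                          labels[!te], k_each)
    keep <- c(which(eeg_cols)[sel_e$ranking], which(fn_cols)[sel_f$ranking])
    # normalisation fitted on training rows only (per participant)
    nv <- nested_normalize(fm$values[, keep, drop = FALSE],
                           fm$meta$participant, !te)
    fp <- fit_predict(nv[!te, , drop = FALSE], labels[!te],
                      nv[te, , drop = FALSE], classifier,
                      levels(labels)[2])
    acc[f] <- 100 * mean(fp$pred == labels[te])
  }
  structure(list(fold_accuracy = acc, accuracy = mean(acc),
                 classifier = classifier, k = k, seed = seed,
                 nested = TRUE),
            class = "cv_report")
}

# per-participant min-max maps fitted on training rows, applied to all
nested_normalize <- function(v, participant, train) {
  out <- v
  for (p in unique(participant)) {
    idx <- participant == p
    fit_idx <- idx & train
    if (!any(fit_idx)) fit_idx <- idx  # participant absent from training
    lo <- apply(v[fit_idx, , drop = FALSE], 2, min)
    hi <- apply(v[fit_idx, , drop = FALSE], 2, max)
    rng <- hi - lo
    const <- rng == 0
    rng[const] <- 1
    sub <- sweep(sweep(v[idx, , drop = FALSE], 2, lo), 2, rng, `/`) * 2 - 1
    sub[, const] <- 0
    out[idx, ] <- pmin(pmax(sub, -1.5), 1.5)
  }
  out
}
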