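test_that("per-participant normalisation maps each participant to [-1, 1]", {
  fm <- synthetic_fm(n_per_class = 3, channels = c("A", "B"))
  fm$meta$participant <- rep(c(1, 2), each = 3)
  fm$values[, 1] <- c(2, 4, 6, 100, 150, 200)
  fm$values[, 2] <- 5  # constant column
  out <- normalize_per_participant(fm)
  expect_equal(out$values[1:3, 1], c(-1, 0, 1))
  expect_equal(out$values[4:6, 1], c(-1, 0, 1))
  expect_equal(out$values[, 2], rep(0, 6))
  fm$meta <- NULL
  expect_error(normalize_per_participant(fm), "participant")
})

test_that("confusion metrics follow the defining formulas", {
  m <- confusion_metrics(c(TP = 3, TN = 2, FP = 1, FN = 2))
  expect_equal(round(unname(m), 1), c(62.5, 60.0, 66.7))
  expect_equal(unname(confusion_metrics(c(TP = 5, TN = 5, FP = 0, FN = 0))),
               c(100, 100, 100))
  expect_equal(unname(confusion_metrics(c(TP = 0, TN = 3, FP = 1, FN = 4))[2]), 0)
  expect_true(is.na(confusion_metrics(c(TP = 0, TN = 3, FP = 1, FN = 0))[2]))
  # Accu = (Sens*P + Spec*N) / (P + N), exactly
  set.seed(14)
  for (i in 1:20) {
    cnt <- c(TP = sample(0:9, 1) + 1, TN = sample(0:9, 1) + 1,
             FP = sample(0:9, 1), FN = sample(0:9, 1))
    m <- confusion_metrics(cnt)
    P <- cnt[["TP"]] + cnt[["FN"]]; N <- cnt[["TN"]] + cnt[["FP"]]
    expect_equal(unname(m[1]), unname((m[2] * P + m[3] * N) / (P + N)))
  }
})

test_that("ROC/AUC equals the U-statistic and behaves under negation", {
  lab <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  expect_equal(roc_auc(c(0, 0, 1, 1), lab)$auc, 1)
  expect_equal(roc_auc(c(1, 1, 1, 1), lab)$auc, 0.5)
  set.seed(15)
  for (i in 1:20) {
    lb <- factor(sample(c("lo", "hi"), 30, replace = TRUE),
                 levels = c("lo", "hi"))
    if (nlevels(droplevels(lb)) < 2) next
    sc <- round(rnorm(30), 1)  # rounding forces ties
    r <- roc_auc(sc, lb)
    expect_lt(abs(r$auc - auc_oracle(sc, lb, "hi")), 1e-10)
    expect_lt(abs(roc_auc(-sc, lb)$auc - (1 - r$auc)), 1e-10)
    # curve is monotone from (0,0) to (1,1)
    expect_equal(unlist(r$roc[1, ], use.names = FALSE), c(0, 0))
    expect_equal(unlist(r$roc[nrow(r$roc), ], use.names = FALSE), c(1, 1))
    expect_true(all(diff(r$roc$tpr) >= 0) && all(diff(r$roc$fpr) >= 0))
  }
  expect_error(roc_auc(1:3, factor(c("a", "a", "a"))), "two classes")
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(16)
  lb <- factor(rep(c("lo", "hi"), each = 20), levels = c("lo", "hi"))
  sc <- rnorm(40) + (lb == "hi") * 0.8
  ours <- roc_auc(sc, lb)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("lo", "hi"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("cross-validation separates separable clusters and is seeded", {
  fm <- synthetic_fm(n_per_class = 15, channels = c("A", "B"),
                     planted = "A", effect = 8)
  r <- crossval(fm, seed = 1)
  expect_equal(r$accuracy, 100)
  expect_equal(r$auc, 1)
  expect_equal(sum(r$confusion), 30)
  expect_equal(mean(r$fold_accuracy), r$accuracy)
  # deterministic given seed
  expect_identical(crossval(fm, seed = 3)$fold_accuracy,
                   crossval(fm, seed = 3)$fold_accuracy)
  # comparator classifiers also solve the separable case
  for (cls in c("knn", "lda", "tree"))
    expect_gte(crossval(fm, classifier = cls, seed = 1)$accuracy, 90)
})

test_that("stratified folds are balanced and guarded", {
  fm <- synthetic_fm(n_per_class = 13, channels = c("A", "B"))
  labels <- droplevels(fm$labels)
  set.seed(2)
  fold <- integer(length(labels))
  for (lev in levels(labels)) {
    idx <- sample(which(labels == lev))
    fold[idx] <- rep_len(seq_len(5), length(idx))
  }
  per_class <- table(fold, labels)
  expect_lte(max(per_class) - min(per_class), 1)
  expect_error(crossval(fm_subset(fm, samples = c(1:3, 14:16))), "folds")
  expect_error(crossval(fm_subset(fm, samples = 1:13)), "binary|two")
})

test_that("permuted labels on fixed features give chance-level accuracy", {
  fm <- synthetic_fm(n_per_class = 20, channels = LETTERS[1:10],
                     planted = "A", effect = 2)
  accs <- vapply(1:50, function(s) {
    set.seed(500 + s)
    fp <- fm
    fp$labels <- sample(fm$labels)
    crossval(fp, seed = s)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 50), 5)
})
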