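# Confusion metrics, ROC/AUC, fold splitting and the cross-validation
# harness.

test_that("confusion tabulation matches its definition", {
  cc <- confusion_counts(c(1, 0), c(1, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  cc <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  expect_error(confusion_counts(c(1, 0), c(1)), "length")
})

test_that("confusion counts match a brute-force loop on random data", {
  set.seed(1)
  y <- sample(c(0L, 1L), 1000, replace = TRUE)
  p <- sample(c(0L, 1L), 1000, replace = TRUE)
  cc <- confusion_counts(y, p)
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y)) {
    if (y[i] == 1L && p[i] == 1L) tp <- tp + 1L
    if (y[i] == 0L && p[i] == 0L) tn <- tn + 1L
    if (y[i] == 0L && p[i] == 1L) fp <- fp + 1L
    if (y[i] == 1L && p[i] == 0L) fn <- fn + 1L
  }
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(tp, tn, fp, fn))
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 1000L)
})

test_that("metrics hit their closed-form values", {
  perfect <- structure(list(TP = 50L, TN = 50L, FP = 0L, FN = 0L),
                       class = "confusion_counts")
  expect_equal(unname(classification_metrics(perfect)), rep(1, 4))

  sym <- structure(list(TP = 1L, TN = 1L, FP = 1L, FN = 1L),
                   class = "confusion_counts")
  expect_equal(classification_metrics(sym),
               c(Acc = 0.5, Spe = 0.5, F1 = 0.5, MCC = 0))

  m <- classification_metrics(
    structure(list(TP = 30L, TN = 900L, FP = 9L, FN = 61L),
              class = "confusion_counts"))
  expect_equal(m[["F1"]], 60 / 130)
  expect_equal(m[["Acc"]], 930 / 1000)
  expect_equal(m[["Spe"]], 900 / 909)
  expect_equal(m[["MCC"]],
               (30 * 900 - 9 * 61) / sqrt(39 * 961 * 91 * 909))
  expect_equal(m[["MCC"]], 0.475, tolerance = 1e-3)
})

test_that("zero denominators collapse to the documented 0", {
  all_neg <- classification_metrics(
    structure(list(TP = 0L, TN = 10L, FP = 0L, FN = 5L),
              class = "confusion_counts"))
  expect_equal(all_neg[["F1"]], 0)
  expect_equal(all_neg[["MCC"]], 0)   # TP+FP column is empty
  no_neg <- classification_metrics(
    structure(list(TP = 5L, TN = 0L, FP = 0L, FN = 0L),
              class = "confusion_counts"))
  expect_equal(no_neg[["Spe"]], 0)
  expect_error(classification_metrics(
    structure(list(TP = 0L, TN = 0L, FP = 0L, FN = 0L),
              class = "confusion_counts")), "empty")
})

test_that("roc_auc reproduces its defining examples", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.4, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("roc curve runs from (0,0) to (1,1) and auc matches the
          pair-count statistic", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    y <- c(0L, 1L, sample(c(0L, 1L), n - 2, replace = TRUE))
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    r <- roc_auc(y, s)
    expect_equal(r$auc, auc_paircount(y, s), tolerance = 1e-12)
    expect_equal(r$roc$fpr[1], 0)
    expect_equal(r$roc$tpr[1], 0)
    expect_equal(utils::tail(r$roc$fpr, 1), 1)
    expect_equal(utils::tail(r$roc$tpr, 1), 1)
  }
})

test_that("auc is invariant under strictly monotone score transforms", {
  set.seed(3)
  y <- sample(c(0L, 1L), 100, replace = TRUE)
  y[1:2] <- c(0L, 1L)
  s <- rnorm(100)
  base <- roc_auc(y, s)$auc
  expect_equal(roc_auc(y, exp(s))$auc, base)
  expect_equal(roc_auc(y, 5 * s - 2)$auc, base)
})

test_that("auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  y <- sample(c(0L, 1L), 150, replace = TRUE)
  y[1:2] <- c(0L, 1L)
  s <- round(rnorm(150), 1)
  expect_equal(roc_auc(y, s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("five folds are disjoint, exhaustive and balanced to one", {
  folds <- five_fold_split(10, seed = 1)
  expect_equal(lengths(folds), rep(2L, 5))

  folds <- five_fold_split(6221, seed = 2)
  expect_equal(sort(lengths(folds), decreasing = TRUE),
               c(1245L, 1244L, 1244L, 1244L, 1244L))
  expect_equal(sort(unlist(folds)), 1:6221)

  expect_error(five_fold_split(4), "at least 5")
})

test_that("fold partition properties hold across many random cases", {
  set.seed(5)
  for (i in 1:1000) {
    n <- sample(5:300, 1)
    folds <- five_fold_split(n, seed = sample.int(1e6, 1))
    expect_equal(sort(unlist(folds)), seq_len(n))
    expect_lte(diff(range(lengths(folds))), 1L)
  }
})

test_that("fold splitting is reproducible and optionally stratified", {
  expect_identical(five_fold_split(100, seed = 7),
                   five_fold_split(100, seed = 7))
  y <- rep(c(1L, 0L), c(10, 90))
  folds <- five_fold_split(100, seed = 8, labels = y, stratify = TRUE)
  pos_per_fold <- vapply(folds, function(f) sum(y[f] == 1L), integer(1))
  expect_equal(pos_per_fold, rep(2L, 5))
})

test_that("cross_validate is reproducible and aggregates correctly", {
  ds <- generate_dataset(synthetic_spec(30, 30, length_range = c(30, 60),
                                        shift = 3, seed = 21))
  X <- feature_matrix(ds$pssms)
  cfg <- quick_pipeline(epochs = 20, hidden = 8)
  r1 <- cross_validate(X, ds$records$label, cfg, seed = 9)
  r2 <- cross_validate(X, ds$records$label, cfg, seed = 9)
  expect_identical(r1$folds, r2$folds)
  for (m in c("Acc", "Spe", "F1", "MCC", "AUC")) {
    expect_equal(r1$summary$mean[r1$summary$metric == m],
                 mean(r1$folds[[m]]), tolerance = 1e-12)
  }
  expect_equal(nrow(r1$folds), 5L)
  expect_equal(sum(r1$folds$n_test), 60L)
})

test_that("separable synthetic data is recovered by the harness", {
  ds <- generate_dataset(synthetic_spec(50, 50, length_range = c(60, 120),
                                        shift = 3, seed = 22))
  X <- feature_matrix(ds$pssms)
  rep_ <- cross_validate(X, ds$records$label, quick_pipeline(), seed = 10)
  expect_gte(rep_$summary$mean[rep_$summary$metric == "Acc"], 0.9)
})

test_that("single-class test folds yield NA AUC with a warning", {
  ds <- generate_dataset(synthetic_spec(2, 28, length_range = c(30, 50),
                                        shift = 1, seed = 23))
  X <- feature_matrix(ds$pssms)
  w <- capture_warnings(
    rep_ <- cross_validate(X, ds$records$label,
                           quick_pipeline(epochs = 10, hidden = 4),
                           seed = 11))
  expect_true(any(grepl("single class", w)))
  expect_true(anyNA(rep_$folds$AUC))
})

test_that("training never sees test-fold labels", {
  ds <- generate_dataset(synthetic_spec(15, 15, length_range = c(30, 50),
                                        seed = 24))
  X <- feature_matrix(ds$pssms)
  y <- ds$records$label
  folds <- five_fold_split(30, seed = 12)
  test_idx <- folds[[1]]
  masked <- y
  masked[test_idx] <- NA_integer_
  g <- build_knn_graph(X, k = 5, labels = masked)
  # asking the trainer to use a test node is an error: the mask holds
  expect_error(train_fastgcn(g, quick_gcn(epochs = 5, hidden = 4),
                             train_nodes = c(setdiff(1:30, test_idx),
                                             test_idx[1])),
               "unlabelled")
  # folds are a partition, so train/test never overlap by construction
  expect_length(intersect(setdiff(1:30, test_idx), test_idx), 0)
})

test_that("reports format as per-fold tables with an Average row", {
  ds <- generate_dataset(synthetic_spec(20, 20, length_range = c(30, 50),
                                        shift = 2, seed = 25))
  X <- feature_matrix(ds$pssms)
  rep_ <- cross_validate(X, ds$records$label,
                         quick_pipeline(epochs = 10, hidden = 4),
                         seed = 13)
  tab <- format_report(rep_)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$fold[6], "Average")
  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$folds$Acc, rep_$folds$Acc)
})
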