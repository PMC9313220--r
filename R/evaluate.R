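# Evaluation protocol: confusion-matrix metrics (accuracy, specificity,
# F1, Matthews correlation), ROC/AUC by threshold sweep, unstratified
# five-fold cross-validation optionally repeated many times, and
# mean +/- standard-deviation aggregation of the per-fold results.

#' Confusion counts with SIP as the positive class
#'
#' @param labels Binary 0/1 truth vector.
#' @param predictions Binary 0/1 prediction vector of the same length.
#' @return Object of class `"confusion_counts"`: list with `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels (", length(labels), ") and predictions (",
         length(predictions), ") differ in length")
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  structure(list(TP = sum(labels == 1L & predictions == 1L),
                 TN = sum(labels == 0L & predictions == 0L),
                 FP = sum(labels == 0L & predictions == 1L),
                 FN = sum(labels == 1L & predictions == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Accuracy, specificity, F1 and Matthews correlation from counts
#'
#' Standard confusion-matrix metrics:
#' \deqn{Acc = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{Spe = TN/(TN+FP)}
#' \deqn{F1 = 2TP/(2TP+FP+FN)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TN+FN)(TP+FN)(TN+FP)}}
#' Any metric whose denominator is zero is defined as 0.
#'
#' @param cc A [confusion_counts()] object.
#' @return Named numeric vector `c(Acc, Spe, F1, MCC)`.
#' @export
classification_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- cc$TP; tn <- cc$TN; fp <- cc$FP; fn <- cc$FN
  total <- tp + tn + fp + fn
  if (total == 0L) stop("empty confusion table")
  den <- sqrt(prod(c(tp + fp, tn + fn, tp + fn, tn + fp)))
  c(Acc = safe_div(tp + tn, total),
    Spe = safe_div(tn, tn + fp),
    F1 = safe_div(2 * tp, 2 * tp + fp + fn),
    MCC = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (higher
#' score = more SIP-like) and integrates the ROC curve by the trapezoid
#' rule. Tied scores are collapsed into single ROC points, so the AUC
#' equals the Mann-Whitney statistic
#' `P(score+ > score-) + 0.5 P(score+ = score-)`.
#'
#' @param labels Binary 0/1 truth vector; both classes must be present.
#' @param scores Real score vector of the same length.
#' @return List with `auc` (scalar) and `roc`, a data frame of
#'   `threshold`, `fpr`, `tpr` points from (0, 0) to (1, 1).
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores differ in length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  ends <- which(c(s[-1L] != s[-length(s)], TRUE))
  tpr <- c(0, cumsum(y == 1L)[ends] / n_pos)
  fpr <- c(0, cumsum(y == 0L)[ends] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(auc = auc,
       roc = data.frame(threshold = c(Inf, s[ends]), fpr = fpr, tpr = tpr))
}

#' Randomly partition indices into five disjoint folds
#'
#' Shuffles `1:n` and splits it into `n_folds` folds whose sizes differ
#' by at most one. Unstratified by default; stratified splitting (same
#' scheme within each class) is available when labels are supplied.
#'
#' @param n Number of samples, at least `n_folds`.
#' @param seed Seed for the shuffle.
#' @param n_folds Number of folds (default 5).
#' @param labels Optional binary labels, required when `stratify = TRUE`.
#' @param stratify Logical, default `FALSE`.
#' @return List of `n_folds` integer index vectors: disjoint, jointly
#'   covering `1:n`.
#' @export
five_fold_split <- function(n, seed = 1L, n_folds = 5L, labels = NULL,
                            stratify = FALSE) {
  n <- as.integer(n)
  n_folds <- as.integer(n_folds)
  if (n < n_folds)
    stop("need at least ", n_folds, " samples to make ", n_folds, " folds")
  split_one <- function(idx) {
    m <- length(idx)
    perm <- idx[sample.int(m)]
    sizes <- rep(m %/% n_folds, n_folds)
    extra <- m %% n_folds
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    split(perm, rep.int(seq_len(n_folds), sizes))
  }
  with_seed(seed, {
    if (stratify) {
      if (is.null(labels) || length(labels) != n)
        stop("stratified splitting requires labels of length n")
      per_class <- lapply(split(seq_len(n), labels), split_one)
      folds <- lapply(seq_len(n_folds), function(f) {
        sort(unlist(lapply(per_class, `[[`, f), use.names = FALSE))
      })
    } else {
      folds <- lapply(split_one(seq_len(n)), unname)
    }
    names(folds) <- NULL
    folds
  })
}

#' Pipeline configuration for cross-validation
#'
#' @param graph_k Neighbour count for [build_knn_graph()].
#' @param gcn A [fastgcn_config()].
#' @param classifier `"rf"`, `"knn"` or `"elm"`.
#' @param classifier_args Named list of extra classifier arguments
#'   (e.g. `n_trees`, `k`, `hidden`).
#' @param stratify Stratify the folds (default `FALSE`).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(graph_k = 10L, gcn = fastgcn_config(),
                            classifier = c("rf", "knn", "elm"),
                            classifier_args = list(), stratify = FALSE) {
  structure(list(graph_k = as.integer(graph_k), gcn = gcn,
                 classifier = match.arg(classifier),
                 classifier_args = classifier_args,
                 stratify = isTRUE(stratify)),
            class = "pipeline_config")
}

# Fit the configured classifier on training embeddings and score the
# test embeddings. Returns list(score, prediction).
fit_and_score <- function(config, E_train, y_train, E_test, seed) {
  args <- config$classifier_args
  switch(config$classifier,
         rf = {
           fit <- do.call(rf_fit, c(list(features = E_train,
                                         labels = y_train, seed = seed),
                                    args))
           predict(fit, E_test)
         },
         knn = do.call(knn_predict,
                       c(list(train_features = E_train,
                              train_labels = y_train,
                              test_features = E_test), args)),
         elm = {
           out <- do.call(elm_fit_predict,
                          c(list(train_features = E_train,
                                 train_labels = y_train,
                                 test_features = E_test, seed = seed),
                            args))
           list(score = out$score, prediction = out$prediction)
         })
}

#' Repeated five-fold cross-validation of the full pipeline
#'
#' For every repetition and fold: the k-nearest-neighbour graph is built
#' from all node features (transductive), the sampled GCN is trained with
#' its loss restricted to the four training folds (test-fold labels are
#' masked), hidden embeddings are extracted, the configured classifier is
#' fit on the training-fold embeddings and the held-out fold is scored.
#' Per-fold accuracy, specificity, F1, MCC and AUC are recorded and
#' aggregated as mean +/- sample standard deviation. All randomness is
#' derived from the master seed.
#'
#' @param features n x d numeric matrix of per-protein features.
#' @param labels Binary 0/1 vector of length n; both classes required.
#' @param config A [pipeline_config()].
#' @param repetitions Number of independent five-fold rounds (default 1;
#'   100 matches the full published protocol).
#' @param seed Master seed.
#' @return Object of class `"eval_report"`: list with `folds` (data frame
#'   of per-fold metric rows), `summary` (mean and sd per metric),
#'   `fold_assignments`, `repetitions` and `seed`. Folds whose test set
#'   contains a single class get `AUC = NA` with a warning.
#' @export
cross_validate <- function(features, labels, config = pipeline_config(),
                           repetitions = 1L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the dataset")
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) stop("repetitions must be >= 1")

  n_folds <- 5L
  seeds <- matrix(derive_seeds(seed, repetitions * (n_folds + 1L)),
                  nrow = repetitions)
  rows <- vector("list", repetitions * n_folds)
  assignments <- vector("list", repetitions)

  for (r in seq_len(repetitions)) {
    folds <- five_fold_split(n, seed = seeds[r, 1L], n_folds = n_folds,
                             labels = labels, stratify = config$stratify)
    assignments[[r]] <- folds
    for (f in seq_len(n_folds)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_len(n), test_idx)
      fold_seed <- seeds[r, f + 1L]

      masked <- labels
      masked[test_idx] <- NA_integer_
      graph <- build_knn_graph(features, k = config$graph_k,
                               labels = masked)
      gcn_cfg <- config$gcn
      gcn_cfg$seed <- fold_seed
      model <- train_fastgcn(graph, gcn_cfg, train_nodes = train_idx)
      E <- extract_embeddings(model, graph)

      res <- fit_and_score(config, E[train_idx, , drop = FALSE],
                           labels[train_idx],
                           E[test_idx, , drop = FALSE], seed = fold_seed)
      cc <- confusion_counts(labels[test_idx], res$prediction)
      met <- classification_metrics(cc)
      auc <- if (length(unique(labels[test_idx])) < 2L) {
        warning("test fold ", f, " (repetition ", r,
                ") contains a single class; AUC undefined")
        NA_real_
      } else {
        roc_auc(labels[test_idx], res$score)$auc
      }
      rows[[(r - 1L) * n_folds + f]] <-
        data.frame(repetition = r, fold = f, n_test = length(test_idx),
                   TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
                   Acc = met[["Acc"]], Spe = met[["Spe"]],
                   F1 = met[["F1"]], MCC = met[["MCC"]], AUC = auc)
    }
  }
  folds_df <- do.call(rbind, rows)
  metrics <- c("Acc", "Spe", "F1", "MCC", "AUC")
  summary_df <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds_df[[m]], na.rm = TRUE),
                  numeric(1L)),
    sd = vapply(metrics, function(m) stats::sd(folds_df[[m]], na.rm = TRUE),
                numeric(1L)),
    row.names = NULL)
  structure(list(folds = folds_df, summary = summary_df,
                 fold_assignments = assignments,
                 repetitions = repetitions, seed = seed,
                 config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("cross-validation report: %d repetition(s) x 5 folds, seed %s\n",
              x$repetitions, format(x$seed)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %6.2f%% +/- %.2f%%\n", s$metric[i],
                100 * s$mean[i], 100 * s$sd[i]))
  }
  invisible(x)
}

#' Per-fold metric table with an Average row
#'
#' Mirrors the conventional cross-validation report layout: one row per
#' fold with percentage metrics, closed by an `Average` row formatted as
#' `mean +/- sd`.
#'
#' @param report An [cross_validate()] report.
#' @param repetition Which repetition to tabulate (default 1).
#' @return A character data frame with columns `fold`, `Acc`, `Spe`,
#'   `F1`, `MCC`, `AUC`.
#' @export
format_report <- function(report, repetition = 1L) {
  stopifnot(inherits(report, "eval_report"))
  df <- report$folds[report$folds$repetition == repetition, , drop = FALSE]
  pct <- function(x) sprintf("%.2f%%", 100 * x)
  out <- data.frame(fold = as.character(df$fold),
                    Acc = pct(df$Acc), Spe = pct(df$Spe), F1 = pct(df$F1),
                    MCC = pct(df$MCC),
                    AUC = sprintf("%.4f", df$AUC),
                    stringsAsFactors = FALSE)
  avg <- function(x) sprintf("%.2f +/- %.2f%%", 100 * mean(x, na.rm = TRUE),
                             100 * stats::sd(x, na.rm = TRUE))
  out[nrow(out) + 1L, ] <- c("Average", avg(df$Acc), avg(df$Spe),
                             avg(df$F1), avg(df$MCC),
                             sprintf("%.4f +/- %.4f",
                                     mean(df$AUC, na.rm = TRUE),
                                     stats::sd(df$AUC, na.rm = TRUE)))
  out
}

#' Write an evaluation report as JSON
#'
#' @param report An [cross_validate()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(seed = report$seed, repetitions = report$repetitions,
                  folds = report$folds, summary = report$summary)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
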