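# Final interaction prediction: bootstrap-aggregated random forest with
# majority voting (the in-repo ensemble strategy), plus the KNN and ELM
# ablation classifiers. Tree induction is delegated to rpart; the
# bootstrap resampling and vote combination are implemented here.

#' Combine per-tree binary votes by majority
#'
#' @param votes n x n_trees 0/1 matrix, one column per tree.
#' @return List with `score` (fraction of trees voting 1) and
#'   `prediction` (1 iff score > 0.5; ties go to class 0).
#' @export
combine_votes <- function(votes) {
  votes <- as.matrix(votes)
  score <- rowMeans(votes)
  list(score = score, prediction = as.integer(score > 0.5))
}

#' Fit a bootstrap-aggregated random forest
#'
#' Implements the three-step ensemble strategy: (a) draw `n_trees`
#' bootstrap resamples of size n with replacement, (b) grow one decision
#' tree per resample (full depth, a random subset of `mtry` features per
#' tree), (c) combine tree outputs by majority vote, with the fraction of
#' trees voting SIP as the score.
#'
#' @param features n x d numeric training matrix.
#' @param labels Binary 0/1 vector of length n; both classes required.
#' @param n_trees Number of trees (default 100).
#' @param seed Seed controlling resampling and feature subsets.
#' @param bootstrap Set `FALSE` to fit every tree on the full sample
#'   (diagnostic hook).
#' @param mtry Features per tree; default `ceiling(sqrt(d))`.
#' @return Object of class `"sip_rf"` with a [predict.sip_rf()] method.
#' @export
rf_fit <- function(features, labels, n_trees = 100L, seed = 1L,
                   bootstrap = TRUE, mtry = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  d <- ncol(features)
  labels <- as.integer(labels)
  if (n < 2L) stop("need at least 2 training samples")
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class; both classes required")
  mtry <- as.integer(mtry %||% ceiling(sqrt(d)))
  mtry <- min(max(mtry, 1L), d)
  colnames(features) <- paste0("f", seq_len(d))
  ctrl <- rpart::rpart.control(minsplit = 2L, cp = 0, xval = 0L,
                               maxsurrogate = 0L, maxcompete = 0L)
  with_seed(seed, {
    trees <- vector("list", n_trees)
    feats <- vector("list", n_trees)
    for (b in seq_len(n_trees)) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      fs <- sort(sample.int(d, mtry))
      yb <- labels[idx]
      if (length(unique(yb)) < 2L) {
        # single-class bootstrap resample: the tree is a constant vote
        trees[[b]] <- list(constant = yb[1L])
      } else {
        df <- data.frame(.y = factor(yb, levels = c(0L, 1L)),
                         features[idx, fs, drop = FALSE])
        trees[[b]] <- rpart::rpart(.y ~ ., data = df, method = "class",
                                   control = ctrl)
      }
      feats[[b]] <- fs
    }
    structure(list(trees = trees, features = feats, n_trees = n_trees,
                   d = d, seed = seed),
              class = "sip_rf")
  })
}

#' Predict with a fitted random forest
#'
#' @param object A [rf_fit()] forest.
#' @param newdata m x d numeric matrix.
#' @param ... Unused.
#' @return List with `score` (fraction of trees voting SIP, in \[0, 1\])
#'   and `prediction` (0/1; vote ties resolved to 0).
#' @export
predict.sip_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d)
    stop("newdata has ", ncol(newdata), " features, forest expects ",
         object$d)
  colnames(newdata) <- paste0("f", seq_len(object$d))
  votes <- vapply(seq_len(object$n_trees), function(b) {
    tree <- object$trees[[b]]
    if (!is.null(tree$constant))
      return(rep(as.integer(tree$constant), nrow(newdata)))
    df <- as.data.frame(newdata[, object$features[[b]], drop = FALSE])
    cl <- predict(tree, newdata = df, type = "class")
    as.integer(as.character(cl))
  }, integer(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  combine_votes(votes)
}

#' K-nearest-neighbour classification
#'
#' Euclidean neighbours in feature space; the score of a test point is
#' the fraction of its `k` nearest training points labelled SIP, and the
#' prediction is 1 iff that fraction exceeds 0.5 (ties to class 0).
#'
#' @param train_features n x d training matrix.
#' @param train_labels Binary 0/1 vector of length n.
#' @param test_features m x d matrix to score.
#' @param k Number of neighbours, `1 <= k <= n`.
#' @return List with `score` and `prediction` vectors of length m.
#' @export
knn_predict <- function(train_features, train_labels, test_features,
                        k = 5L) {
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  k <- as.integer(k)
  n <- nrow(train_features)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds the number of training points (",
                  n, ")")
  train_labels <- as.integer(train_labels)
  d2 <- outer(rowSums(test_features^2), rowSums(train_features^2), "+") -
    2 * tcrossprod(test_features, train_features)
  score <- apply(d2, 1L, function(row) {
    mean(train_labels[order(row)[seq_len(k)]])
  })
  list(score = unname(score), prediction = as.integer(score > 0.5))
}

#' Extreme learning machine classification
#'
#' Single hidden layer with seeded random input weights and biases,
#' sigmoid activations and output weights fit by least squares
#' (Moore-Penrose pseudo-inverse) against +/-1 targets. The score is the
#' logistic of the real-valued output; the prediction is its sign.
#'
#' @param train_features n x d training matrix.
#' @param train_labels Binary 0/1 vector.
#' @param test_features m x d matrix to score.
#' @param hidden Hidden-layer width (default 256).
#' @param seed Seed for the random projection.
#' @return List with `score` (in (0, 1)) and `prediction` (0/1) for the
#'   test points, plus `train_score` for the training points.
#' @export
elm_fit_predict <- function(train_features, train_labels, test_features,
                            hidden = 256L, seed = 1L) {
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  hidden <- as.integer(hidden)
  if (hidden < 1L) stop("hidden must be >= 1")
  d <- ncol(train_features)
  y2 <- 2 * as.integer(train_labels) - 1
  with_seed(seed, {
    Win <- matrix(stats::runif(d * hidden, -1, 1), d, hidden)
    bias <- stats::runif(hidden, -1, 1)
  })
  Htr <- stats::plogis(sweep(train_features %*% Win, 2L, bias, "+"))
  Hte <- stats::plogis(sweep(test_features %*% Win, 2L, bias, "+"))
  degenerate <- nrow(Htr) > 1L &&
    all(apply(Htr, 2L, function(col) diff(range(col))) < 1e-12)
  if (degenerate) {
    warning("degenerate hidden outputs (all rows identical); ",
            "falling back to ridge-regularised output weights")
    beta <- solve(crossprod(Htr) + 1e-6 * diag(hidden), crossprod(Htr, y2))
  } else {
    beta <- MASS::ginv(Htr) %*% y2
  }
  out <- drop(Hte %*% beta)
  tr <- drop(Htr %*% beta)
  list(score = stats::plogis(out), prediction = as.integer(out > 0),
       train_score = stats::plogis(tr),
       train_prediction = as.integer(tr > 0))
}
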