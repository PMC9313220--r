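# Independent brute-force oracles and small fixture builders shared by
# the test files. Oracles deliberately use naive loops, not the package
# code paths they check.

# Random integer-valued PSSM over a random standard-residue sequence.
random_pssm <- function(n, seed = 1, normalized = FALSE) {
  withr_seed(seed)
  p <- pssm(matrix(round(rnorm(n * 20, 0, 2)), n, 20),
            paste(sample(AA_STANDARD, n, replace = TRUE), collapse = ""))
  if (normalized) p <- normalize_pssm(p)
  p
}

# Minimal seed setter local to the helper (tests restore nothing; each
# test sets what it needs).
withr_seed <- function(seed) set.seed(seed)

# Hand-built protein_graph from explicit parts (bypasses kNN
# construction so degenerate topologies like isolated self-loops can be
# tested).
manual_graph <- function(A_hat, features, q = NULL, labels = NULL) {
  n <- nrow(A_hat)
  structure(list(n = n, features = features, adjacency_hat = A_hat,
                 sampling_dist = q %||% rep(1 / n, n), labels = labels),
            class = "protein_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Composition oracle: explicit double loop over (residue, column).
composition_bruteforce <- function(p) {
  S <- plogis(p$scores)[, sipgraph::AA_STANDARD, drop = FALSE]
  res <- strsplit(p$residues, "")[[1]]
  out <- numeric(0)
  for (a in sipgraph::AA_STANDARD) {
    for (j in 1:20) {
      rows <- which(res == a)
      out <- c(out, if (length(rows)) mean(S[rows, j]) else 0)
    }
  }
  out
}

# Autocovariance oracle: explicit triple loop.
ac_bruteforce <- function(p, lg) {
  S <- plogis(p$scores)[, sipgraph::AA_STANDARD, drop = FALSE]
  n <- nrow(S)
  out <- numeric(0)
  for (j in 1:20) {
    mu <- mean(S[, j])
    for (l in 1:lg) {
      acc <- 0
      for (i in 1:(n - l)) acc <- acc + (S[i, j] - mu) * (S[i + l, j] - mu)
      out <- c(out, acc / (n - l))
    }
  }
  out
}

# Full-batch layer oracle: explicit double loop over (v, u).
layer_bruteforce <- function(H, A_hat, W, activate = TRUE) {
  n <- nrow(A_hat)
  HW <- H %*% W
  out <- matrix(0, n, ncol(HW))
  for (v in 1:n) {
    for (u in 1:n) out[v, ] <- out[v, ] + A_hat[v, u] * HW[u, ]
  }
  if (activate) out[out < 0] <- 0
  out
}

# Mann-Whitney oracle: exhaustive positive/negative pair count.
auc_paircount <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Cross-entropy + L2 oracle written independently of fastgcn_loss.
loss_bruteforce <- function(logits, y, weights, lambda) {
  ce <- 0
  for (i in seq_along(y)) {
    z <- logits[i, ]
    p <- exp(z) / sum(exp(z))
    ce <- ce - log(p[y[i] + 1])
  }
  ce / length(y) + lambda * sum(vapply(weights, function(w) sum(w^2),
                                       numeric(1)))
}

# Reduced-width GCN configuration for unit checks: full epoch count but
# a narrower hidden layer than the 256-unit default keeps tests quick.
quick_gcn <- function(epochs = 200, hidden = 64, seed = 1) {
  fastgcn_config(epochs = epochs, hidden = hidden, seed = seed)
}

quick_pipeline <- function(..., n_trees = 25, graph_k = 5) {
  pipeline_config(graph_k = graph_k, gcn = quick_gcn(...),
                  classifier_args = list(n_trees = n_trees))
}
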