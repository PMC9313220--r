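# Protein graph construction and the sampled graph convolutional
# network: full-batch layer propagation, the Monte-Carlo layer
# estimator, supervised training and embedding extraction.
#
# The layer propagation is viewed as an integral of A_hat(v, u) h(u) W
# over a probability measure P on the vertex set; sampling t nodes from
# P and importance-weighting each draw by 1 / (t * q(u)) yields an
# estimator whose expectation equals the full-batch product A_hat H W
# for any strictly positive sampling distribution q.

#' Build a cosine k-nearest-neighbour protein graph
#'
#' Connects each protein to its `k` most cosine-similar neighbours,
#' symmetrises the edge set by union, adds self-loops and applies the
#' symmetric normalization `A_hat = D^{-1/2} (A + I) D^{-1/2}`. The node
#' sampling distribution defaults to the variance-reducing importance
#' weights `q(u)` proportional to the squared Euclidean norm of column
#' `u` of `A_hat`; a uniform distribution is available.
#'
#' @param features Numeric n x d matrix of node features (the layer-0
#'   embeddings).
#' @param k Number of neighbours per node; `1 <= k < n`.
#' @param labels Optional binary (0/1, `NA` = unlabelled) node labels.
#' @param sampling `"importance"` (default) or `"uniform"`.
#' @return An object of class `"protein_graph"`: a list with `n`,
#'   `features`, `adjacency_hat`, `sampling_dist` and `labels`.
#' @export
build_knn_graph <- function(features, k = 10L, labels = NULL,
                            sampling = c("importance", "uniform")) {
  sampling <- match.arg(sampling)
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) stop("need at least 2 nodes to build a graph")
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  if (k >= n) stop("k (", k, ") must be smaller than the node count (", n, ")")
  norms <- sqrt(rowSums(features^2))
  if (any(norms == 0)) {
    stop("zero-norm feature row at node(s): ",
         paste(which(norms == 0), collapse = ", "))
  }
  X <- features / norms
  S <- tcrossprod(X)
  diag(S) <- -Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, order(S[i, ], decreasing = TRUE)[seq_len(k)]] <- 1
  }
  A <- pmax(A, t(A))        # union symmetrisation
  diag(A) <- 1              # self-loops
  dinv <- 1 / sqrt(rowSums(A))
  A_hat <- A * tcrossprod(dinv)
  q <- switch(sampling,
              importance = colSums(A_hat^2),
              uniform = rep(1, n))
  q <- q / sum(q)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    labels <- as.integer(labels)
  }
  structure(list(n = n, features = features, adjacency_hat = A_hat,
                 sampling_dist = q, labels = labels),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat(sprintf("protein graph: %d nodes, %d features, %d labelled\n",
              x$n, ncol(x$features),
              if (is.null(x$labels)) 0L else sum(!is.na(x$labels))))
  invisible(x)
}

#' Full-batch graph convolution layer
#'
#' The exact population form of one propagation step:
#' `sigma(A_hat %*% H %*% W)`, optionally without the nonlinearity.
#'
#' @param H n x d input embedding matrix.
#' @param graph A [build_knn_graph()] object.
#' @param W d x d' weight matrix.
#' @param activate Apply the ReLU nonlinearity (default `TRUE`).
#' @return n x d' output matrix.
#' @export
gcn_layer_full <- function(H, graph, W, activate = TRUE) {
  H <- as.matrix(H); W <- as.matrix(W)
  if (nrow(H) != graph$n)
    stop("H has ", nrow(H), " rows but the graph has ", graph$n, " nodes")
  if (ncol(H) != nrow(W))
    stop("shape mismatch: H is ", nrow(H), "x", ncol(H), " but W is ",
         nrow(W), "x", ncol(W))
  out <- graph$adjacency_hat %*% (H %*% W)
  if (activate) out <- relu(out)
  out
}

#' Monte-Carlo sampled graph convolution layer
#'
#' Estimates the full-batch pre-activation `A_hat H W` by drawing `t`
#' i.i.d. node indices `u_1..u_t` from the graph's sampling distribution
#' `q` and averaging the importance-weighted contributions
#' `A_hat(v, u_j) H[u_j, ] W / (t * q(u_j))`. The estimator is unbiased
#' for the full-batch pre-activation at every node and for any strictly
#' positive `q`; with `exhaustive = TRUE` sampling is replaced by an
#' enumeration of all nodes (weights `1 / (n * q)`), which reproduces the
#' full-batch layer exactly under a uniform sampling distribution.
#'
#' @inheritParams gcn_layer_full
#' @param t Number of sampled nodes, `1 <= t <= n`.
#' @param seed Optional seed for the draw (caller's RNG restored after).
#' @param exhaustive Deterministic test mode: enumerate every node once.
#' @return n x d' output matrix (activated unless `activate = FALSE`).
#' @export
gcn_layer_sampled <- function(H, graph, W, t, seed = NULL, activate = TRUE,
                              exhaustive = FALSE) {
  H <- as.matrix(H); W <- as.matrix(W)
  n <- graph$n
  q <- graph$sampling_dist
  if (!exhaustive) {
    t <- as.integer(t)
    if (t < 1L || t > n) stop("sample count t must satisfy 1 <= t <= n")
  }
  if (ncol(H) != nrow(W))
    stop("shape mismatch: H is ", nrow(H), "x", ncol(H), " but W is ",
         nrow(W), "x", ncol(W))
  if (exhaustive) {
    idx <- seq_len(n)
    w <- 1 / (n * q)
  } else {
    idx <- with_seed(seed, sample.int(n, t, replace = TRUE, prob = q))
    w <- 1 / (t * q[idx])
  }
  out <- graph$adjacency_hat[, idx, drop = FALSE] %*%
    ((H[idx, , drop = FALSE] * w) %*% W)
  if (activate) out <- relu(out)
  out
}

#' Training configuration for the sampled GCN
#'
#' Defaults follow the grid-searched settings of the underlying study:
#' learning rate 0.1, one hidden layer of 256 neurons, 200 iterations,
#' cross-entropy loss with an L2 weight penalty. The per-layer sample
#' size defaults to `min(256, n)`.
#'
#' @param lr Learning rate.
#' @param epochs Number of gradient iterations.
#' @param hidden Hidden-layer width.
#' @param lambda L2 weight-penalty coefficient.
#' @param t_l Per-layer Monte-Carlo sample size (`NULL` = `min(256, n)`).
#' @param optimizer `"sgd"` (plain gradient descent, the default: stable
#'   at the published learning rate) or `"adam"`.
#' @param seed Seed controlling initialisation and layer sampling.
#' @return A list of class `"fastgcn_config"`.
#' @export
fastgcn_config <- function(lr = 0.1, epochs = 200L, hidden = 256L,
                           lambda = 5e-4, t_l = NULL,
                           optimizer = c("sgd", "adam"), seed = 1L) {
  structure(list(lr = lr, epochs = as.integer(epochs),
                 hidden = as.integer(hidden), lambda = lambda,
                 t_l = if (is.null(t_l)) NULL else as.integer(t_l),
                 optimizer = match.arg(optimizer), seed = seed),
            class = "fastgcn_config")
}

# One-hot matrix for binary labels (columns: class 0, class 1).
one_hot2 <- function(y) cbind(`0` = 1 - y, `1` = y)

#' Cross-entropy + L2 loss of a GCN on a node subset
#'
#' Mean per-node cross-entropy of the softmaxed final-layer outputs over
#' `node_subset`, plus `lambda` times the summed squared Frobenius norms
#' of all weight matrices.
#'
#' @param model A [train_fastgcn()] model (or a list with `weights` and
#'   `config$lambda`).
#' @param graph A labelled [build_knn_graph()] object.
#' @param node_subset Integer indices of labelled nodes to score.
#' @return Scalar loss.
#' @export
fastgcn_loss <- function(model, graph, node_subset) {
  if (!length(node_subset)) stop("node_subset must not be empty")
  y <- graph$labels[node_subset]
  if (anyNA(y)) stop("all nodes in node_subset must be labelled")
  H <- graph$features
  nw <- length(model$weights)
  for (l in seq_len(nw)) {
    H <- gcn_layer_full(H, graph, model$weights[[l]], activate = l < nw)
  }
  P <- row_softmax(H[node_subset, , drop = FALSE])
  ce <- -mean(log(pmax(P[cbind(seq_along(node_subset), y + 1L)], 1e-12)))
  ce + model$config$lambda * sum(vapply(model$weights,
                                        function(w) sum(w^2), numeric(1L)))
}

# Glorot-uniform initialisation.
glorot <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

#' Train a two-layer sampled GCN node classifier
#'
#' Minimises the cross-entropy + L2 loss over the labelled training
#' nodes, propagating each layer through the Monte-Carlo sampled
#' estimator of [gcn_layer_sampled()] (fresh node samples per layer and
#' epoch, importance-weighted by the graph's sampling distribution).
#' Architecture: input -> `hidden` ReLU units -> 2 output classes.
#' Fully reproducible from `config$seed`.
#'
#' @param graph A [build_knn_graph()] object with labels.
#' @param config A [fastgcn_config()].
#' @param train_nodes Indices of nodes whose labels are used; defaults to
#'   all labelled nodes. Test-fold labels must be `NA` or excluded here.
#' @return An object of class `"gcn_model"`: list with `weights` (list of
#'   two matrices), `activation`, `layer_dims`, `config` and
#'   `loss_trajectory` (per-epoch sampled-batch loss).
#' @export
train_fastgcn <- function(graph, config = fastgcn_config(),
                          train_nodes = NULL) {
  stopifnot(inherits(graph, "protein_graph"))
  if (is.null(graph$labels)) stop("graph has no labels to train on")
  if (is.null(train_nodes)) train_nodes <- which(!is.na(graph$labels))
  train_nodes <- as.integer(train_nodes)
  if (!length(train_nodes)) stop("no labelled training nodes")
  y <- graph$labels[train_nodes]
  if (anyNA(y)) stop("train_nodes include unlabelled nodes")

  n <- graph$n
  d <- ncol(graph$features)
  h <- config$hidden
  t_l <- min(config$t_l %||% 256L, n)
  q <- graph$sampling_dist
  A <- graph$adjacency_hat
  H0 <- graph$features
  Y <- one_hot2(y)
  nb <- length(train_nodes)
  lam <- config$lambda

  with_seed(config$seed, {
    W0 <- glorot(d, h)
    W1 <- glorot(h, 2L)
    m0 <- v0 <- matrix(0, d, h)
    m1 <- v1 <- matrix(0, h, 2L)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    traj <- numeric(config$epochs)

    for (ep in seq_len(config$epochs)) {
      S0 <- sample.int(n, t_l, replace = TRUE, prob = q)
      S1 <- sample.int(n, t_l, replace = TRUE, prob = q)
      w0 <- 1 / (t_l * q[S0])
      w1 <- 1 / (t_l * q[S1])
      A1 <- A[S1, S0, drop = FALSE] * rep(w0, each = t_l)
      A2 <- A[train_nodes, S1, drop = FALSE] * rep(w1, each = nb)
      X0 <- H0[S0, , drop = FALSE]

      Z1 <- A1 %*% (X0 %*% W0)
      H1 <- relu(Z1)
      Z2 <- A2 %*% (H1 %*% W1)
      P <- row_softmax(Z2)
      traj[ep] <- -mean(log(pmax(P[cbind(seq_len(nb), y + 1L)], 1e-12))) +
        lam * (sum(W0^2) + sum(W1^2))

      dZ2 <- (P - Y) / nb
      dW1 <- crossprod(A2 %*% H1, dZ2) + 2 * lam * W1
      dH1 <- crossprod(A2, dZ2) %*% t(W1)
      dZ1 <- dH1 * (Z1 > 0)
      dW0 <- crossprod(A1 %*% X0, dZ1) + 2 * lam * W0

      if (config$optimizer == "adam") {
        m0 <- b1 * m0 + (1 - b1) * dW0; v0 <- b2 * v0 + (1 - b2) * dW0^2
        m1 <- b1 * m1 + (1 - b1) * dW1; v1 <- b2 * v1 + (1 - b2) * dW1^2
        c1 <- 1 - b1^ep; c2 <- 1 - b2^ep
        W0 <- W0 - config$lr * (m0 / c1) / (sqrt(v0 / c2) + eps)
        W1 <- W1 - config$lr * (m1 / c1) / (sqrt(v1 / c2) + eps)
      } else {
        W0 <- W0 - config$lr * dW0
        W1 <- W1 - config$lr * dW1
      }
    }
    structure(list(weights = list(W0, W1), activation = "relu",
                   layer_dims = c(d, h, 2L), config = config,
                   train_nodes = train_nodes, loss_trajectory = traj),
              class = "gcn_model")
  })
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("sampled GCN: layers %s, %d epochs, final loss %.4f\n",
              paste(x$layer_dims, collapse = "-"), x$config$epochs,
              utils::tail(x$loss_trajectory, 1L)))
  invisible(x)
}

#' Hidden-layer embeddings from a trained GCN
#'
#' Deterministic full-batch (non-sampled) forward pass through the first
#' layer; returns the post-activation hidden representation used as
#' downstream classifier features.
#'
#' @param model A [train_fastgcn()] model.
#' @param graph The graph to embed (feature width must match the model).
#' @return n x hidden matrix of non-negative embeddings.
#' @export
extract_embeddings <- function(model, graph) {
  if (ncol(graph$features) != nrow(model$weights[[1L]]))
    stop("graph feature width (", ncol(graph$features),
         ") does not match model input width (",
         nrow(model$weights[[1L]]), ")")
  gcn_layer_full(graph$features, graph, model$weights[[1L]], activate = TRUE)
}

#' Class probabilities from a trained GCN
#'
#' Full-batch forward pass through both layers followed by a softmax.
#'
#' @param object A [train_fastgcn()] model.
#' @param graph The graph to score.
#' @param ... Unused.
#' @return List with `prob` (n x 2 matrix) and `class` (0/1 vector).
#' @export
predict.gcn_model <- function(object, graph, ...) {
  H1 <- extract_embeddings(object, graph)
  Z <- gcn_layer_full(H1, graph, object$weights[[2L]], activate = FALSE)
  P <- row_softmax(Z)
  list(prob = P, class = as.integer(P[, 2L] > P[, 1L]))
}
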