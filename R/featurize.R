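# Fixed-length descriptors from variable-length PSSM profiles: the
# 400-dimensional residue-grouped composition fed to the graph network,
# and the autocovariance (AC) baseline.

#' Map raw PSSM log-odds scores to (0, 1)
#'
#' Applies the logistic function 1 / (1 + exp(-x)) elementwise, turning
#' unbounded log-odds into bounded pseudo-probabilities before
#' aggregation. Idempotence is tracked through the `normalized` flag so
#' downstream featurizers never normalize twice.
#'
#' @param p A [pssm()] object.
#' @return The same object with scores in (0, 1) and `normalized = TRUE`.
#' @export
normalize_pssm <- function(p) {
  stopifnot(inherits(p, "pssm"))
  if (p$normalized) return(p)
  p$scores <- stats::plogis(p$scores)
  p$normalized <- TRUE
  p
}

#' Residue-grouped PSSM composition features
#'
#' Summarises an N x 20 profile into a fixed 400-length vector: a 20 x 20
#' matrix C where `C[a, j]` is the mean normalized score in amino-acid
#' column `j` over the positions whose residue is `a`. Rows for residues
#' absent from the sequence are zero. The matrix is flattened row-major
#' with both axes in alphabetical amino-acid order; profile columns are
#' reordered to that canonical order first so features are comparable
#' across files with different header orderings.
#'
#' @param p A [pssm()] object (normalized internally if needed).
#' @return Numeric vector of length 400 with a `scheme` attribute
#'   `"pssm_composition"`; names are `"<residue>.<column>"`.
#' @export
pssm_composition <- function(p) {
  stopifnot(inherits(p, "pssm"))
  p <- normalize_pssm(p)
  S <- p$scores[, AA_STANDARD, drop = FALSE]
  res <- strsplit(p$residues, "")[[1L]]
  keep <- res %in% AA_STANDARD
  if (!any(keep))
    stop("sequence contains no standard amino-acid residues")
  C <- matrix(0, 20L, 20L, dimnames = list(AA_STANDARD, AA_STANDARD))
  for (a in unique(res[keep])) {
    C[a, ] <- colMeans(S[res == a, , drop = FALSE])
  }
  v <- as.vector(t(C))
  names(v) <- paste(rep(AA_STANDARD, each = 20L), AA_STANDARD, sep = ".")
  attr(v, "scheme") <- "pssm_composition"
  v
}

#' Autocovariance features of a PSSM profile
#'
#' The baseline descriptor: for each of the 20 profile columns `j` (in
#' canonical order, normalized scores `S`) and each lag `l = 1..lg`,
#' `AC(l, j) = (1 / (N - l)) * sum_i (S[i, j] - mu_j) (S[i + l, j] - mu_j)`
#' with `mu_j` the column mean. Output is ordered column-major then lag,
#' giving `20 * lg` values.
#'
#' @param p A [pssm()] object (normalized internally if needed).
#' @param lg Maximum lag; must be smaller than the profile length.
#' @return Numeric vector of length `20 * lg` with a `scheme` attribute
#'   `"ac"`.
#' @export
ac_features <- function(p, lg = 5L) {
  stopifnot(inherits(p, "pssm"))
  lg <- as.integer(lg)
  if (lg < 1L) stop("lag bound lg must be >= 1")
  p <- normalize_pssm(p)
  S <- p$scores[, AA_STANDARD, drop = FALSE]
  n <- nrow(S)
  if (n <= lg)
    stop("profile with ", n, " residues is too short for lag bound ", lg)
  mu <- colMeans(S)
  out <- numeric(20L * lg)
  nm <- character(20L * lg)
  k <- 0L
  for (j in seq_len(20L)) {
    x <- S[, j] - mu[j]
    for (l in seq_len(lg)) {
      k <- k + 1L
      out[k] <- sum(x[seq_len(n - l)] * x[(l + 1L):n]) / (n - l)
      nm[k] <- paste0(AA_STANDARD[j], ".lag", l)
    }
  }
  names(out) <- nm
  attr(out, "scheme") <- "ac"
  out
}

#' Feature matrix for a set of proteins
#'
#' Applies a per-protein featurizer across a list of profiles and stacks
#' the results into a proteins x features matrix.
#'
#' @param pssms Named list of [pssm()] objects.
#' @param scheme `"pssm_composition"` (default) or `"ac"`.
#' @param lg Lag bound for the AC scheme.
#' @return Numeric matrix with one row per protein (rownames from
#'   `names(pssms)`).
#' @export
feature_matrix <- function(pssms, scheme = c("pssm_composition", "ac"),
                           lg = 5L) {
  scheme <- match.arg(scheme)
  f <- switch(scheme,
              pssm_composition = pssm_composition,
              ac = function(p) ac_features(p, lg = lg))
  rows <- lapply(pssms, f)
  X <- do.call(rbind, rows)
  rownames(X) <- names(pssms)
  X
}

#' Write a feature matrix as delimited text
#'
#' @param X Feature matrix with protein IDs as rownames.
#' @param path Output path (tab-separated, ID first column).
#' @return `path`, invisibly.
#' @export
write_features <- function(X, path) {
  df <- data.frame(id = rownames(X) %||% as.character(seq_len(nrow(X))),
                   X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
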