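# Seeded generator of labelled synthetic proteins with PSSM-like
# profiles and a plantable class-mean shift, so the whole pipeline is
# testable without PSI-BLAST runs or database downloads.

#' Specification of a synthetic SIP dataset
#'
#' Describes a dataset of random proteins whose integer score matrices
#' are discretised Gaussian noise (mean 0, sd 2), with an effect size
#' `shift` added to the designated profile columns of positive-class
#' proteins. With `shift = 0` the two classes are exchangeable.
#'
#' @param n_pos,n_neg Number of SIP (label 1) and non-SIP (label 0)
#'   proteins. Realistic imbalance presets are in [SIP_CLASS_SIZES].
#' @param length_range Two-element integer range of residue counts per
#'   protein, within \[1, 5000\]. The default \[50, 300\] keeps profiles
#'   inside the curated length band while staying small.
#' @param shift Class-mean effect size added to `signal_cols` for
#'   positive proteins (profile-score units).
#' @param signal_cols Indices (1--20) of profile columns carrying the
#'   signal; must be non-empty when `shift != 0`.
#' @param noise_sd Standard deviation of the Gaussian score noise.
#' @param seed Seed making generation fully reproducible.
#' @return List of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_pos, n_neg, length_range = c(50L, 300L),
                           shift = 0, signal_cols = 1:3, noise_sd = 2,
                           seed = 1L) {
  n_pos <- as.integer(n_pos)
  n_neg <- as.integer(n_neg)
  stopifnot(n_pos >= 0L, n_neg >= 0L)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1L] > length_range[2L] ||
      length_range[1L] < 1L || length_range[2L] > 5000L)
    stop("length_range must be an increasing pair within [1, 5000]")
  signal_cols <- as.integer(signal_cols)
  if (shift != 0 && !length(signal_cols))
    stop("shift != 0 requires a non-empty signal_cols set")
  if (length(signal_cols) &&
      (min(signal_cols) < 1L || max(signal_cols) > 20L))
    stop("signal_cols must be indices in 1..20")
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 length_range = length_range, shift = shift,
                 signal_cols = signal_cols, noise_sd = noise_sd,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic labelled dataset of PSSM-like profiles
#'
#' Per protein: a random length in `length_range`, a random sequence
#' over the 20 standard amino acids and an integer score matrix of
#' rounded Gaussian entries; positive-class proteins additionally get
#' `shift` added to the `signal_cols` columns. When `dir` is given the
#' dataset is also written to disk in the layout [load_dataset()]
#' consumes: `proteins.fasta`, one `<id>.pssm` file per protein and
#' `labels.tsv`. Byte-identical output for identical specs.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory (created if missing).
#' @return List with `records` (data frame `id`, `sequence`, `label`),
#'   `pssms` (named list of [pssm()] objects) and `spec`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_pos + spec$n_neg
  if (n < 1L) stop("empty dataset specification")
  labels <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  ids <- sprintf("prot%05d", seq_len(n))

  out <- with_seed(spec$seed, {
    pssms <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      len <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
      seqs[i] <- paste(sample(AA_STANDARD, len, replace = TRUE),
                       collapse = "")
      scores <- matrix(round(stats::rnorm(len * 20L, 0, spec$noise_sd)),
                       len, 20L)
      if (labels[i] == 1L && spec$shift != 0) {
        scores[, spec$signal_cols] <- scores[, spec$signal_cols] +
          spec$shift
      }
      pssms[[i]] <- pssm(scores, seqs[i])
    }
    list(pssms = pssms, seqs = seqs)
  })
  names(out$pssms) <- ids
  records <- data.frame(id = ids, sequence = out$seqs, label = labels,
                        stringsAsFactors = FALSE)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(records, file.path(dir, "proteins.fasta"))
    for (i in seq_len(n)) {
      write_psiblast_pssm(out$pssms[[i]],
                          file.path(dir, paste0(ids[i], ".pssm")))
    }
    writeLines(c("id\tlabel", sprintf("%s\t%d", ids, labels)),
               file.path(dir, "labels.tsv"))
  }
  list(records = records, pssms = out$pssms, spec = spec)
}
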