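# Readers and writers for the formats the pipeline touches: FASTA
# sequences, PSI-BLAST ASCII PSSM profiles and two-column label tables.

#' Construct a PSSM object
#'
#' A PSSM (position-specific scoring matrix) holds, for a protein of N
#' residues, the N x 20 matrix of per-position substitution scores produced
#' by an iterative profile search (PSI-BLAST log-odds in practice), together
#' with the residue string and the amino-acid column ordering of the source
#' file.
#'
#' @param scores Numeric matrix with exactly 20 columns and one row per
#'   residue.
#' @param residues Single string of one-letter residue codes; its length
#'   must equal `nrow(scores)`.
#' @param column_order Character vector of 20 one-letter amino-acid codes
#'   giving the column ordering; must be a permutation of the 20 standard
#'   amino acids. Defaults to alphabetical order.
#' @param normalized Logical; `TRUE` once scores have been mapped to (0, 1)
#'   by [normalize_pssm()].
#'
#' @return An object of class `"pssm"`: a list with elements `scores`,
#'   `residues`, `column_order` and `normalized`.
#' @export
#' @examples
#' p <- pssm(matrix(0, 2, 20), "AC")
#' dim(p$scores)
pssm <- function(scores, residues, column_order = AA_STANDARD,
                 normalized = FALSE) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    stop("PSSM scores must have exactly 20 columns, got ", ncol(scores))
  if (nrow(scores) < 1L)
    stop("PSSM must have at least one residue row")
  if (!is.character(residues) || length(residues) != 1L)
    stop("residues must be a single string")
  if (nchar(residues) != nrow(scores))
    stop("residue string length (", nchar(residues),
         ") does not match score rows (", nrow(scores), ")")
  if (length(column_order) != 20L || !setequal(column_order, AA_STANDARD))
    stop("column_order must be a permutation of the 20 standard amino acids")
  colnames(scores) <- column_order
  structure(list(scores = scores, residues = toupper(residues),
                 column_order = column_order,
                 normalized = isTRUE(normalized)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: %d residues x 20 amino acids%s\n", nrow(x$scores),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Read protein records from a FASTA file
#'
#' Record IDs are the first whitespace-delimited token of each header;
#' sequences are uppercased with line breaks removed. Labels are absent
#' (`NA`) until joined with a label table.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `sequence` and `label`
#'   (all `NA`), one row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1L), 1L)
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("FASTA record with empty sequence: ", headers[which(empty)[1L]])
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, sequence = unname(seqs), label = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM profile
#'
#' Accepts the standard PSI-BLAST text layout: header lines, a (usually
#' doubled) 20-letter column header, then one row per residue starting with
#' the row index and residue letter followed by at least 20 integer columns.
#' Only the first 20 numeric columns per row (the log-odds block) are kept;
#' trailing weighted-percentage columns and the statistics footer are
#' ignored.
#'
#' @param text Either the full file contents as a single string or a
#'   character vector of lines.
#' @return A [pssm()] object with the parsed scores, residue string and the
#'   verbatim column ordering of the file header.
#' @export
parse_psiblast_pssm <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(text)
  }
  header_i <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    if (length(tok) >= 20L && all(grepl("^[A-Z]$", tok[1:20]))) {
      header_i <- i
      break
    }
  }
  if (is.na(header_i))
    stop("PSSM format error: 20-letter amino-acid column header not found")
  column_order <- strsplit(trimws(lines[[header_i]]), "\\s+")[[1L]][1:20]

  rows <- list()
  residues <- character(0L)
  if (header_i < length(lines)) {
    for (i in (header_i + 1L):length(lines)) {
      ln <- trimws(lines[[i]])
      if (!nzchar(ln)) {
        if (length(rows)) break else next
      }
      tok <- strsplit(ln, "\\s+")[[1L]]
      if (!grepl("^[0-9]+$", tok[1L])) {
        if (length(rows)) break else next
      }
      rown <- length(rows) + 1L
      if (length(tok) < 22L)
        stop("PSSM format error: data row ", rown,
             " has fewer than 20 score fields")
      vals <- suppressWarnings(as.numeric(tok[3:22]))
      if (anyNA(vals))
        stop("PSSM format error: non-numeric score field in data row ", rown)
      rows[[rown]] <- vals
      residues <- c(residues, tok[2L])
    }
  }
  if (!length(rows)) stop("empty profile: no PSSM data rows found")
  scores <- do.call(rbind, rows)
  pssm(scores, paste(residues, collapse = ""), column_order)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' @param path Path to the profile file.
#' @return A [pssm()] object. See [parse_psiblast_pssm()].
#' @export
read_psiblast_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  parse_psiblast_pssm(readLines(path, warn = FALSE))
}

#' Write a PSSM object in the PSI-BLAST ASCII layout
#'
#' Emits the conventional two header lines, the doubled 20-letter column
#' header, one row per residue carrying the score block twice (standing in
#' for the log-odds and weighted-percentage blocks) plus two trailing
#' statistics columns, and a footer. Files written here re-parse through
#' [parse_psiblast_pssm()] without loss for integer-valued scores.
#'
#' @param p A [pssm()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psiblast_pssm <- function(p, path) {
  stopifnot(inherits(p, "pssm"))
  res <- strsplit(p$residues, "")[[1L]]
  fmt_row <- function(i) {
    block <- paste(sprintf("%4s", format(p$scores[i, ], trim = TRUE)),
                   collapse = "")
    sprintf("%5d %s %s %s  0.00 0.00", i, res[i], block, block)
  }
  lines <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("        ", paste(sprintf("%4s", rep(p$column_order, 2L)),
                             collapse = "")),
    vapply(seq_along(res), fmt_row, character(1L)),
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1337     0.3176"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column protein label table
#'
#' Expects delimited text with an id column and a 0/1 label column; the
#' delimiter is auto-detected among tab and comma and a header row is
#' optional.
#'
#' @param path Path to the label file.
#' @return A `data.frame` with columns `id` (character) and `label`
#'   (integer 0/1).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("label file is empty: ", path)
  sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("label file row ", bad[1L], " does not have two fields")
  ids <- trimws(vapply(parts, `[[`, character(1L), 1L))
  labs <- trimws(vapply(parts, `[[`, character(1L), 2L))
  if (is.na(suppressWarnings(as.integer(labs[1L])))) {  # header row
    ids <- ids[-1L]
    labs <- labs[-1L]
  }
  label <- suppressWarnings(as.integer(labs))
  if (anyNA(label) || !all(label %in% c(0L, 1L)))
    stop("labels must be 0 or 1; offending value: ",
         labs[which(is.na(label) | !(label %in% c(0L, 1L)))[1L]])
  data.frame(id = ids, label = label, stringsAsFactors = FALSE)
}

#' Assemble a labelled dataset from FASTA, PSSM directory and label table
#'
#' Joins the three sources on protein ID and returns only proteins present
#' in all of them. Each protein's PSSM residue string must equal its FASTA
#' sequence (after uppercasing); mismatching proteins are dropped with a
#' warning. With `curated = TRUE` the curated-set length filter of 50--5000
#' residues is enforced.
#'
#' @param fasta Path to the FASTA file.
#' @param pssm_dir Directory holding one profile per protein.
#' @param labels Path to the label table (see [read_labels()]).
#' @param pattern Filename pattern for profiles, with `%s` standing for the
#'   protein ID.
#' @param curated Logical; enforce the 50--5000 residue length filter used
#'   when curating gold-standard SIP sets.
#' @param strict Logical; if `TRUE` (default) a labelled protein without a
#'   PSSM file is a hard error listing the missing IDs, otherwise such
#'   proteins are skipped with a warning.
#' @return A list with `records` (data frame `id`, `sequence`, `label`) and
#'   `pssms` (named list of [pssm()] objects, parallel to `records`).
#' @export
load_dataset <- function(fasta, pssm_dir, labels, pattern = "%s.pssm",
                         curated = FALSE, strict = TRUE) {
  if (!dir.exists(pssm_dir)) stop("PSSM directory not found: ", pssm_dir)
  recs <- read_fasta(fasta)
  labs <- read_labels(labels)
  if (anyDuplicated(labs$id))
    stop("duplicate ids in label table: ",
         paste(unique(labs$id[duplicated(labs$id)]), collapse = ", "))
  keep <- intersect(recs$id, labs$id)
  recs <- recs[match(keep, recs$id), , drop = FALSE]
  recs$label <- labs$label[match(keep, labs$id)]

  paths <- file.path(pssm_dir, sprintf(pattern, recs$id))
  missing <- !file.exists(paths)
  if (any(missing)) {
    msg <- paste(recs$id[missing], collapse = ", ")
    if (strict) stop("missing PSSM files for labelled proteins: ", msg)
    warning("skipping proteins without PSSM files: ", msg)
    recs <- recs[!missing, , drop = FALSE]
    paths <- paths[!missing]
  }

  pssms <- lapply(paths, read_psiblast_pssm)
  names(pssms) <- recs$id
  ok <- vapply(seq_along(pssms),
               function(i) pssms[[i]]$residues == recs$sequence[i],
               logical(1L))
  if (!all(ok)) {
    warning("PSSM/FASTA sequence mismatch, dropping: ",
            paste(recs$id[!ok], collapse = ", "))
    recs <- recs[ok, , drop = FALSE]
    pssms <- pssms[ok]
  }
  if (curated) {
    len <- nchar(recs$sequence)
    inband <- len >= 50L & len <= 5000L
    if (!all(inband)) {
      warning("outside the 50-5000 residue curated band, dropping: ",
              paste(recs$id[!inband], collapse = ", "))
      recs <- recs[inband, , drop = FALSE]
      pssms <- pssms[inband]
    }
  }
  rownames(recs) <- NULL
  list(records = recs, pssms = pssms)
}
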