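# Shared constants and small internal helpers.

#' The 20 standard amino acids in alphabetical one-letter order
#'
#' Canonical ordering used for the rows and columns of composition features.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Positive/negative class sizes of the curated human and yeast SIP sets
#'
#' Reference imbalance ratios (SIPs : non-SIPs) useful as presets for
#' [synthetic_spec()] when emulating realistically imbalanced data.
#'
#' @format Named list with elements `human` and `yeast`, each
#'   `c(n_pos, n_neg)`.
#' @export
SIP_CLASS_SIZES <- list(human = c(n_pos = 1441L, n_neg = 15938L),
                        yeast = c(n_pos = 710L,  n_neg = 5511L))

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.  `seed = NULL` leaves the
# current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Draw `n` derived sub-seeds from a master seed; keeps all values well
# inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise softmax of a numeric matrix (numerically stabilised).
row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# x/y with the convention 0 when the denominator is 0 (degenerate
# confusion tables); used by classification_metrics().
safe_div <- function(x, y) if (y == 0) 0 else x / y
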