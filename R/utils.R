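#' Evaluate code under a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the caller's RNG
#' state so that package functions with a `seed` argument never disturb the
#' global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
#' @examples
#' with_seed(1, runif(1)) == with_seed(1, runif(1))
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive independent sub-seeds from one root seed
#'
#' All permutation-based stages of the pipeline draw their seeds from one
#' root seed through this function, so a single `--seed` reproduces every
#' stage while stages stay statistically independent.
#'
#' @param seed Root integer seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(42, 3)
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(n), n >= 1)
  with_seed(seed, sample.int(.Machine$integer.max - 1L, as.integer(n)))
}

#' Validate a taxa-by-samples count table
#'
#' @param x Matrix to validate.
#' @param require_integer Require whole-number entries (default `TRUE`).
#' @return `x`, invisibly, after passing all checks.
#' @keywords internal
validate_count_table <- function(x, require_integer = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("count table must be a numeric matrix (taxa rows x sample columns)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count table must have taxon rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate taxon ids in count table")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids in count table")
  if (any(x < 0)) stop("count table has negative entries")
  if (require_integer && any(abs(x - round(x)) > 1e-8)) {
    stop("count table has non-integer entries")
  }
  invisible(x)
}

#' Column-wise relative abundances
#'
#' @param table Count table (taxa x samples).
#' @return Matrix of the same shape with columns summing to 1.
#' @keywords internal
rel_abund <- function(table) {
  tot <- colSums(table)
  if (any(tot == 0)) stop("sample(s) with zero total abundance: ",
                          paste(colnames(table)[tot == 0], collapse = ", "))
  sweep(table, 2, tot, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
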