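# Input validation and RNG helpers shared across the package.

#' Validate a count matrix
#'
#' Checks that `mat` is a numeric matrix of non-negative integers with
#' `G >= 1` genes (rows) and `N >= 2` samples (columns), and attaches
#' default unique dimnames when absent.
#'
#' @param mat A numeric matrix of counts (genes x samples).
#' @param arg Name used in error messages.
#'
#' @return The validated matrix with dimnames guaranteed.
#' @keywords internal
validate_counts <- function(mat, arg = "mat") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop(arg, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(mat) < 1L || ncol(mat) < 2L) {
    stop(arg, " must have at least 1 gene (row) and 2 samples (columns)",
         call. = FALSE)
  }
  cell_label <- function(bad) {
    g <- if (!is.null(rownames(mat))) rownames(mat)[bad[["row"]]] else
      bad[["row"]]
    n <- if (!is.null(colnames(mat))) colnames(mat)[bad[["col"]]] else
      bad[["col"]]
    paste0("gene ", g, ", sample ", n)
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(arg, " contains a missing value at ", cell_label(bad),
         call. = FALSE)
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(arg, " contains a negative entry at ", cell_label(bad),
         call. = FALSE)
  }
  if (any(mat != round(mat))) {
    bad <- which(mat != round(mat), arr.ind = TRUE)[1L, ]
    stop(arg, " contains a non-integer entry at ", cell_label(bad),
         call. = FALSE)
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- paste0("gene_", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("sample_", seq_len(ncol(mat)))
  }
  if (anyDuplicated(rownames(mat))) {
    stop(arg, ": duplicated gene labels", call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop(arg, ": duplicated sample labels", call. = FALSE)
  }
  storage.mode(mat) <- "double"
  mat
}

# Coerce a design/coefficient argument to a numeric matrix with finite
# entries. NULL (or a zero-column matrix) means "block absent".
validate_block_matrix <- function(x, arg) {
  if (is.null(x)) return(NULL)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(arg, " must be a numeric matrix or vector", call. = FALSE)
  }
  if (ncol(x) == 0L) return(NULL)
  if (any(!is.finite(x))) {
    stop(arg, " must contain only finite values", call. = FALSE)
  }
  x
}

validate_permutation <- function(perm, n) {
  perm <- as.integer(perm)
  if (length(perm) != n || !identical(sort(perm), seq_len(n))) {
    stop("perm must be a permutation of 1..", n, call. = FALSE)
  }
  perm
}

# Probability that a fraction argument must obey.
validate_fraction <- function(x, arg, open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(arg, " must be a single number", call. = FALSE)
  }
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) {
    stop(arg, " must lie in ", if (open_lower) "(" else "[", "0, 1",
         if (open_upper) ")" else "]", call. = FALSE)
  }
  x
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream;
# when seed is NULL, use the ambient stream.
with_seed_or_ambient <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), force(code))
  }
}

#' Split a master seed into independent sub-seeds
#'
#' Several operations consume randomness in more than one stage (for
#' example choosing a permutation and then binomially subsampling). To keep
#' the stages reproducible independently of one another, a master seed is
#' deterministically split into sub-seeds: under the master seed, `n`
#' integers are drawn uniformly from `1 .. 2^31 - 2` with
#' `sample.int()`. Stage `i` is then run under sub-seed `i`.
#'
#' @param seed Master seed (single integer) or NULL for the ambient stream.
#' @param n Number of sub-seeds.
#'
#' @return An integer vector of length `n`, or a list of NULLs when
#'   `seed` is NULL.
#' @keywords internal
split_seed <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  as.list(withr::with_seed(as.integer(seed),
                           sample.int(2147483646L, n, replace = FALSE)))
}
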