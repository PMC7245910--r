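# Core binomial-thinning operations.
#
# The source counts are assumed to follow a log-linear count model: each
# count has log2-mean theta_gn, where Theta collects gene intercepts, any
# observed covariates, latent factors, and unstructured variation. Thinning
# each count y_gn with Binomial(y_gn, 2^{q_gn}) shifts the log2-mean to
# theta_gn + q_gn (a Poisson thinned with probability p is Poisson with
# mean scaled by p; a negative binomial keeps its size parameter and has
# its mean scaled by p). So any signal expressible as a non-positive
# G x N matrix Q on the log2 scale can be injected exactly, while all
# unwanted variation in the source data is preserved.

#' Construct the log2 thinning matrix from design/coefficient blocks
#'
#' Builds `Q = B2 X2' + B3 (Pi X3)' - e 1'`, where `e` is the row-wise
#' maximum of the un-offset matrix. Subtracting the row maximum makes every
#' binomial success probability `2^q` lie in (0, 1] and discards the fewest
#' counts compatible with injecting the requested signal; the price is a
#' per-gene intercept shift of `-e` in the thinned data.
#'
#' @param coef_fixed G x P2 coefficient matrix (log2 scale) for the
#'   fixed-row design block, or NULL for no block.
#' @param design_fixed N x P2 design matrix whose rows are never permuted.
#' @param coef_perm G x P3 coefficient matrix for the permutable block.
#' @param design_perm N x P3 design matrix whose rows may be permuted.
#' @param perm Length-N permutation of `1..N`; row `n` of the applied
#'   design is row `perm[n]` of `design_perm`. Defaults to the identity.
#'
#' @return An object of class `"thin_log"`: a list with elements `q`
#'   (G x N matrix, all entries <= 0, each row attaining 0) and `e`
#'   (length-G vector of subtracted row maxima).
#'
#' @examples
#' q <- build_thin_log(coef_perm = matrix(1), design_perm = c(0, 1))
#' q$q  # (-1, 0); one unit of log2 fold change between the two samples
#'
#' @export
build_thin_log <- function(coef_fixed = NULL, design_fixed = NULL,
                           coef_perm = NULL, design_perm = NULL,
                           perm = NULL) {
  coef_fixed  <- validate_block_matrix(coef_fixed, "coef_fixed")
  design_fixed <- validate_block_matrix(design_fixed, "design_fixed")
  coef_perm   <- validate_block_matrix(coef_perm, "coef_perm")
  design_perm <- validate_block_matrix(design_perm, "design_perm")

  has_fixed <- !is.null(coef_fixed) && !is.null(design_fixed)
  has_perm  <- !is.null(coef_perm) && !is.null(design_perm)
  if (xor(is.null(coef_fixed), is.null(design_fixed))) {
    stop("coef_fixed and design_fixed must be supplied together",
         call. = FALSE)
  }
  if (xor(is.null(coef_perm), is.null(design_perm))) {
    stop("coef_perm and design_perm must be supplied together",
         call. = FALSE)
  }
  if (!has_fixed && !has_perm) {
    stop("at least one design/coefficient block is required", call. = FALSE)
  }
  if (has_fixed && ncol(coef_fixed) != ncol(design_fixed)) {
    stop("coef_fixed and design_fixed must have the same number of columns",
         call. = FALSE)
  }
  if (has_perm && ncol(coef_perm) != ncol(design_perm)) {
    stop("coef_perm and design_perm must have the same number of columns",
         call. = FALSE)
  }
  g <- if (has_fixed) nrow(coef_fixed) else nrow(coef_perm)
  n <- if (has_fixed) nrow(design_fixed) else nrow(design_perm)
  if (has_fixed && has_perm) {
    if (nrow(coef_perm) != g) {
      stop("coefficient blocks must have the same number of genes",
           call. = FALSE)
    }
    if (nrow(design_perm) != n) {
      stop("design blocks must have the same number of samples",
           call. = FALSE)
    }
  }
  if (is.null(perm)) perm <- seq_len(n)
  perm <- validate_permutation(perm, n)

  m <- matrix(0, nrow = g, ncol = n)
  if (has_fixed) m <- m + tcrossprod(coef_fixed, design_fixed)
  if (has_perm) m <- m + tcrossprod(coef_perm, design_perm[perm, , drop = FALSE])
  e <- apply(m, 1L, max)
  q <- m - e
  structure(list(q = q, e = e), class = "thin_log")
}

#' Binomially subsample a count matrix
#'
#' Each count `y_gn` is replaced by a draw from
#' `Binomial(y_gn, 2^{q_gn})`. Entries of `q` must be non-positive and
#' finite (use a large negative value rather than `-Inf`); `q = 0` leaves a
#' cell untouched. The binomial draws consume the RNG stream in
#' column-major order over the matrix, so any two thinning operations with
#' identical `q` and seed produce identical output.
#'
#' @param mat Count matrix (genes x samples), non-negative integers.
#' @param q Either a G x N matrix of log2 thinning factors (all <= 0) or a
#'   `"thin_log"` object from [build_thin_log()].
#' @param seed Single integer seed, or NULL to use the current RNG stream.
#'
#' @return The thinned count matrix, same shape and dimnames as `mat`,
#'   elementwise no larger than `mat`.
#'
#' @examples
#' y <- matrix(rpois(20, 100), nrow = 4)
#' thinned <- binomial_thin(y, matrix(log2(0.5), 4, 5), seed = 1)
#' stopifnot(all(thinned <= y))
#'
#' @export
binomial_thin <- function(mat, q, seed = NULL) {
  mat <- validate_counts(mat)
  if (inherits(q, "thin_log")) q <- q$q
  if (!is.matrix(q) || !is.numeric(q)) {
    stop("q must be a numeric matrix", call. = FALSE)
  }
  if (!identical(dim(q), dim(mat))) {
    stop("q must have the same dimensions as mat (",
         nrow(mat), " x ", ncol(mat), ")", call. = FALSE)
  }
  if (anyNA(q)) stop("q must not contain NaN/NA", call. = FALSE)
  if (any(is.infinite(q))) {
    stop("q must be finite; replace -Inf by a large negative value",
         call. = FALSE)
  }
  if (any(q > 0)) {
    stop("q must be non-positive (2^q is a probability)", call. = FALSE)
  }
  out <- with_seed_or_ambient(seed, {
    rbinom(length(mat), size = as.vector(mat), prob = 2^as.vector(q))
  })
  out <- matrix(as.double(out), nrow = nrow(mat), ncol = ncol(mat),
                dimnames = dimnames(mat))
  out
}

#' Add signal to a count matrix with arbitrary designs
#'
#' The general signal-injection routine. The signal has two blocks: a
#' fixed-row block (`design_fixed`, `coef_fixed`) applied as given, and a
#' permutable block (`design_perm`, `coef_perm`) whose rows are reordered
#' by a permutation before application. By default the permutation is
#' uniform, which makes the injected covariates independent of any latent
#' factors in the source data. Supplying `target_cor` instead chooses the
#' permutation so that the applied design columns have approximately the
#' requested Pearson correlations with latent factors estimated from the
#' source counts (see [estimate_surrogates()], [draw_latent_target()],
#' [match_rows()]); infeasible targets are first shrunk by
#' [repair_target_correlation()].
#'
#' Alternatively, a custom non-positive `q` matrix may be supplied
#' directly, bypassing the design blocks entirely (useful for non-linear
#' signals on the log2 scale).
#'
#' @inheritParams build_thin_log
#' @inheritParams binomial_thin
#' @param mat Source count matrix (genes x samples).
#' @param target_cor P3 x K matrix of desired correlations between the
#'   columns of the applied (permuted) design and the latent factors, or
#'   NULL for a uniform permutation.
#' @param num_sv Number of latent factors to estimate when `target_cor` is
#'   used; must equal `ncol(target_cor)` (the default).
#' @param match_method Row-matching algorithm used for correlation
#'   targeting: `"hungarian"` (exact optimum), `"greedy"`, or
#'   `"gale_shapley"`.
#' @param perm Optional fixed permutation of `1..N`, overriding both the
#'   uniform draw and correlation targeting.
#' @param q Optional custom G x N non-positive matrix of log2 thinning
#'   factors, bypassing the design blocks.
#' @param verbose Log matrix sizes, the fraction of counts discarded, and
#'   (when targeting) the achieved design/factor correlation.
#'
#' @return An object of class `"thin_result"`: a list with elements
#'   `counts` (thinned matrix), `thin_log` (`q` and `e`), `permutation`
#'   (1-based; applied design row `n` is `design_perm[permutation[n], ]`),
#'   `design_fixed`, `coef_fixed`, `design_perm`, `design_perm_applied`,
#'   `coef_perm`, `target_cor`, `target_cor_used` (after feasibility
#'   repair), and `seed`.
#'
#' @examples
#' y <- simulate_base_counts(n_genes = 50, n_samples = 6,
#'                           mu = rep(log2(100), 50), seed = 1)$counts
#' x <- c(0, 0, 0, 1, 1, 1)
#' b <- matrix(rnorm(50, 0, 0.8), ncol = 1)
#' res <- thin_diff(y, design_perm = x, coef_perm = b, seed = 2)
#' dim(res$counts)
#'
#' @export
thin_diff <- function(mat,
                      design_fixed = NULL, coef_fixed = NULL,
                      design_perm = NULL, coef_perm = NULL,
                      target_cor = NULL,
                      num_sv = if (!is.null(target_cor)) ncol(target_cor),
                      match_method = c("hungarian", "greedy", "gale_shapley"),
                      perm = NULL, q = NULL, seed = NULL, verbose = FALSE) {
  mat <- validate_counts(mat)
  match_method <- match.arg(match_method)
  n <- ncol(mat)
  g <- nrow(mat)
  seeds <- split_seed(seed, 2L)  # [[1]] permutation/U-draw, [[2]] thinning

  if (!is.null(q)) {
    # Custom-Q escape hatch: pass-through contract.
    if (inherits(q, "thin_log")) q <- q$q
    thin_log <- structure(list(q = q, e = rep(0, g)), class = "thin_log")
    counts <- binomial_thin(mat, q, seed = seeds[[2L]])
    return(new_thin_result(counts = counts, thin_log = thin_log,
                           permutation = seq_len(n), seed = seed))
  }

  design_fixed <- validate_block_matrix(design_fixed, "design_fixed")
  coef_fixed   <- validate_block_matrix(coef_fixed, "coef_fixed")
  design_perm  <- validate_block_matrix(design_perm, "design_perm")
  coef_perm    <- validate_block_matrix(coef_perm, "coef_perm")
  for (d in list(design_fixed, design_perm)) {
    if (!is.null(d) && nrow(d) != n) {
      stop("design matrices must have ", n, " rows (one per sample)",
           call. = FALSE)
    }
  }
  for (b in list(coef_fixed, coef_perm)) {
    if (!is.null(b) && nrow(b) != g) {
      stop("coefficient matrices must have ", g, " rows (one per gene)",
           call. = FALSE)
    }
  }

  target_cor_used <- NULL
  if (!is.null(perm)) {
    perm <- validate_permutation(perm, n)
  } else if (!is.null(target_cor) && !is.null(design_perm)) {
    if (is.vector(target_cor)) target_cor <- matrix(target_cor, nrow = 1L)
    if (nrow(target_cor) != ncol(design_perm)) {
      stop("target_cor must have one row per column of design_perm",
           call. = FALSE)
    }
    if (!is.null(num_sv) && num_sv != ncol(target_cor)) {
      stop("num_sv must equal ncol(target_cor)", call. = FALSE)
    }
    zhat <- estimate_surrogates(mat, k = ncol(target_cor))
    s_z <- surrogate_correlation(zhat)
    target_cor_used <- repair_target_correlation(target_cor, s_z)
    u <- draw_latent_target(zhat, target_cor_used, seed = seeds[[1L]])
    perm <- match_rows(design_perm, u, method = match_method)
    if (verbose) {
      realized <- cor(design_perm[perm, , drop = FALSE], zhat$z)
      message("realized design/factor correlation: ",
              paste(signif(realized, 3), collapse = ", "))
    }
  } else {
    perm <- with_seed_or_ambient(seeds[[1L]], sample.int(n))
  }

  if (is.null(design_perm) && is.null(design_fixed)) {
    thin_log <- structure(list(q = matrix(0, g, n), e = rep(0, g)),
                          class = "thin_log")
  } else {
    thin_log <- build_thin_log(coef_fixed = coef_fixed,
                               design_fixed = design_fixed,
                               coef_perm = coef_perm,
                               design_perm = design_perm,
                               perm = perm)
  }
  counts <- binomial_thin(mat, thin_log, seed = seeds[[2L]])
  if (verbose) {
    message(g, " genes x ", n, " samples; fraction of counts discarded: ",
            signif(1 - sum(counts) / max(sum(mat), 1), 4))
  }
  new_thin_result(counts = counts, thin_log = thin_log, permutation = perm,
                  design_fixed = design_fixed, coef_fixed = coef_fixed,
                  design_perm = design_perm,
                  design_perm_applied =
                    if (!is.null(design_perm)) design_perm[perm, , drop = FALSE],
                  coef_perm = coef_perm,
                  target_cor = target_cor, target_cor_used = target_cor_used,
                  seed = seed)
}

#' Two-group differential-expression benchmark
#'
#' Thins a count matrix so that a fraction of genes acquire a known
#' log2-fold change between two sample groups. Exactly
#' `floor(group_prop * N)` samples are assigned to group 1 (chosen by
#' random permutation rather than independent coin flips, to keep the
#' design balanced across replicates), and `ceiling((1 - prop_null) * G)`
#' genes (chosen uniformly at random) receive a non-zero coefficient
#' `b_g = s_g^alpha * coef_sampler(1)`, where `s_g` is the sample standard
#' deviation of row `g` of `log2(mat + 0.5)`. `alpha = 0` specifies the
#' effect distribution directly; `alpha = 1` scales effects by each gene's
#' log-count variability (the "p-value prior" convention).
#'
#' @inheritParams thin_diff
#' @param prop_null Fraction of genes left untouched (coefficient 0).
#' @param coef_sampler Function of one argument `n` returning `n`
#'   i.i.d. log2 effect-size draws. Default: `Normal(0, 0.8^2)`.
#' @param group_prop Fraction of samples assigned to group 1.
#' @param alpha Effect-scaling exponent (see above).
#'
#' @return A `"thin_result"` (see [thin_diff()]) with two extra elements:
#'   `null_mask` (logical, TRUE for untouched genes) and `group`
#'   (the 0/1 sample indicator actually applied).
#'
#' @examples
#' y <- simulate_base_counts(n_genes = 100, n_samples = 10,
#'                           mu = rep(log2(50), 100), seed = 1)$counts
#' res <- thin_2group(y, prop_null = 0.8, seed = 2)
#' table(res$null_mask)
#'
#' @export
thin_2group <- function(mat, prop_null = 1,
                        coef_sampler = function(n) rnorm(n, 0, 0.8),
                        group_prop = 0.5, alpha = 0, seed = NULL) {
  mat <- validate_counts(mat)
  validate_fraction(prop_null, "prop_null")
  validate_fraction(group_prop, "group_prop", open_lower = TRUE,
                    open_upper = TRUE)
  n <- ncol(mat)
  seeds <- split_seed(seed, 3L)  # coefficients, group labels, thinning

  coefs <- draw_coefficients(mat, p = 1L, prop_null = prop_null,
                             sampler = coef_sampler, alpha = alpha,
                             seed = seeds[[1L]])
  n1 <- floor(group_prop * n)
  if (n1 < 1L || n1 >= n) {
    stop("group_prop leaves one group empty at N = ", n, call. = FALSE)
  }
  x <- with_seed_or_ambient(seeds[[2L]], {
    g1 <- sample.int(n, n1)
    as.numeric(seq_len(n) %in% g1)
  })
  res <- thin_diff(mat, design_perm = matrix(x, ncol = 1L),
                   coef_perm = coefs$coef, perm = seq_len(n),
                   seed = seeds[[3L]])
  res$null_mask <- coefs$null_mask
  res$group <- x
  res$seed <- seed
  res
}

#' Thin whole samples (library-size heterogeneity)
#'
#' Column `n` of the matrix is thinned with uniform probability
#' `2^{log2_factors[n]}` across genes, emulating samples sequenced to
#' different depths. On the log2 scale this adds the rank-one term
#' `1_G t(log2_factors)` to the mean matrix.
#'
#' @inheritParams binomial_thin
#' @param log2_factors Length-N vector of non-positive finite log2
#'   thinning factors, one per sample.
#'
#' @return The thinned count matrix.
#' @examples
#' y <- matrix(rpois(40, 1000), nrow = 4)
#' thinned <- thin_lib(y, log2_factors = rep(-1, 10), seed = 1)
#' colSums(thinned) / colSums(y)  # close to 0.5
#' @export
thin_lib <- function(mat, log2_factors, seed = NULL) {
  mat <- validate_counts(mat)
  check_log2_factors(log2_factors, ncol(mat), "log2_factors")
  q <- matrix(log2_factors, nrow = nrow(mat), ncol = ncol(mat), byrow = TRUE)
  binomial_thin(mat, q, seed = seed)
}

#' Thin whole genes
#'
#' Row-wise analogue of [thin_lib()]: row `g` is thinned with uniform
#' probability `2^{log2_factors[g]}` across samples, shifting that gene's
#' intercept by `log2_factors[g]`.
#'
#' @inheritParams binomial_thin
#' @param log2_factors Length-G vector of non-positive finite log2
#'   thinning factors, one per gene.
#'
#' @return The thinned count matrix.
#' @export
thin_gene <- function(mat, log2_factors, seed = NULL) {
  mat <- validate_counts(mat)
  check_log2_factors(log2_factors, nrow(mat), "log2_factors")
  q <- matrix(log2_factors, nrow = nrow(mat), ncol = ncol(mat))
  binomial_thin(mat, q, seed = seed)
}

#' Thin an entire dataset uniformly
#'
#' Every count is thinned with the same probability `2^{log2_factor}` —
#' a uniform reduction of sequencing depth. Equivalent to [thin_lib()]
#' with a constant factor vector (same seed, same output).
#'
#' @inheritParams binomial_thin
#' @param log2_factor Single non-positive finite log2 thinning factor.
#'
#' @return The thinned count matrix.
#' @export
thin_all <- function(mat, log2_factor, seed = NULL) {
  mat <- validate_counts(mat)
  check_log2_factors(log2_factor, 1L, "log2_factor")
  q <- matrix(log2_factor, nrow = nrow(mat), ncol = ncol(mat))
  binomial_thin(mat, q, seed = seed)
}

check_log2_factors <- function(x, len, arg) {
  if (!is.numeric(x) || length(x) != len) {
    stop(arg, " must be a numeric vector of length ", len, call. = FALSE)
  }
  if (anyNA(x) || any(is.infinite(x))) {
    stop(arg, " must be finite (use a large negative value, not -Inf)",
         call. = FALSE)
  }
  if (any(x > 0)) {
    stop(arg, " must be non-positive", call. = FALSE)
  }
  invisible(x)
}

new_thin_result <- function(counts, thin_log, permutation,
                            design_fixed = NULL, coef_fixed = NULL,
                            design_perm = NULL, design_perm_applied = NULL,
                            coef_perm = NULL, target_cor = NULL,
                            target_cor_used = NULL, seed = NULL) {
  structure(list(counts = counts, thin_log = thin_log,
                 permutation = permutation,
                 design_fixed = design_fixed, coef_fixed = coef_fixed,
                 design_perm = design_perm,
                 design_perm_applied = design_perm_applied,
                 coef_perm = coef_perm,
                 target_cor = target_cor, target_cor_used = target_cor_used,
                 seed = seed),
            class = "thin_result")
}

#' @export
print.thin_result <- function(x, ...) {
  cat("Thinned count matrix: ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples\n", sep = "")
  p2 <- if (is.null(x$coef_fixed)) 0L else ncol(x$coef_fixed)
  p3 <- if (is.null(x$coef_perm)) 0L else ncol(x$coef_perm)
  cat("Signal blocks: ", p2, " fixed column(s), ", p3,
      " permuted column(s)\n", sep = "")
  if (!is.null(x$target_cor)) {
    cat("Correlation targeting active (",
        nrow(x$target_cor), " x ", ncol(x$target_cor), " target)\n", sep = "")
  }
  invisible(x)
}
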