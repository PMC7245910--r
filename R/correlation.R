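# Correlation targeting: choose the design-row permutation so that the
# applied design columns have a requested Pearson correlation with latent
# factors estimated from the source counts.
#
# Pipeline: (1) estimate surrogate factors Z-hat by truncated SVD of the
# row-centered log2 counts; (2) repair the target correlation matrix R so
# that the joint normal covariance [[I, R], [R', S]] (S = sample correlation
# of Z-hat) is positive semi-definite; (3) draw a latent target matrix U
# row-wise from the conditional normal U | Z-hat; (4) permute the rows of
# the design so they match the rows of U as closely as possible.

#' Estimate surrogate factors by truncated SVD
#'
#' Computes the leading `k` right singular vectors of the row-centered
#' `log2(mat + 0.5)` matrix. Each column's sign is fixed so that its
#' largest-magnitude loading is positive, and columns are standardized to
#' mean 0, variance 1. The estimate is used only to choose the design-row
#' permutation; it never enters the thinned counts directly.
#'
#' @inheritParams binomial_thin
#' @param k Number of factors; must satisfy `1 <= k < min(G, N)`.
#'
#' @return An object of class `"surrogate_matrix"`: a list with `z`
#'   (N x k standardized factor matrix), `column_mean` and `column_sd`
#'   (pre-standardization moments), and `d` (the associated singular
#'   values).
#'
#' @export
estimate_surrogates <- function(mat, k) {
  mat <- validate_counts(mat)
  if (!is.numeric(k) || length(k) != 1L || k != round(k)) {
    stop("k must be a single integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L || k >= min(dim(mat))) {
    stop("k must satisfy 1 <= k < min(G, N) = ", min(dim(mat)),
         call. = FALSE)
  }
  l <- log2(mat + 0.5)
  l <- l - rowMeans(l)
  if (all(abs(l) < 1e-12)) {
    stop("all genes are constant across samples; no variation to decompose",
         call. = FALSE)
  }
  sv <- svd(l, nu = 0L, nv = k)
  if (sv$d[k] < 1e-10 * sv$d[1L]) {
    stop("centered log2 counts have rank < k = ", k, call. = FALSE)
  }
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(v[, j]))
    if (v[lead, j] < 0) v[, j] <- -v[, j]
  }
  mu <- colMeans(v)
  sdv <- apply(v, 2L, sd)
  z <- sweep(sweep(v, 2L, mu), 2L, sdv, "/")
  structure(list(z = z, column_mean = mu, column_sd = sdv,
                 d = sv$d[seq_len(k)]),
            class = "surrogate_matrix")
}

# Sample correlation of the (standardized) surrogate columns.
surrogate_correlation <- function(zhat) {
  stopifnot(inherits(zhat, "surrogate_matrix"))
  cor(zhat$z)
}

#' Shrink a target correlation matrix until it is feasible
#'
#' The joint normal used to draw the latent target has covariance
#' `[[I, R], [R', S]]`, which is positive semi-definite iff the Schur
#' complement `I - R S^{-1} R'` is. Infeasible targets are shrunk
#' geometrically — `R <- shrink^m * R` with the smallest `m >= 0` such that
#' the minimum eigenvalue of the Schur complement is `>= -1e-8`. A feasible
#' input is returned unchanged.
#'
#' @param target_cor P3 x K matrix (or vector for P3 = 1) of desired
#'   correlations, entries in `[-1, 1]`.
#' @param z_cor K x K sample correlation matrix of the surrogate factors
#'   (symmetric, unit diagonal, PSD).
#' @param shrink Per-iteration shrink factor in (0, 1).
#' @param max_iter Maximum number of shrink steps.
#'
#' @return The repaired matrix, a non-negative scalar multiple (<= 1) of
#'   the input, with attribute `"shrink_steps"` = number of steps applied.
#'
#' @export
repair_target_correlation <- function(target_cor, z_cor, shrink = 0.95,
                                      max_iter = 500L) {
  if (is.vector(target_cor)) target_cor <- matrix(target_cor, nrow = 1L)
  if (!is.matrix(target_cor) || !is.numeric(target_cor) ||
      anyNA(target_cor) || any(abs(target_cor) > 1)) {
    stop("target_cor must be a numeric matrix with entries in [-1, 1]",
         call. = FALSE)
  }
  if (!is.matrix(z_cor) || nrow(z_cor) != ncol(z_cor) ||
      ncol(z_cor) != ncol(target_cor)) {
    stop("z_cor must be a K x K matrix with K = ncol(target_cor)",
         call. = FALSE)
  }
  if (max(abs(z_cor - t(z_cor))) > 1e-8 || any(abs(diag(z_cor) - 1) > 1e-8)) {
    stop("z_cor must be symmetric with unit diagonal", call. = FALSE)
  }
  zinv <- safe_inverse(z_cor)
  p3 <- nrow(target_cor)
  schur_min_eig <- function(r) {
    s <- diag(p3) - r %*% zinv %*% t(r)
    min(eigen((s + t(s)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  }
  out <- target_cor
  m <- 0L
  while (schur_min_eig(out) < -1e-8 && m < max_iter) {
    out <- shrink * out
    m <- m + 1L
  }
  if (schur_min_eig(out) < -1e-8) {
    stop("could not repair target correlation within ", max_iter,
         " shrink steps", call. = FALSE)
  }
  attr(out, "shrink_steps") <- m
  out
}

# Inverse with a ridge fallback for numerically singular correlation
# matrices.
safe_inverse <- function(s) {
  inv <- tryCatch(solve(s), error = function(e) NULL)
  if (is.null(inv) || rcond(s) < 1e-12) {
    warning("surrogate correlation matrix is numerically singular; ",
            "using a ridge-regularized inverse", call. = FALSE)
    inv <- solve(s + diag(1e-6, nrow(s)))
  }
  inv
}

#' Draw the latent target matrix for row matching
#'
#' Draws `U` (N x P3) row-wise from the conditional normal distribution of
#' `u_n | z_n` under the joint model in which `(u_n, z_n)` is normal with
#' unit marginal variances, `cov(u_n, z_n) = R`, and `cov(z_n) = S` (the
#' sample correlation of the surrogates): mean `R S^{-1} z_n`, covariance
#' `I - R S^{-1} R'`. As N grows, the empirical correlation between the
#' columns of `U` and the columns of `z` converges to `R`.
#'
#' @param zhat A `"surrogate_matrix"` from [estimate_surrogates()].
#' @param target_cor Feasible P3 x K target correlation matrix (repair
#'   first with [repair_target_correlation()] if needed).
#' @param seed Single integer seed, or NULL.
#'
#' @return An N x P3 numeric matrix.
#'
#' @export
draw_latent_target <- function(zhat, target_cor, seed = NULL) {
  stopifnot(inherits(zhat, "surrogate_matrix"))
  if (is.vector(target_cor)) target_cor <- matrix(target_cor, nrow = 1L)
  z <- zhat$z
  k <- ncol(z)
  if (ncol(target_cor) != k) {
    stop("target_cor must have ", k, " columns (one per surrogate)",
         call. = FALSE)
  }
  p3 <- nrow(target_cor)
  s <- cor(z)
  sinv <- safe_inverse(s)
  cond_cov <- diag(p3) - target_cor %*% sinv %*% t(target_cor)
  cond_cov <- (cond_cov + t(cond_cov)) / 2
  ev <- eigen(cond_cov, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("target correlation is infeasible for these surrogates; ",
         "apply repair_target_correlation() first", call. = FALSE)
  }
  lam <- pmax(ev$values, 0)
  chol_like <- ev$vectors %*% diag(sqrt(lam), p3)
  cond_mean <- z %*% sinv %*% t(target_cor)
  n <- nrow(z)
  noise <- with_seed_or_ambient(seed, matrix(rnorm(n * p3), n, p3))
  cond_mean + noise %*% t(chol_like)
}

#' Match design rows to a latent target
#'
#' Finds a permutation pairing each row of `u` with a distinct row of
#' `design_perm` so that the applied design `design_perm[perm, ]` is as
#' close to `u` as possible. `"hungarian"` minimizes the total squared
#' Euclidean distance exactly (shortest augmenting path,
#' O(N^3)); `"greedy"` repeatedly pairs the globally closest remaining
#' rows (ties broken by lowest index); `"gale_shapley"` computes a stable
#' matching with both sides ranking by distance.
#'
#' @param design_perm N x P3 design matrix whose rows are to be permuted.
#' @param u N x P3 latent target matrix from [draw_latent_target()].
#' @param method Matching algorithm.
#'
#' @return An integer permutation `perm` of `1..N`: row `n` of the applied
#'   design is `design_perm[perm[n], ]`.
#'
#' @export
match_rows <- function(design_perm, u,
                       method = c("hungarian", "greedy", "gale_shapley")) {
  method <- match.arg(method)
  design_perm <- validate_block_matrix(design_perm, "design_perm")
  if (is.vector(u)) u <- matrix(u, ncol = 1L)
  if (!identical(dim(design_perm), dim(u))) {
    stop("design_perm and u must have the same dimensions", call. = FALSE)
  }
  # cost[i, j] = || u_i - x_j ||^2
  cost <- outer(rowSums(u^2), rowSums(design_perm^2), "+") -
    2 * tcrossprod(u, design_perm)
  cost <- pmax(cost, 0)
  perm <- switch(method,
                 hungarian = lap_solve_cpp(cost),
                 greedy = greedy_match_cpp(cost),
                 gale_shapley = gale_shapley_cpp(cost))
  as.integer(perm)
}

#' Monte-Carlo estimate of the realized design/factor correlation
#'
#' The row-matching pipeline achieves the target correlation only
#' approximately for general (non-normal) designs. This estimator runs the
#' draw-and-match step `n_mc` times and averages the empirical Pearson
#' correlations between the columns of the applied design and the columns
#' of the surrogates, approximating the expected realized correlation
#' conditional on the estimated factors.
#'
#' @inheritParams match_rows
#' @param zhat A `"surrogate_matrix"`.
#' @param target_cor P3 x K target correlation matrix (repaired internally
#'   if infeasible).
#' @param n_mc Number of Monte-Carlo replications.
#' @param seed Single integer seed, or NULL.
#'
#' @return A P3 x K matrix of estimated realized correlations.
#'
#' @export
estimate_realized_correlation <- function(design_perm, zhat, target_cor,
                                          n_mc = 100L,
                                          method = c("hungarian", "greedy",
                                                     "gale_shapley"),
                                          seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(zhat, "surrogate_matrix"))
  design_perm <- validate_block_matrix(design_perm, "design_perm")
  if (is.vector(target_cor)) target_cor <- matrix(target_cor, nrow = 1L)
  if (n_mc < 1L) stop("n_mc must be >= 1", call. = FALSE)
  s_z <- surrogate_correlation(zhat)
  r <- repair_target_correlation(target_cor, s_z)
  seeds <- split_seed(seed, n_mc)
  acc <- matrix(0, nrow(r), ncol(r))
  for (i in seq_len(n_mc)) {
    u <- draw_latent_target(zhat, r, seed = seeds[[i]])
    perm <- match_rows(design_perm, u, method = method)
    acc <- acc + cor(design_perm[perm, , drop = FALSE], zhat$z)
  }
  acc / n_mc
}
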