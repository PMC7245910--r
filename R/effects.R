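# Effect-size generation and signal-strength summaries.

#' Draw log2 effect-size coefficients
#'
#' Builds a G x p coefficient matrix for signal injection. A random subset
#' of `ceiling((1 - prop_null) * G)` genes (chosen uniformly without
#' replacement) is non-null; the rest get coefficient 0 in every column.
#' A non-null gene `g` receives `s_g^alpha * sampler(1)` in each column,
#' where `s_g` is the sample standard deviation of row `g` of
#' `log2(mat + 0.5)`. With `alpha = 0` the sampler specifies the effect
#' distribution directly; `alpha = 1` scales effects by each gene's
#' log-count variability. A gene with `s_g = 0` (constant across samples)
#' cannot be scaled when `alpha != 0`; such genes are forced null with a
#' warning rather than producing `0^alpha` artifacts.
#'
#' @inheritParams binomial_thin
#' @param p Number of coefficient columns.
#' @param prop_null Fraction of genes with zero coefficients.
#' @param sampler Function of one argument `n` returning `n` i.i.d. log2
#'   effect draws; must return finite values.
#' @param alpha Scaling exponent applied to `s_g`.
#'
#' @return A list with `coef` (G x p matrix) and `null_mask` (logical
#'   G-vector, TRUE for null genes).
#'
#' @export
draw_coefficients <- function(mat, p = 1L, prop_null = 1,
                              sampler = function(n) rnorm(n, 0, 0.8),
                              alpha = 0, seed = NULL) {
  mat <- validate_counts(mat)
  validate_fraction(prop_null, "prop_null")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha)) {
    stop("alpha must be a single finite number", call. = FALSE)
  }
  if (p < 1L) stop("p must be >= 1", call. = FALSE)
  g <- nrow(mat)
  n_signal <- ceiling((1 - prop_null) * g)

  with_seed_or_ambient(seed, {
    null_mask <- rep(TRUE, g)
    if (n_signal > 0L) null_mask[sample.int(g, n_signal)] <- FALSE
    coef <- matrix(0, nrow = g, ncol = p)
    if (n_signal > 0L) {
      idx <- which(!null_mask)
      if (alpha != 0) {
        s <- apply(log2(mat[idx, , drop = FALSE] + 0.5), 1L, sd)
        degenerate <- s == 0
        if (any(degenerate)) {
          warning(sum(degenerate), " constant gene(s) cannot take an ",
                  "effect scaled by s_g^alpha; forcing them null",
                  call. = FALSE)
          null_mask[idx[degenerate]] <- TRUE
          idx <- idx[!degenerate]
          s <- s[!degenerate]
        }
        scale_g <- s^alpha
      } else {
        scale_g <- rep(1, length(idx))
      }
      if (length(idx) > 0L) {
        draws <- sampler(length(idx) * p)
        if (length(draws) != length(idx) * p || anyNA(draws) ||
            any(!is.finite(draws))) {
          stop("sampler must return the requested number of finite values",
               call. = FALSE)
        }
        coef[idx, ] <- scale_g * matrix(draws, nrow = length(idx), ncol = p)
      }
    }
    rownames(coef) <- rownames(mat)
    list(coef = coef, null_mask = null_mask)
  })
}

#' Per-gene proportion of variance explained by the injected signal
#'
#' For gene `g` with injected coefficient `b_g` and applied design column
#' `x`, the proportion of variance explained is
#' `V(x * b_g) / V(log2(y_g + 0.5))`, where `y_g` is the thinned count row
#' and `V` is the sample variance (denominator `n - 1`). By convention the
#' PVE of a null gene (`b_g = 0`) is 0. A non-null gene whose thinned row
#' is constant has an undefined PVE, reported as `NA`.
#'
#' @param mat Thinned count matrix (genes x samples).
#' @param x Length-N applied design column (already permuted).
#' @param coef Length-G vector of injected log2 coefficients.
#'
#' @return A length-G numeric vector of PVE values (0 for null genes,
#'   `NA` where undefined).
#'
#' @export
compute_pve <- function(mat, x, coef) {
  mat <- validate_counts(mat)
  if (length(x) != ncol(mat)) {
    stop("x must have one entry per sample", call. = FALSE)
  }
  if (length(coef) != nrow(mat)) {
    stop("coef must have one entry per gene", call. = FALSE)
  }
  vx <- var(x)
  numer <- coef^2 * vx
  denom <- apply(log2(mat + 0.5), 1L, var)
  pve <- numer / denom
  pve[coef == 0] <- 0
  pve[coef != 0 & denom == 0] <- NA_real_
  names(pve) <- rownames(mat)
  pve
}

#' Median PVE over non-null genes
#'
#' @param pve Length-G PVE vector from [compute_pve()].
#' @param null_mask Logical G-vector, TRUE for null genes.
#'
#' @return The median PVE over non-null genes, ignoring undefined (`NA`)
#'   entries; `NA` when every gene is null.
#'
#' @export
median_pve <- function(pve, null_mask) {
  if (length(pve) != length(null_mask)) {
    stop("pve and null_mask must have the same length", call. = FALSE)
  }
  vals <- pve[!null_mask]
  if (length(vals) == 0L) return(NA_real_)
  median(vals, na.rm = TRUE)
}
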