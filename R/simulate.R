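# Synthetic base-count generation.
#
# Generates count matrices whose log2-mean matrix is
#   Theta = mu 1' + A Z' + Omega,
# i.e. gene intercepts plus an optional latent factor block plus
# unstructured log2-scale noise, with counts drawn from a Poisson,
# negative binomial, or zero-inflated negative binomial family. Every
# other module is testable against these matrices without any download.

#' Simulate a base count matrix with known structure
#'
#' @param n_genes,n_samples Matrix dimensions G and N.
#' @param mu Length-G vector (or scalar, recycled) of log2 intercepts.
#' @param factor_loadings Optional G x K loading matrix A.
#' @param factors Optional N x K factor matrix Z (required with
#'   `factor_loadings`).
#' @param omega_sd Standard deviation of i.i.d. Normal unstructured log2
#'   noise; ignored when `omega` is supplied.
#' @param omega Optional explicit G x N matrix of unstructured log2
#'   variation (the noise term is deliberately pluggable — real data's
#'   unwanted variation has no canonical distribution).
#' @param family Count family: `"poisson"`, `"nb"` (negative binomial,
#'   variance `m + m^2/size`), or `"zinb"` (NB masked by structural
#'   Bernoulli zeros).
#' @param nb_size Per-gene NB size (dispersion) parameter, scalar or
#'   length-G; the size is invariant under binomial thinning.
#' @param zero_inflation Structural zero probability for `"zinb"`, in
#'   `[0, 1)`. The NB mean is scaled by `1/(1 - zero_inflation)` so that
#'   the marginal mean of every cell stays `2^theta` in all families.
#' @param seed Single integer seed, or NULL.
#'
#' @return A list with `counts` (G x N matrix with dimnames), `theta`
#'   (the true log2-mean matrix), and the `factor_loadings` / `factors`
#'   actually used (NULL when absent).
#'
#' @examples
#' sim <- simulate_base_counts(100, 10, mu = log2(50), seed = 1)
#' mean(sim$counts)  # near 50
#'
#' @export
simulate_base_counts <- function(n_genes, n_samples, mu = log2(100),
                                 factor_loadings = NULL, factors = NULL,
                                 omega_sd = 0, omega = NULL,
                                 family = c("poisson", "nb", "zinb"),
                                 nb_size = 1, zero_inflation = 0,
                                 seed = NULL) {
  family <- match.arg(family)
  g <- as.integer(n_genes)
  n <- as.integer(n_samples)
  if (g < 1L || n < 2L) stop("need n_genes >= 1 and n_samples >= 2",
                             call. = FALSE)
  mu <- rep_len(as.numeric(mu), g)
  if (xor(is.null(factor_loadings), is.null(factors))) {
    stop("factor_loadings and factors must be supplied together",
         call. = FALSE)
  }
  if (!is.null(factor_loadings)) {
    factor_loadings <- validate_block_matrix(factor_loadings,
                                             "factor_loadings")
    factors <- validate_block_matrix(factors, "factors")
    if (nrow(factor_loadings) != g || nrow(factors) != n ||
        ncol(factor_loadings) != ncol(factors)) {
      stop("factor block must be G x K loadings and N x K factors",
           call. = FALSE)
    }
  }
  if (!is.null(omega)) {
    if (!is.matrix(omega) || !identical(dim(omega), c(g, n))) {
      stop("omega must be a G x N matrix", call. = FALSE)
    }
  }
  if (family == "nb" || family == "zinb") {
    nb_size <- rep_len(as.numeric(nb_size), g)
    if (any(nb_size <= 0)) stop("nb_size must be > 0", call. = FALSE)
  }
  if (family == "zinb") {
    validate_fraction(zero_inflation, "zero_inflation", open_upper = TRUE)
  }

  with_seed_or_ambient(seed, {
    theta <- matrix(mu, nrow = g, ncol = n)
    if (!is.null(factor_loadings)) {
      theta <- theta + tcrossprod(factor_loadings, factors)
    }
    if (!is.null(omega)) {
      theta <- theta + omega
    } else if (omega_sd > 0) {
      theta <- theta + matrix(rnorm(g * n, sd = omega_sd), g, n)
    }
    if (any(theta > 30)) {
      warning("log2-mean entries above 30 capped to avoid overflow",
              call. = FALSE)
      theta[theta > 30] <- 30
    }
    lambda <- 2^theta
    counts <- switch(family,
      poisson = rpois(g * n, lambda = as.vector(lambda)),
      nb = rnbinom(g * n, mu = as.vector(lambda), size = rep(nb_size, n)),
      zinb = {
        m <- as.vector(lambda) / (1 - zero_inflation)
        draws <- rnbinom(g * n, mu = m, size = rep(nb_size, n))
        keep <- rbinom(g * n, size = 1L, prob = 1 - zero_inflation)
        draws * keep
      })
    counts <- matrix(as.double(counts), nrow = g, ncol = n,
                     dimnames = list(paste0("gene_", seq_len(g)),
                                     paste0("sample_", seq_len(n))))
    list(counts = counts, theta = theta,
         factor_loadings = factor_loadings, factors = factors)
  })
}

#' Write a self-contained test fixture to disk
#'
#' Produces small named data bundles consumable by the command-line
#' interface and by the test suite:
#' \describe{
#'   \item{two_group_small}{500 genes x 20 samples of Poisson counts plus
#'     a balanced two-group indicator (`design.tsv`).}
#'   \item{factor_rank1}{300 genes x 40 samples with a known rank-1 latent
#'     block; the true loadings and factors are written alongside the
#'     counts for surrogate-recovery tests.}
#'   \item{null_only}{200 genes x 10 samples with no signal and an all-zero
#'     design/coefficient pair, so downstream thinning is a no-op.}
#' }
#'
#' @param name Fixture recipe.
#' @param dir Output directory (created if missing).
#' @param seed Single integer seed, or NULL.
#'
#' @return Invisibly, a named character vector of the files written.
#'
#' @export
make_fixture <- function(name = c("two_group_small", "factor_rank1",
                                  "null_only"),
                         dir, seed = NULL) {
  name <- match.arg(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(seed, 2L)
  paths <- c(counts = file.path(dir, "counts.tsv"))
  meta <- list(fixture = name, seed = seed)

  if (name == "two_group_small") {
    sim <- with_seed_or_ambient(seeds[[1L]], {
      simulate_base_counts(500L, 20L, mu = runif(500L, log2(20), log2(500)))
    })
    x <- rep(c(0, 1), each = 10L)
    paths["design"] <- file.path(dir, "design.tsv")
    write_design(matrix(x, ncol = 1L, dimnames = list(NULL, "group")),
                 paths["design"])
  } else if (name == "factor_rank1") {
    sim <- with_seed_or_ambient(seeds[[1L]], {
      a <- matrix(rnorm(300L, sd = 0.7), ncol = 1L)
      z <- matrix(rnorm(40L), ncol = 1L)
      simulate_base_counts(300L, 40L, mu = runif(300L, log2(50), log2(500)),
                           factor_loadings = a, factors = z,
                           omega_sd = 0.1)
    })
    paths["loadings"] <- file.path(dir, "loadings.tsv")
    paths["factors"] <- file.path(dir, "factors.tsv")
    write_design(sim$factor_loadings, paths["loadings"])
    write_design(sim$factors, paths["factors"])
  } else {
    sim <- with_seed_or_ambient(seeds[[1L]], {
      simulate_base_counts(200L, 10L, mu = runif(200L, log2(20), log2(200)))
    })
    paths["design"] <- file.path(dir, "design.tsv")
    paths["coef"] <- file.path(dir, "coef.tsv")
    write_design(matrix(0, 10L, 1L, dimnames = list(NULL, "null_cov")),
                 paths["design"])
    write_design(matrix(0, 200L, 1L, dimnames = list(NULL, "null_cov")),
                 paths["coef"])
  }
  write_counts(sim$counts, paths[["counts"]], format = "tsv")
  paths["meta"] <- file.path(dir, "fixture.json")
  jsonlite::write_json(meta, paths[["meta"]], auto_unbox = TRUE,
                       null = "null")
  invisible(paths)
}
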