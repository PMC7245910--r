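# Shared fixtures and independent oracles built in code.

# Small random count matrix (Poisson around `mean_count`), in the same
# representation the package returns (double storage, dimnames set).
rand_counts <- function(g, n, mean_count = 50) {
  matrix(as.double(rpois(g * n, mean_count)), nrow = g, ncol = n,
         dimnames = list(paste0("g", seq_len(g)), paste0("s", seq_len(n))))
}

# Stamp an arbitrary matrix into that representation.
counts_mat <- function(m) {
  storage.mode(m) <- "double"
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  m
}

# Random non-positive log2 thinning matrix.
rand_q <- function(g, n, max_abs = 2) {
  matrix(-runif(g * n, 0, max_abs), nrow = g, ncol = n)
}

# All permutations of 1..n (n small), as a list.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# Exhaustive-minimum assignment: perm minimizing sum_i cost[i, perm[i]].
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  best_perm <- NULL
  for (p in all_perms(n)) {
    tot <- sum(cost[cbind(seq_len(n), p)])
    if (tot < best) {
      best <- tot
      best_perm <- p
    }
  }
  list(cost = best, perm = best_perm)
}

# Drop the shrink_steps attribute for whole-object comparisons.
unclass_strip <- function(x) {
  attr(x, "shrink_steps") <- NULL
  x
}

# Wrap an N x K matrix as a surrogate_matrix (standardized columns).
make_zhat <- function(z) {
  z <- as.matrix(z)
  mu <- colMeans(z)
  sdv <- apply(z, 2L, sd)
  structure(list(z = sweep(sweep(z, 2L, mu), 2L, sdv, "/"),
                 column_mean = mu, column_sd = sdv,
                 d = rep(NA_real_, ncol(z))),
            class = "surrogate_matrix")
}
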