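# Core thinning operations: Q construction and binomial subsampling.

test_that("build_thin_log matches hand and brute-force evaluation", {
  withr::local_seed(101)

  # Zero-coefficient block: q identically zero, no offset.
  tl <- build_thin_log(coef_perm = matrix(0, 3, 1),
                       design_perm = matrix(rnorm(4), 4, 1))
  expect_equal(tl$q, matrix(0, 3, 4))
  expect_equal(tl$e, rep(0, 3))

  # Hand evaluation: G = 1, B3 = 1, x3 = (0, 1)' -> un-offset row (0, 1),
  # row max e = 1, q = (-1, 0).
  tl <- build_thin_log(coef_perm = matrix(1), design_perm = matrix(c(0, 1)))
  expect_equal(tl$q, matrix(c(-1, 0), 1, 2))
  expect_equal(tl$e, 1)

  # Brute-force matrix oracle with both blocks and a non-trivial
  # permutation: direct loop evaluation of B2 X2' + B3 X3' Pi' - e 1'.
  g <- 20L; n <- 8L
  b2 <- matrix(rnorm(g * 2), g, 2); x2 <- matrix(rnorm(n * 2), n, 2)
  b3 <- matrix(rnorm(g * 2), g, 2); x3 <- matrix(rnorm(n * 2), n, 2)
  perm <- sample.int(n)
  expected_m <- matrix(0, g, n)
  for (gi in seq_len(g)) {
    for (ni in seq_len(n)) {
      expected_m[gi, ni] <- sum(b2[gi, ] * x2[ni, ]) +
        sum(b3[gi, ] * x3[perm[ni], ])
    }
  }
  expected_e <- apply(expected_m, 1, max)
  tl <- build_thin_log(coef_fixed = b2, design_fixed = x2,
                       coef_perm = b3, design_perm = x3, perm = perm)
  expect_equal(tl$q, expected_m - expected_e, tolerance = 1e-12)
  expect_equal(tl$e, expected_e, tolerance = 1e-12)
  expect_true(all(tl$q <= 1e-12))
  expect_equal(apply(tl$q, 1, max), rep(0, g))

  expect_error(build_thin_log(coef_perm = matrix(1, 2, 1),
                              design_perm = matrix(1, 3, 2)),
               "same number of columns")
  expect_error(build_thin_log(coef_perm = matrix(NA_real_, 1, 1),
                              design_perm = matrix(1)),
               "finite")
})

test_that("binomial_thin honours its mean, bounds, and validation contract", {
  withr::local_seed(42)

  # p = 1 is deterministic; Bin(0, p) = 0.
  y <- rand_counts(10, 5)
  expect_identical(binomial_thin(y, matrix(0, 10, 5), seed = 1), y)
  y0 <- matrix(0, 4, 4)
  expect_true(all(binomial_thin(y0, rand_q(4, 4), seed = 1) == 0))

  # Closed-form binomial mean: 1000 cells of 10000 halved.
  y <- matrix(10000, 40, 25)
  thinned <- binomial_thin(y, matrix(log2(0.5), 40, 25), seed = 7)
  se <- sqrt(10000 * 0.5 * 0.5 / 1000)
  expect_lt(abs(mean(thinned) - 5000), 3 * se)

  # Validation: positive q, NaN, -Inf all rejected.
  expect_error(binomial_thin(y, matrix(0.1, 40, 25)), "non-positive")
  expect_error(binomial_thin(y, matrix(NaN, 40, 25)), "NaN")
  expect_error(binomial_thin(y, matrix(-Inf, 40, 25)), "finite")
  expect_error(binomial_thin(y, matrix(0, 2, 2)), "dimensions")
})

test_that("thinning is monotone, deterministic, and identity at Q = 0", {
  withr::local_seed(3)
  for (i in 1:20) {
    y <- rand_counts(sample(1:30, 1), sample(2:10, 1),
                     mean_count = sample(c(1, 20, 200), 1))
    q <- rand_q(nrow(y), ncol(y), max_abs = 3)
    a <- binomial_thin(y, q, seed = 1000 + i)
    b <- binomial_thin(y, q, seed = 1000 + i)
    expect_identical(a, b)
    expect_true(all(a <= y))
    expect_true(all(a >= 0))
    expect_identical(binomial_thin(y, matrix(0, nrow(y), ncol(y)),
                                   seed = i), y)
  }
})

test_that("thin_lib / thin_gene / thin_all hit their closed-form means", {
  withr::local_seed(11)

  y <- rand_counts(5, 4)
  expect_identical(thin_lib(y, rep(0, 4), seed = 1), y)
  expect_identical(thin_gene(y, rep(0, 5), seed = 1), y)
  expect_identical(thin_all(y, 0, seed = 1), y)

  # Column with ~10^6 counts halved: column total within 3 SE of 5e5.
  y <- rand_counts(2000, 3, mean_count = 500)
  f <- c(-1, 0, 0)
  thinned <- thin_lib(y, f, seed = 2)
  tot <- sum(y[, 1])
  expect_lt(abs(sum(thinned[, 1]) - tot / 2), 3 * sqrt(tot * 0.25))
  expect_identical(thinned[, 2:3], y[, 2:3])

  # Single gene at p = 0.25: count 4000 -> ~1000 within 3 SE.
  y <- counts_mat(matrix(c(rep(400, 10), rep(7, 10)), nrow = 2,
                         byrow = TRUE))
  thinned <- thin_gene(y, c(log2(0.25), 0), seed = 3)
  expect_lt(abs(sum(thinned[1, ]) - 1000), 3 * sqrt(4000 * 0.25 * 0.75))
  expect_identical(thinned[2, ], y[2, ])

  # Grand-total closed form for uniform thinning at p = 0.1.
  y <- matrix(rpois(10000, 1000), 100, 100)
  thinned <- thin_all(y, log2(0.1), seed = 4)
  expect_lt(abs(sum(thinned) - 0.1 * sum(y)),
            3 * sqrt(sum(y) * 0.1 * 0.9))

  # Factor -30 leaves a column essentially empty; -Inf rejected.
  y <- rand_counts(50, 3)
  expect_lt(sum(thin_lib(y, c(-30, 0, 0), seed = 5)[, 1]), 1)
  expect_error(thin_lib(y, c(-Inf, 0, 0)), "finite")
  expect_error(thin_lib(y, c(0.5, 0, 0)), "non-positive")

  # Consistency contract: same Q + same seed => identical output across
  # the uniform thinning wrappers.
  y <- rand_counts(30, 6)
  expect_identical(thin_all(y, -1, seed = 9),
                   thin_lib(y, rep(-1, 6), seed = 9))
  expect_identical(thin_all(y, -1, seed = 9),
                   thin_gene(y, rep(-1, 30), seed = 9))
  expect_identical(thin_all(y, -1, seed = 9),
                   binomial_thin(y, matrix(-1, 30, 6), seed = 9))
})

test_that("thin_diff: null signal, custom-Q hatch, and provenance", {
  withr::local_seed(21)
  y <- rand_counts(40, 8)

  # Null coefficients: output counts equal input exactly.
  res <- thin_diff(y, design_perm = matrix(rnorm(8), 8, 1),
                   coef_perm = matrix(0, 40, 1), seed = 5)
  expect_identical(res$counts, y)
  expect_equal(res$thin_log$e, rep(0, 40))

  # Custom-Q escape hatch equals binomial_thin on the same Q under the
  # thinning sub-seed.
  q <- rand_q(40, 8)
  res_q <- thin_diff(y, q = q, seed = 6)
  sub <- thinsim:::split_seed(6, 2L)
  expect_identical(res_q$counts, binomial_thin(y, q, seed = sub[[2L]]))
  expect_error(thin_diff(y, q = abs(q)), "non-positive")

  # Provenance: applied design is design_perm reordered by `permutation`.
  x3 <- matrix(rnorm(16), 8, 2)
  res <- thin_diff(y, design_perm = x3, coef_perm = matrix(rnorm(80), 40, 2),
                   seed = 7)
  expect_equal(res$design_perm_applied, x3[res$permutation, ])
  expect_true(all(res$counts <= y))
})

test_that("thin_diff recovers an injected two-group fold change", {
  # Point mass b = -1 on every gene: within the thinned data the per-gene
  # ratio of group means concentrates near 1/2.
  withr::local_seed(31)
  g <- 2000L; n <- 200L
  y <- simulate_base_counts(g, n, mu = log2(100), seed = 1)$counts
  x <- rep(c(0, 1), each = n / 2)
  res <- thin_diff(y, design_perm = matrix(x, ncol = 1),
                   coef_perm = matrix(-1, g, 1), perm = seq_len(n),
                   seed = 2)
  m1 <- rowMeans(res$counts[, x == 1])
  m0 <- rowMeans(res$counts[, x == 0])
  lfc <- log2(m1 / m0)
  expect_lt(abs(mean(lfc) + 1), 4 * sd(lfc) / sqrt(g))
})

test_that("permute-then-thin commutes with a fixed permutation", {
  withr::local_seed(41)
  y <- rand_counts(30, 10)
  x3 <- matrix(rnorm(20), 10, 2)
  b3 <- matrix(rnorm(60, sd = 0.5), 30, 2)
  perm <- sample.int(10)
  res1 <- thin_diff(y, design_perm = x3, coef_perm = b3, perm = perm,
                    seed = 8)
  res2 <- thin_diff(y, design_perm = x3[perm, ], coef_perm = b3,
                    perm = seq_len(10), seed = 8)
  expect_identical(res1$counts, res2$counts)
  expect_equal(res1$thin_log$q, res2$thin_log$q)
})

test_that("thin_2group builds the stated design and coefficients", {
  withr::local_seed(51)
  y <- rand_counts(200, 12)

  # Fully null: identity on the counts.
  res <- thin_2group(y, prop_null = 1, seed = 1)
  expect_identical(res$counts, y)
  expect_true(all(res$null_mask))

  # Exactly floor(group_prop * N) samples in group 1 and
  # ceiling((1 - prop_null) * G) non-null genes.
  res <- thin_2group(y, prop_null = 0.77, group_prop = 1 / 3, seed = 2)
  expect_equal(sum(res$group), floor(12 / 3))
  expect_equal(sum(!res$null_mask), ceiling(0.23 * 200))

  # alpha = 0 with a point-mass sampler: all non-null coefficients exact.
  res <- thin_2group(y, prop_null = 0.5,
                     coef_sampler = function(n) rep(-0.7, n), seed = 3)
  expect_true(all(res$coef_perm[!res$null_mask, 1] == -0.7))
  expect_true(all(res$coef_perm[res$null_mask, 1] == 0))

  # alpha = 1 with point mass 1: coefficients equal s_g recomputed with an
  # independent standard-deviation routine.
  res <- thin_2group(y, prop_null = 0.5, alpha = 1,
                     coef_sampler = function(n) rep(1, n), seed = 4)
  idx <- which(!res$null_mask)
  l2 <- log2(y + 0.5)
  s_indep <- vapply(idx, function(g) {
    v <- l2[g, ]
    sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  }, numeric(1))
  expect_equal(unname(res$coef_perm[idx, 1]), unname(s_indep),
               tolerance = 1e-12)

  expect_error(thin_2group(y, prop_null = 1.2), "0, 1")
  expect_error(thin_2group(y, group_prop = 1), "0, 1")

  # Reproducibility under the master seed.
  expect_identical(thin_2group(y, prop_null = 0.5, seed = 99)$counts,
                   thin_2group(y, prop_null = 0.5, seed = 99)$counts)
})
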