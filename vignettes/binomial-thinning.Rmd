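---
title: "Injecting known signal into RNA-seq counts by binomial thinning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Injecting known signal into RNA-seq counts by binomial thinning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thinsim)
```

## The model and its assumptions

`thinsim` assumes the source counts follow a log-linear count model:
`y_gn` has `log2 E[y_gn] = θ_gn`, where the mean matrix
`Θ = μ1ᵀ + B₁X₁ᵀ + AZᵀ + Ω` collects gene intercepts, any observed
covariates, latent factors `Z`, and arbitrary unstructured variation `Ω`.
Nothing on the right-hand side needs to be known — that is the point. The
only distributional assumption that matters is *thinning invariance*: if
`ỹ | y ~ Binomial(y, p)` then a Poisson(λ) count becomes Poisson(λp), and a
negative binomial with mean μ and size r becomes negative binomial with
mean pμ and the *same* size r; mixtures and zero-inflated variants inherit
the property. Even when the family assumption fails entirely, the law of
total expectation still gives `log2 E[Ỹ] = Θ + Q`, so the *mean* log2-fold
changes are always correct; only the mean–variance relationship may drift.

Given user blocks `(X₂, B₂)` (rows fixed) and `(X₃, B₃)` (rows permutable
by `Π`), the package forms the un-offset signal `M = B₂X₂ᵀ + B₃(ΠX₃)ᵀ`,
subtracts each row's maximum `e_g`, and thins with probabilities
`2^{Q} = 2^{M − e1ᵀ}`. The row-max subtraction serves two purposes: it
makes every probability lie in (0, 1], and it is *minimal* — each gene has
at least one sample thinned with probability 1, so no counts are discarded
beyond what the signal requires. The cost is a per-gene intercept shift
`μ → μ − e`, which is immaterial for effect-size benchmarking.

## Tunable parameters

* `prop_null` (fraction in [0, 1], default 1): fraction of genes whose
  coefficients are zero. Exactly `ceiling((1 − prop_null)·G)` genes are
  non-null, chosen uniformly without replacement — an exact count, not a
  coin flip per gene, so replicate datasets have identical signal density.
* `coef_sampler` / `alpha`: non-null gene `g` receives
  `b_g = s_g^α · draw`, with `s_g` the sample standard deviation of row `g`
  of `log2(Y + 0.5)` (unitless, log2 scale). `alpha = 0` (default)
  specifies the effect distribution directly; `alpha = 1` scales effects
  with each gene's log-count variability, the classic "p-value prior"
  convention. The default sampler is `Normal(0, 0.8²)` on the log2 scale —
  a moderate-signal regime for two-group benchmarks. A constant gene
  (`s_g = 0`) cannot carry a scaled effect; it is forced null with a
  warning instead of silently producing `0^α`.
* `group_prop` (default 0.5): exactly `floor(group_prop·N)` samples are
  assigned to group 1 by random permutation, keeping designs balanced
  across replicates.
* `target_cor` (`P₃ × K`, entries in [−1, 1]): desired Pearson correlation
  between the applied design columns and `K` latent factors. `K` has no
  default; choosing the number of factors is the caller's problem (methods
  like parallel analysis exist but are out of scope here).
* `match_method` (default `"hungarian"`): the Hungarian assignment is the
  exact minimizer of total squared distance between design rows and the
  latent target, at O(N³); `"greedy"` and `"gale_shapley"` are cheaper
  heuristics kept for parity with existing software. Greedy ties are broken
  by lowest index for determinism.
* Feasibility repair: the conditional-normal draw needs
  `I − R S⁻¹ Rᵀ ⪰ 0`. Infeasible targets are shrunk geometrically by
  λ = 0.95 per step (at most 500 steps) until the minimum eigenvalue is
  ≥ −10⁻⁸. Geometric shrinkage always terminates for |r| ≤ 1, and 0.95
  trades resolution (≈5% granularity in the achieved correlation) against
  iteration count. The repaired matrix is always a scalar multiple ≤ 1 of
  the request, so the *direction* of the target is preserved exactly.

## Correlation targeting, step by step

1. **Surrogates.** `estimate_surrogates()` takes the leading `k` right
   singular vectors of the row-centered `log2(Y + 0.5)` matrix. Full
   surrogate-variable analysis would also be a valid estimator; truncated
   SVD is the simple, deterministic choice. Signs are fixed so each
   column's largest-magnitude entry is positive, and columns are
   standardized to mean 0, variance 1. Standardizing before the draw is a
   deliberate reading of an under-specified point: the target is stated as
   a *correlation* matrix, which presumes unit marginal variances, so the
   joint covariance is instantiated as `[[I, R], [Rᵀ, S]]` with `S` the
   sample correlation of the standardized surrogates.
2. **Latent target.** Row `n` of `U` is drawn from
   `Normal(R S⁻¹ ẑ_n, I − R S⁻¹ Rᵀ)`, so `(u_n, ẑ_n)` is jointly normal
   with cross-correlation `R`. Small negative eigenvalues of the
   conditional covariance (from the −10⁻⁸ feasibility slack) are clamped to
   zero before the square-root factorization; a numerically singular `S`
   falls back to a ridge-regularized inverse with a warning.
3. **Matching.** The rows of `X₃` are permuted to be as close to `U` as
   possible. For normal `X₃` the realized correlation `cor(ΠX₃, Ẑ)`
   converges to `R`; for general designs it does not, which is why
   `estimate_realized_correlation()` exists — it repeats the draw-and-match
   step `n_mc` times and averages the realized correlations, estimating
   what the pipeline actually achieves for *your* design.

Crucially, `Ẑ` influences the simulated data only through the chosen
permutation. The thinned counts for a fixed permutation are identical
whether the permutation came from the surrogate machinery or was supplied
directly (this is asserted in the test suite).

## The synthetic generator: what it does and does not emulate

`simulate_base_counts()` produces `Θ = μ1ᵀ + AZᵀ + Ω` with `Ω` either
i.i.d. normal on the log2 scale (`omega_sd`) or any user-supplied matrix —
the unstructured term is deliberately pluggable because real unwanted
variation has no canonical distribution, and the whole motivation for
thinning real data is that `Ω` need not be specified. Families:

* `poisson`: counts with mean `2^Θ`.
* `nb`: negative binomial with per-gene size `r` and variance `μ + μ²/r`;
  the size parameter is exactly invariant under thinning.
* `zinb`: a negative binomial masked by structural Bernoulli zeros. The NB
  mean is scaled by `1/(1 − zero_inflation)` so that the *marginal* mean of
  every cell is `2^Θ` in all three families — this keeps the generator's
  ground-truth `Θ` meaningful for recovery tests across families.

What a green test on synthetic data establishes: the thinning arithmetic,
the family invariances, the permutation machinery, and parameter recovery
under the stated model. What it does not establish: realism of the base
data. The generator has no GC-content or length bias, no gene–gene
correlation beyond the planted factor block, no library-size trend unless
injected, and log-normal-ish overdispersion only through `Ω`. For realistic
benchmarks, feed the tools a real count matrix; the synthetic generator
exists so that the machinery is testable without one. `Θ` entries are
capped at 30 (≈10⁹ expected counts) with a warning to avoid integer
overflow in the count draws.

## Numerical and reproducibility choices

* All exponents are base 2 throughout; coefficients are log2-fold changes.
* The binomial draws consume the RNG in column-major order over the count
  matrix, so `thin_all`, `thin_lib`, `thin_gene`, and `binomial_thin`
  produce bit-identical output whenever their `Q` matrices coincide and the
  seed matches.
* Master seeds are split into stage sub-seeds (permutation/latent draw,
  thinning, coefficient draw) by drawing integers with `sample.int()` under
  the master seed. Consequently the thinned counts for a given permutation
  do not depend on *how* the permutation was chosen, and `seed = NULL`
  falls through to the ambient RNG stream for interactive use.
* `q = −Inf` (probability exactly 0) is rejected rather than honoured: the
  construction keeps probabilities in (0, 1], and callers who want an
  effectively dead cell can pass a large negative value such as −30.
* Variance is `n − 1` throughout (PVE numerator and denominator, effect
  scaling `s_g`); the "empirical variance" in the PVE definition is
  ambiguous between `n` and `n − 1`, and the ratio is nearly unaffected,
  but fixing one convention makes the oracle tests exact.
* PVE of a null gene is 0 by convention; a non-null gene with a constant
  thinned row reports `NA` rather than raising, and `median_pve()` skips
  `NA`s.

## Known limitations

* Signals are linear on the log2 scale. Non-linear effects (e.g. GC bias)
  are supported only through the custom-`Q` escape hatch of `thin_diff()`,
  which accepts any non-positive `G × N` matrix.
* Thinning can only *remove* counts: injectable signals are bounded by the
  depth of the source data, and strong signals on low-count genes mostly
  produce zeros.
* The realized design/factor correlation is approximate for non-normal
  designs (binary designs in particular saturate well below |r| = 1); use
  the Monte-Carlo estimator to calibrate rather than trusting the target.
* The surrogate estimator is a plain truncated SVD; if the latent structure
  is weak relative to noise, the targeted correlation refers to the
  *estimated* factors, not the true ones.
* No DE testing, normalization, plotting, or factor-analysis evaluation is
  included; the package generates benchmark data and stops there.
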