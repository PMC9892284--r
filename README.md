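# lnbart

Bayesian additive regression trees (BART) with a choice of priors on the
split-probability simplex, for high-dimensional, weak-signal prediction
problems such as predicting gene expression from the SNPs in a gene's
cis-region.

In BART, `f(x) ≈ Σ_h g(x; T_h, M_h)` is a sum of H shallow regression
trees, and each interior node picks its splitting predictor j with
probability `s_j`.  Standard BART fixes `s_j = 1/p`, which cannot adapt
when only a few of hundreds of SNPs matter.  This package implements three
priors on `s`:

* **uniform** — standard BART (`s_j = 1/p`);
* **dirichlet** — the DART sparsity prior `s ~ Dir(θ/p, …, θ/p)` with the
  beta-prime-type hyperprior `θ/(θ+ρ) ~ Beta(a, b)`, updated by conjugate
  Gibbs;
* **logitnormal** — `s_j = exp(ψ_j) / Σ exp(ψ_j′)` with `ψ_j ~ N(m_j0, τ²)`
  (reference element pinned at 0).  Predictor-level functional annotations
  `a_j` (e.g. TSS distance, exon and repressor flags) enter through
  `m_j0 = ã_j′β`, so the prior importance of each SNP is informed by its
  annotation profile.  The posterior is sampled with exact Pólya-gamma
  Gibbs updates: `ω_j ~ PG(R, ψ_j − φ_j)` makes the conditional of `ψ_j`
  Gaussian, where `c_j` counts the ensemble's splits on predictor j and
  `R = Σ c_j`.

The package also provides the matching simulation engine (correlated
Hardy–Weinberg genotypes via a Gaussian copula, inverse-Wishart LD
structure, annotation-driven importance vectors, noise calibrated so the
true signal explains half the outcome variance), PSIS-LOO model comparison
(ELPD with generalized-Pareto smoothing, k̂ diagnostics at the strict 0.5
threshold and exact-refit fallback), a conjugate null model, and a
benchmark harness for out-of-sample R².

## Worked example

```r
library(lnbart)

# one simulated dataset: 100 SNPs, extremely sparse importance (tau2 = 10),
# informative annotations, weakly correlated SNPs
sc <- simulation_scenario(p = 100, tau2 = 10, informative = TRUE,
                          correlation = "weak", seed = 3)
ds <- simulate_dataset(sc, mc_draws = 2e4)

fit <- lnbart(ds$X_train, ds$y_train, x_test = ds$X_test,
              prior = "logitnormal", annotations = ds$A,
              n_iter = 2000, burn = 1000, thin = 5, seed = 11)
fit
#> BART fit (logitnormal split prior): n = 500, p = 100, trees = 200
#> 200 retained draws; posterior mean sigma^2 = 0.1132

r_squared(ds$y_test, colMeans(fit$yhat_test))   # out-of-sample R2, %
#> [1] 46.11736
r_squared(ds$y_test, ds$f_test)                 # oracle ceiling, ~50 by design
#> [1] 48.03518
```

The logit-normal-with-annotations fit reaches 46.1% test-set R² against an
oracle ceiling of 48% on this replicate; a uniform-prior BART fit of the
same data (`prior = "uniform"`) reaches 40.9%, the gap being the value of
sparsity adaptation plus the annotations.  `colMeans(fit$s)` shows where
the posterior split mass concentrated, and `fit$beta` holds the annotation
coefficient draws.

Model comparison against the intercept-only null:

```r
null <- fit_null_model(ds$y_train, n_draws = 200, seed = 1)
elpd_compare(loo_elpd(fit$loglik), loo_elpd(null$loglik))$diff
#> [1] 164.7996
```

A positive difference of hundreds of ELPD units says the SNPs are strongly
predictive of this (synthetic) expression outcome.

A thin command-line front end over these functions ships in
`inst/cli/lnbart.R` with `fit`, `simulate`, `compare` and `benchmark`
subcommands operating on delimited text files.

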