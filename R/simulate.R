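#' Describe one simulation scenario
#'
#' A scenario fixes every knob of the synthetic SNP-to-expression design:
#' the number of SNPs `p`, the sparsity scale `tau2` of the logit-normal
#' variable-importance vector (1 = antisparse, 5 = moderately sparse,
#' 10 = extremely sparse), whether the annotations carry signal
#' (`informative`: coefficient pattern +5/-5/0 by tens over `T = 30`
#' annotations, versus all zero), the SNP correlation strength
#' (`"strong"` = inverse-Wishart(p, I) correlation, `"weak"` =
#' inverse-Wishart(10p, I)), and the train/test sizes (500 / 1000).
#' Together with `seed` it fully determines a dataset.
#'
#' @param p number of SNPs (the benchmark design uses 100, 250 or 529).
#' @param tau2 logit-normal scale, one of 1, 5, 10 in the benchmark design.
#' @param informative logical; annotation effects present?
#' @param correlation `"weak"` or `"strong"`.
#' @param n_train,n_test sample sizes.
#' @param n_annotations number of annotation columns T.
#' @param seed integer seed that makes the dataset reproducible.
#' @param mafs optional vector of minor allele frequencies in (0, 0.5]; by
#'   default they are drawn per dataset from a mixture of common (80%,
#'   Uniform(0.05, 0.5)) and rare (20%, Uniform(0.01, 0.05)) variants.
#' @return an object of class `lnbart_scenario`.
#' @export
simulation_scenario <- function(p, tau2, informative = FALSE,
                                correlation = c("weak", "strong"),
                                n_train = 500L, n_test = 1000L,
                                n_annotations = 30L, seed = NULL,
                                mafs = NULL) {
  correlation <- match.arg(correlation)
  if (p < 2) stop("'p' must be at least 2")
  if (tau2 <= 0) stop("'tau2' must be positive")
  structure(list(p = as.integer(p), tau2 = tau2,
                 informative = isTRUE(informative), correlation = correlation,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 n_annotations = as.integer(n_annotations), seed = seed,
                 mafs = mafs),
            class = "lnbart_scenario")
}

#' Draw a SNP correlation matrix
#'
#' A draw from the inverse-Wishart distribution with identity scale and
#' degrees of freedom `p` (strong correlation) or `10 p` (weak), rescaled to
#' unit diagonal.
#'
#' @param p dimension.
#' @param strength `"strong"` or `"weak"`.
#' @return a p x p positive-definite correlation matrix.
#' @export
simulate_correlation <- function(p, strength = c("weak", "strong")) {
  strength <- match.arg(strength)
  df <- if (strength == "strong") p else 10L * p
  W <- stats::rWishart(1L, df = df, Sigma = diag(p))[, , 1L]
  stats::cov2cor(chol2inv(chol(W)))
}

# MAF mixture: 80% common Uniform(0.05, 0.5), 20% rare Uniform(0.01, 0.05)
simulate_mafs <- function(p) {
  rare <- stats::runif(p) < 0.2
  ifelse(rare, stats::runif(p, 0.01, 0.05), stats::runif(p, 0.05, 0.5))
}

#' Simulate correlated Hardy-Weinberg genotypes
#'
#' Gaussian-copula draw: latent `Z ~ N(0, corr)` thresholded per column at
#' the Hardy-Weinberg genotype cumulative probabilities
#' `((1-m)^2, 2m(1-m), m^2)` for minor allele frequency `m`, so each column's
#' marginal genotype frequencies match its MAF while the latent correlation
#' carries the linkage-disequilibrium structure.
#'
#' @param n number of individuals.
#' @param p number of SNPs.
#' @param mafs vector of minor allele frequencies in (0, 0.5].
#' @param corr p x p correlation matrix (identity for independent SNPs).
#' @return an n x p integer-valued matrix with entries in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(n, p, mafs, corr = diag(p)) {
  if (length(mafs) == 1L) mafs <- rep(mafs, p)
  if (any(mafs <= 0 | mafs > 0.5)) stop("MAFs must lie in (0, 0.5]")
  U <- chol(corr)
  genotypes_from_chol(n, mafs, U)
}

# worker shared with simulate_dataset so the Cholesky factor is reused
genotypes_from_chol <- function(n, mafs, U) {
  p <- length(mafs)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% U
  q0 <- qnorm((1 - mafs)^2)                      # below: genotype 0
  q1 <- qnorm((1 - mafs)^2 + 2 * mafs * (1 - mafs))  # below: genotype <= 1
  X <- matrix(0L, n, p)
  for (j in seq_len(p))
    X[, j] <- (Z[, j] > q0[j]) + (Z[, j] > q1[j])
  X
}

#' Draw annotations, annotation effects and the importance vector psi
#'
#' Annotations are 15 standardized continuous N(0,1) columns followed by 15
#' Bernoulli(0.2) indicator columns (mimicking a mix of continuous distance
#' measures and binary regulatory flags).  In the informative setting the
#' coefficients are +5 for the first ten annotations, -5 for the next ten
#' and 0 for the last ten; otherwise all zero.  The importance vector is
#' generated from the identified annotation model
#' `psi_j = (a_j - a_ref)' beta + eta_j`, `eta_j ~ N(0, tau2)`, with the
#' reference element (the last SNP) pinned at 0, and mapped to the simplex
#' `s = softmax(psi)`.
#'
#' @param scenario an `lnbart_scenario`.
#' @return list with `A` (p x T), `beta_true`, `psi_true`, `s_true`.
#' @export
simulate_annotations_and_psi <- function(scenario) {
  p <- scenario$p
  Tn <- scenario$n_annotations
  ncont <- floor(Tn / 2)
  A <- cbind(matrix(stats::rnorm(p * ncont), p, ncont),
             matrix(stats::rbinom(p * (Tn - ncont), 1L, 0.2), p, Tn - ncont))
  colnames(A) <- paste0("annot", seq_len(Tn))
  beta_true <- numeric(Tn)
  if (scenario$informative) {
    third <- floor(Tn / 3)
    beta_true[seq_len(third)] <- 5
    beta_true[third + seq_len(third)] <- -5
  }
  A_centered <- sweep(A, 2, A[p, ])
  psi <- drop(A_centered %*% beta_true) +
    stats::rnorm(p, 0, sqrt(scenario$tau2))
  psi[p] <- 0
  list(A = A, beta_true = beta_true, psi_true = psi,
       s_true = logit_to_simplex(psi))
}

# the ten recycled nonlinear signal pieces, as functions of one genotype
signal_pieces <- function() {
  list(
    function(x) sin(pi * (x - 1)),
    function(x) -x^2,
    function(x) exp(x),
    function(x) as.numeric(x <= 1),
    function(x) as.numeric(x >= 1),
    function(x) x^2 - x,
    function(x) -log(x + 1),
    function(x) cos(pi * (x - 1)),
    function(x) -x * (x^2 - 1),
    function(x) as.numeric(x != 0) * sin(pi * (x - 1)) -
      as.numeric(x == 0) * sin(pi * (x - 1))
  )
}

#' Evaluate the true regression function of the simulation design
#'
#' `f(x_i) = 0.5 * sum_j s_j f~_j(x_ij) + 4.5`, where the ten nonlinear
#' pieces `f~_1 ... f~_10` are recycled over the SNPs with period 10
#' (`f~_11 = f~_1`, etc.).  The simplex `s` acts as the variable-importance
#' weighting of the additive pieces.
#'
#' @param X genotype matrix with entries in \{0, 1, 2\}.
#' @param s_true importance simplex of length `ncol(X)`.
#' @return numeric vector of `f` values, one per row of `X`.
#' @export
true_function <- function(X, s_true) {
  X <- as.matrix(X)
  if (!all(X %in% c(0, 1, 2))) stop("genotypes must be coded 0/1/2")
  p <- ncol(X)
  if (length(s_true) != p) stop("'s_true' must have one weight per column")
  pieces <- signal_pieces()
  # each piece only ever sees x in {0,1,2}: tabulate the three values
  tab <- vapply(pieces, function(f) f(c(0, 1, 2)), numeric(3))
  piece_of <- ((seq_len(p) - 1L) %% 10L) + 1L
  f <- numeric(nrow(X))
  for (j in seq_len(p))
    f <- f + s_true[j] * tab[X[, j] + 1L, piece_of[j]]
  0.5 * f + 4.5
}

#' Calibrate the noise variance to a 50% signal fraction
#'
#' Sets the noise variance equal to the Monte-Carlo variance of the true
#' function, so that `Var(f) / (Var(f) + sigma2) = 0.5`: the true signal
#' explains half of the outcome variability by construction.
#'
#' @param f_values_mc a large Monte-Carlo sample of `f` values.
#' @return the calibrated noise variance.
#' @export
calibrate_noise <- function(f_values_mc) {
  if (length(f_values_mc) < 2) stop("need at least two Monte-Carlo values")
  v <- stats::var(f_values_mc)
  if (!is.finite(v) || v <= 0) stop("degenerate signal: zero variance")
  v
}

#' Simulate one full dataset from a scenario
#'
#' Composes the generation steps: correlation draw, MAF draw, annotation /
#' psi / s draw, correlated genotypes for train, test and a Monte-Carlo
#' calibration sample, evaluation of the true function, noise calibration
#' and outcome generation `y = f(x) + eps`, `eps ~ N(0, sigma2_true)`.
#'
#' @param scenario an `lnbart_scenario`.
#' @param mc_draws Monte-Carlo sample size for the noise calibration.
#' @return an object of class `lnbart_dataset`: a list with `X_train`,
#'   `y_train`, `X_test`, `y_test`, `f_train`, `f_test`, `A`, `psi_true`,
#'   `s_true`, `beta_true`, `sigma2_true`, `mafs` and the scenario.
#' @export
simulate_dataset <- function(scenario, mc_draws = 1e5) {
  if (!inherits(scenario, "lnbart_scenario"))
    stop("'scenario' must come from simulation_scenario()")
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  p <- scenario$p
  corr <- simulate_correlation(p, scenario$correlation)
  U <- chol(corr)
  mafs <- if (is.null(scenario$mafs)) simulate_mafs(p) else scenario$mafs
  ann <- simulate_annotations_and_psi(scenario)

  n_all <- scenario$n_train + scenario$n_test
  X_all <- genotypes_from_chol(n_all, mafs, U)
  f_all <- true_function(X_all, ann$s_true)

  # Monte-Carlo noise calibration, chunked to bound memory
  remaining <- mc_draws
  f_mc <- numeric(0)
  while (remaining > 0) {
    m <- min(remaining, 2e4)
    f_mc <- c(f_mc, true_function(genotypes_from_chol(m, mafs, U), ann$s_true))
    remaining <- remaining - m
  }
  sigma2_true <- calibrate_noise(f_mc)

  y_all <- f_all + stats::rnorm(n_all, 0, sqrt(sigma2_true))
  tr <- seq_len(scenario$n_train)
  structure(list(X_train = X_all[tr, , drop = FALSE],
                 y_train = y_all[tr],
                 X_test = X_all[-tr, , drop = FALSE],
                 y_test = y_all[-tr],
                 f_train = f_all[tr], f_test = f_all[-tr],
                 A = ann$A, psi_true = ann$psi_true, s_true = ann$s_true,
                 beta_true = ann$beta_true, sigma2_true = sigma2_true,
                 mafs = mafs, scenario = scenario),
            class = "lnbart_dataset")
}
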