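test_that("logit_to_simplex is the overflow-safe softmax", {
  expect_equal(logit_to_simplex(rep(0, 4)), rep(0.25, 4))
  expect_equal(logit_to_simplex(c(0.5, 0))[1], exp(0.5) / (1 + exp(0.5)))
  s <- logit_to_simplex(c(1000, 0, -5))
  expect_equal(sum(s), 1)
  expect_equal(s[1], 1, tolerance = 1e-10)
  s2 <- logit_to_simplex(rnorm(20) * 50)
  expect_true(all(s2 > 0))
  expect_equal(sum(s2), 1)
})

test_that("count_splits tallies interior nodes exactly", {
  ens <- figure_toy_ensemble()
  cs <- count_splits(ens, 2)
  expect_identical(cs$counts, c(3L, 2L))
  expect_identical(cs$R, 5L)
  # stump-only ensemble
  stump <- as_ensemble(list(toy_tree(nd_leaf(1, NA, 0.5, 0))), 0)
  expect_identical(count_splits(stump, 3)$counts, c(0L, 0L, 0L))
  expect_identical(count_splits(stump, 3)$R, 0L)
})

test_that("count_splits agrees with a brute-force tree walk on a fitted ensemble", {
  set.seed(51)
  n <- 80
  x <- matrix(runif(n * 5), n, 5)
  y <- x[, 2] * 3 + sin(4 * x[, 4]) + rnorm(n, 0, 0.3)
  f <- do.call(lnbart, c(list(x = x, y = y, prior = "uniform", seed = 3), quick_mcmc))
  got <- count_splits(f$ensemble, 5)
  oracle <- count_splits_walk(f$ensemble, 5)
  expect_identical(got$counts, oracle$counts)
  expect_identical(got$R, oracle$R)
})

test_that("dirichlet update matches the conjugate closed form", {
  counts <- c(4L, 0L, 7L)
  expect_equal(dirichlet_posterior(counts, theta = 1.5),
               1.5 / 3 + counts)
  set.seed(52)
  # moment identity: posterior mean of s_j is (theta/p + c_j) / (theta + R)
  draws <- t(replicate(3e4, dirichlet_update(counts, theta = 1.5)))
  expect_equal(colMeans(draws), (1.5 / 3 + counts) / (1.5 + sum(counts)),
               tolerance = 0.01)
  expect_true(all(abs(rowSums(draws) - 1) < 1e-12))
  # c = 0 draws come from the prior
  prior_draws <- t(replicate(2e4, dirichlet_update(c(0L, 0L), theta = 2)))
  expect_equal(colMeans(prior_draws), c(0.5, 0.5), tolerance = 0.01)
  # theta -> 0 with concentrated counts collapses onto the first coordinate
  conc <- replicate(200, dirichlet_update(c(10L, 0L, 0L), theta = 1e-8)[1])
  expect_true(all(conc > 0.999))
})

test_that("theta grid draw matches a fine-grid numeric posterior", {
  set.seed(53)
  s <- c(0.7, 0.2, 0.1)
  a <- 0.5; b <- 1; rho <- 3
  draws <- replicate(4000, theta_update(s, a = a, b = b, rho = rho))
  # independent quadrature oracle on a fine uniform grid of u = theta/(theta+rho)
  u <- seq(1e-6, 1 - 1e-6, length.out = 2e5)
  th <- rho * u / (1 - u)
  p <- length(s)
  lpost <- dbeta(u, a, b, log = TRUE) +
    lgamma(th) - p * lgamma(th / p) + (th / p - 1) * sum(log(s))
  w <- exp(lpost - max(lpost)); w <- w / sum(w)
  q_oracle <- function(pr) th[which.min(abs(cumsum(w) - pr))]
  expect_equal(unname(quantile(draws, 0.5)), q_oracle(0.5), tolerance = 0.08)
  expect_equal(unname(quantile(draws, 0.25)), q_oracle(0.25), tolerance = 0.08)
  expect_equal(unname(quantile(draws, 0.75)), q_oracle(0.75), tolerance = 0.08)
  expect_equal(mean(log(draws)), sum(w * log(th)), tolerance = 0.05)
})

test_that("near-uniform s pushes theta up relative to its prior", {
  set.seed(54)
  p <- 50
  s <- logit_to_simplex(rnorm(p, 0, 0.01))
  post <- replicate(500, theta_update(s, rho = p))
  # prior draws: u ~ Beta(0.5, 1), theta = rho u/(1-u)
  u <- rbeta(5000, 0.5, 1)
  prior <- p * u / (1 - u)
  expect_gt(median(post), median(prior))
})

test_that("pg_conditional_omega has the Polya-gamma conditional mean", {
  set.seed(55)
  counts <- c(6L, 4L, 2L)   # R = 12
  psi <- c(0.8, -0.3, 0)
  z <- psi[1] - log_sum_exp(psi[-1])
  draws <- replicate(2e4, pg_conditional_omega(1, counts, psi))
  expect_lt(abs(mean(draws) - pg_moment_mean(12, z)),
            4 * sqrt(pg_moment_var(12, z) / 2e4) + 0.002)
  # R = 0 is degenerate at zero
  expect_identical(pg_conditional_omega(1, c(0L, 0L), psi = c(0, 0)), 0)
})

test_that("psi conditional moments reproduce the Gaussian update formulas", {
  # symmetric case: kappa = 0, omega = 1, tau2 = 1, phi = 0 -> N(0, 1/2)
  mo <- psi_conditional_moments(1, counts = c(2L, 2L), psi = c(0.7, 0),
                                omega_j = 1, m0_j = 0, tau2 = 1)
  expect_equal(mo$mean, 0)
  expect_equal(mo$var, 0.5)
  # plug-in case: tau2 = 2, omega = 0.5, kappa = 3, phi = 1 -> mean 3.5, var 1
  mo2 <- psi_conditional_moments(1, counts = c(8L, 2L), psi = c(-1, 1),
                                 omega_j = 0.5, m0_j = 0, tau2 = 2)
  expect_equal(mo2$var, 1)
  expect_equal(mo2$mean, 3.5)
  # omega -> 0 limit: N(m0 + tau2 kappa, tau2)
  mo3 <- psi_conditional_moments(1, counts = c(8L, 2L), psi = c(-1, 1),
                                 omega_j = 0, m0_j = 0.3, tau2 = 2)
  expect_equal(mo3$mean, 0.3 + 2 * 3)
  expect_equal(mo3$var, 2)
  set.seed(56)
  draws <- replicate(1e4, psi_conditional(1, c(8L, 2L), c(-1, 1), 0.5, 0, 2))
  expect_equal(mean(draws), 3.5, tolerance = 0.05)
  expect_equal(var(draws), 1, tolerance = 0.05)
})

test_that("annotation design centers at the reference and drops flat columns", {
  set.seed(57)
  A <- cbind(rnorm(6), rep(2, 6), rbinom(6, 1, 0.5))
  des <- annotation_design(A)
  expect_identical(des$kept_cols, c(1L, 3L))        # constant column removed
  expect_equal(unname(des$A_tilde[6, ]), c(0, 0))   # reference row is zero
  expect_identical(nrow(des$A_tilde_nr), 5L)
  expect_equal(des$A_tilde[2, 1], A[2, 1] - A[6, 1])
})

test_that("beta update matches conjugate closed forms", {
  # zero design carries no information: posterior equals the prior
  Az <- matrix(0, 4, 2)
  mo <- beta_posterior(rnorm(4), Az, tau2 = 1, v_beta0 = 7)
  expect_equal(mo$mean, c(0, 0))
  expect_equal(mo$cov, diag(7, 2))
  # one-annotation least-squares limit
  A1 <- matrix(c(1, -1), 2, 1)
  mo2 <- beta_posterior(c(2, -2), A1, tau2 = 1, v_beta0 = 1e10)
  expect_equal(mo2$mean, 2, tolerance = 1e-6)
  # degenerate prior shrinks the draw to zero
  set.seed(58)
  d <- replicate(200, beta_update(c(2, -2), A1, tau2 = 1, v_beta0 = 1e-10))
  expect_lt(max(abs(d)), 1e-3)
})

test_that("tau2 inverse-gamma branch is exactly conjugate", {
  par <- tau2_posterior_ig(rss = 6, m = 4, a0 = 1, b0 = 1)
  expect_equal(par$shape, 3)
  expect_equal(par$rate, 4)
  set.seed(59)
  psi <- rnorm(4); psi <- psi * sqrt(6 / sum(psi^2))   # force RSS = 6
  prior <- list(type = "ig", a0 = 1, b0 = 1)
  draws <- replicate(3e4, tau2_update(psi, 0, prior)$tau2)
  expect_equal(mean(draws), 4 / (3 - 1), tolerance = 0.05)  # IG mean b/(a-1)
  # m = 0: prior draw
  set.seed(60)
  d0 <- replicate(3e4, tau2_update(numeric(0), 0, list(type = "ig", a0 = 3, b0 = 2))$tau2)
  expect_equal(mean(d0), 2 / (3 - 1), tolerance = 0.05)
})

test_that("half-t tau2 chain targets the quadrature posterior", {
  set.seed(61)
  m <- 6; rss <- 3.2
  psi <- rnorm(m); psi <- psi * sqrt(rss / sum(psi^2))
  prior <- list(type = "half-t", scale = 1, df = 3)
  niter <- 3e4
  draws <- numeric(niter)
  st <- list(tau2 = 1, aux = NULL)
  for (it in seq_len(niter)) {
    st <- tau2_update(psi, 0, prior, st$aux)
    draws[it] <- st$tau2
  }
  # quadrature of prior x likelihood in tau2
  lg <- seq(log(1e-5), log(100), length.out = 6000)
  t2 <- exp(lg)
  tau <- sqrt(t2)
  # half-t(df, scale) density on tau, transformed to tau2 (+ log-grid jacobian)
  lp <- stats::dt(tau / prior$scale, df = prior$df, log = TRUE) -
    log(prior$scale) - log(2 * tau) - (m / 2) * log(t2) - rss / (2 * t2) + lg
  w <- exp(lp - max(lp)); w <- w / sum(w)
  cdf <- cumsum(w)
  expect_lt(ks_against_grid(draws, t2, cdf), 0.02)
})

test_that("a full sweep preserves the simplex and is reproducible", {
  counts <- c(5L, 1L, 0L, 8L)
  run <- function() {
    set.seed(62)
    st <- ln_state(4)
    for (i in 1:50) st <- sweep_update(st, counts)
    st
  }
  s1 <- run(); s2 <- run()
  expect_identical(s1$psi, s2$psi)
  expect_equal(sum(s1$s), 1)
  expect_true(all(s1$s > 0))
  expect_identical(s1$psi[4], 0)          # reference stays pinned
  expect_identical(s1$m0, rep(0, 4))      # no annotations: m0 stays zero
})

test_that("annotation sweep learns beta and recomputes the prior means", {
  set.seed(63)
  p <- 40; Tn <- 3
  A <- matrix(rnorm(p * Tn), p, Tn)
  st <- ln_state(p, annotations = A, tau2 = 1)
  counts <- rep(2L, p)
  st <- sweep_update(st, counts)
  expect_length(st$beta, Tn)
  expect_equal(st$m0[-p], drop(st$annotations$A_tilde_nr %*% st$beta))
  expect_identical(st$m0[p], 0)
  expect_gt(st$tau2, 0)
})

test_that("non-identity psi correlation structures are rejected as unimplemented", {
  Sig <- diag(3); Sig[1, 2] <- Sig[2, 1] <- 0.5
  expect_error(ln_state(3, Sigma_psi0 = Sig), "not implemented")
  expect_silent(ln_state(3, Sigma_psi0 = diag(3)))
})

test_that("sparse truth concentrates the posterior split mass on active predictors", {
  set.seed(64)
  sc <- simulation_scenario(p = 60, tau2 = 10, informative = FALSE,
                            correlation = "weak", n_train = 250, n_test = 50,
                            seed = 8)
  ds <- simulate_dataset(sc, mc_draws = 5e3)
  f <- do.call(lnbart, c(list(x = ds$X_train, y = ds$y_train,
                              prior = "logitnormal", seed = 19), quick_mcmc))
  active <- order(ds$s_true, decreasing = TRUE)[1:2]
  s_post <- colMeans(f$s)
  # enrichment over the uniform prior's 1/p on the truly active predictors
  expect_gt(mean(s_post[active]), 1 / ncol(ds$X_train))
})
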