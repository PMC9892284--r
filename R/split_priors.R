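#' Map a logit-normal vector to the split-probability simplex
#'
#' Overflow-safe softmax: `s_j = exp(psi_j) / sum_j' exp(psi_j')`.  In the
#' logit-normal prior one reference element of `psi` (by convention the last)
#' is pinned at 0 for identifiability, so this is
#' `exp(psi_j) / (1 + sum_{j' != ref} exp(psi_j'))`.
#'
#' @param psi numeric vector; the reference element should be 0.
#' @return a simplex vector of the same length (positive, sums to one).
#' @examples
#' logit_to_simplex(c(0, 0, 0, 0))
#' @export
logit_to_simplex <- function(psi) {
  e <- exp(psi - max(psi))
  e / sum(e)
}

#' Tally splitting-rule predictor counts over an ensemble
#'
#' Counts, over every interior node of every tree, how often each predictor
#' appears in a splitting rule: `c_j = sum_r I(v_r = j)`, with `R = sum_j c_j`
#' the total number of interior nodes.  These counts are the "data" through
#' which the Dirichlet and logit-normal priors learn about the
#' split-probability simplex.
#'
#' @param ensemble an `lnbart_ensemble` (see [as_ensemble()]), or the
#'   `$ensemble` element of a fitted model.
#' @param p number of predictors.
#' @return list with integer vector `counts` (length `p`) and total `R`.
#' @export
count_splits <- function(ensemble, p) {
  vars <- unlist(lapply(ensemble$trees, function(tr) tr$var[!is.na(tr$var)]),
                 use.names = FALSE)
  counts <- tabulate(vars, nbins = p)
  list(counts = as.integer(counts), R = length(vars))
}

#' Conjugate Dirichlet update of the split probabilities (DART)
#'
#' Under the prior `s ~ Dir(theta/p, ..., theta/p)` and multinomial split
#' counts `c`, the conditional is `s | c ~ Dir(theta/p + c_1, ..., theta/p + c_p)`.
#' `dirichlet_update()` returns one draw; `dirichlet_posterior()` returns the
#' exact parameter vector of that conditional.
#'
#' @param counts integer vector of per-predictor split counts.
#' @param theta Dirichlet concentration (global sparsity parameter).
#' @param p number of predictors (defaults to `length(counts)`).
#' @return `dirichlet_update()`: a simplex draw; `dirichlet_posterior()`: the
#'   Dirichlet parameter vector.
#' @export
dirichlet_update <- function(counts, theta, p = length(counts)) {
  shape <- dirichlet_posterior(counts, theta, p)
  # log-space gamma draws: for tiny shapes (theta -> 0 under sparsity) the
  # direct rgamma draw underflows to zero, so use
  # Gamma(a) = Gamma(a + 1) * U^(1/a) on the log scale
  logg <- log(stats::rgamma(p, shape = shape + 1, rate = 1)) +
    log(stats::runif(p)) / shape
  logs <- logg - log_sum_exp(logg)
  s <- exp(logs)
  s <- s / sum(s)
  attr(s, "log_s") <- logs
  s
}

#' @rdname dirichlet_update
#' @export
dirichlet_posterior <- function(counts, theta, p = length(counts)) {
  if (theta <= 0) stop("'theta' must be positive")
  theta / p + counts
}

#' Gibbs update of the Dirichlet sparsity parameter theta
#'
#' The DART prior places `theta / (theta + rho) ~ Beta(a, b)` (a beta-prime
#' prior scaled by `rho` on `theta`).  The conditional of `theta` given the
#' simplex `s` is sampled on a discrete grid of `grid_size` log-spaced values
#' of `theta` with exact evaluation of prior times Dirichlet likelihood
#' (log-spacing is accounted for with the appropriate Jacobian weight).
#'
#' @param s current split-probability simplex.
#' @param a,b Beta hyperparameters (defaults 0.5 and 1).
#' @param rho prior scale, usually the number of predictors.
#' @param grid_size number of grid points.
#' @return a positive draw of theta.
#' @export
theta_update <- function(s, a = 0.5, b = 1, rho = length(s),
                         grid_size = 1000L) {
  p <- length(s)
  theta <- rho * exp(seq(log(1e-4), log(1e4), length.out = grid_size))
  lw <- theta_log_conditional(theta, s, a, b, rho) + log(theta)
  w <- exp(lw - max(lw))
  theta[sample.int(grid_size, 1L, prob = w)]
}

# log density (up to a constant) of theta given s under the scaled
# beta-prime prior and Dir(theta/p) likelihood; uses the exact log
# coordinates of s when dirichlet_update() attached them
theta_log_conditional <- function(theta, s, a, b, rho) {
  p <- length(s)
  logs <- attr(s, "log_s")
  if (is.null(logs)) logs <- log(s)
  u <- theta / (theta + rho)
  lprior <- stats::dbeta(u, a, b, log = TRUE) + log(rho) - 2 * log(theta + rho)
  llik <- lgamma(theta) - p * lgamma(theta / p) + (theta / p - 1) * sum(logs)
  lprior + llik
}

#' Polya-gamma auxiliary draw for one predictor's logit-normal update
#'
#' Draws `omega_j ~ PG(R, psi_j - phi_j)` where
#' `phi_j = log sum_{j' != j} exp(psi_j')` (computed overflow-safely) and `R`
#' is the total interior-node count.  With `R = 0` the distribution is
#' degenerate at zero.
#'
#' @param j predictor index.
#' @param counts per-predictor split counts (only their sum `R` enters).
#' @param psi current logit-normal vector.
#' @param threshold passed to [pg_draw()].
#' @return a nonnegative draw of `omega_j`.
#' @export
pg_conditional_omega <- function(j, counts, psi, threshold = 170L) {
  R <- sum(counts)
  if (R == 0) return(0)
  phi <- log_sum_exp(psi[-j])
  pg_draw(R, psi[j] - phi, threshold = threshold)
}

#' Conditional normal update of one logit-normal element
#'
#' Given the auxiliary variate `omega_j`, the conditional of `psi_j` is
#' normal with variance `V_j = tau2 / (omega_j tau2 + 1)` and mean
#' `m_j = (m0_j + tau2 (kappa_j + omega_j phi_j)) / (omega_j tau2 + 1)`,
#' where `kappa_j = c_j - R/2`.  `psi_conditional_moments()` returns the
#' exact mean and variance; `psi_conditional()` returns a draw.
#'
#' @inheritParams pg_conditional_omega
#' @param omega_j Polya-gamma auxiliary value.
#' @param m0_j prior mean of `psi_j` (annotation-driven, or 0).
#' @param tau2 prior variance of `psi_j` around `m0_j`.
#' @return a draw (or a list with `mean` and `var`).
#' @export
psi_conditional <- function(j, counts, psi, omega_j, m0_j = 0, tau2 = 1) {
  mo <- psi_conditional_moments(j, counts, psi, omega_j, m0_j, tau2)
  stats::rnorm(1, mo$mean, sqrt(mo$var))
}

#' @rdname psi_conditional
#' @export
psi_conditional_moments <- function(j, counts, psi, omega_j, m0_j = 0, tau2 = 1) {
  R <- sum(counts)
  kappa <- counts[j] - R / 2
  phi <- log_sum_exp(psi[-j])
  den <- omega_j * tau2 + 1
  list(mean = (m0_j + tau2 * (kappa + omega_j * phi)) / den,
       var = tau2 / den)
}

#' Build a centered annotation design
#'
#' Annotations enter the logit-normal prior through
#' `psi_j = beta0 + a_j' beta + eta_j`; with the identifiability constraint
#' `psi_ref = 0` the model is estimated by centering every annotation row at
#' the reference row (`a~_j = a_j - a_ref`) and dropping the intercept.
#' Columns with zero variance across predictors carry no information and are
#' removed before centering.
#'
#' @param A numeric matrix, one row per predictor, one column per annotation.
#' @param reference reference predictor index (default: the last row).
#' @param v_beta0 prior variance of each annotation coefficient.
#' @return an object of class `lnbart_annotations` with the centered design
#'   `A_tilde` (reference row identically zero), the reference-dropped design
#'   `A_tilde_nr`, the kept column indices and `v_beta0`.
#' @export
annotation_design <- function(A, reference = nrow(A), v_beta0 = 100) {
  A <- as.matrix(A)
  if (!is.numeric(A)) stop("annotations must be numeric")
  p <- nrow(A)
  if (reference < 1 || reference > p) stop("invalid reference index")
  keep <- which(apply(A, 2, function(col) stats::var(col) > 0))
  A_kept <- A[, keep, drop = FALSE]
  A_tilde <- sweep(A_kept, 2, A_kept[reference, ])
  structure(list(A = A, A_tilde = A_tilde,
                 A_tilde_nr = A_tilde[-reference, , drop = FALSE],
                 reference = reference, kept_cols = keep,
                 v_beta0 = v_beta0),
            class = "lnbart_annotations")
}

#' Conjugate update of the annotation coefficients
#'
#' With prior `beta ~ N(0, v_beta0 I)` and `psi_j = a~_j' beta + eta_j`,
#' `eta_j ~ N(0, tau2)` over the non-reference predictors, the conditional is
#' `beta ~ N(m_beta, V_beta)` with
#' `V_beta = (A~'A~ / tau2 + I / v_beta0)^{-1}` and
#' `m_beta = V_beta A~' psi / tau2`.  `beta_posterior()` returns the exact
#' moments; `beta_update()` returns a draw.
#'
#' @param psi_minus_ref psi values for the non-reference predictors.
#' @param A_tilde_nr centered annotation matrix with the reference row
#'   dropped (rows aligned with `psi_minus_ref`).
#' @param tau2 annotation-model error variance.
#' @param v_beta0 prior variance of each coefficient.
#' @return a coefficient draw (or a list with `mean` and `cov`).
#' @export
beta_update <- function(psi_minus_ref, A_tilde_nr, tau2, v_beta0 = 100) {
  mo <- beta_posterior(psi_minus_ref, A_tilde_nr, tau2, v_beta0)
  U <- chol(mo$cov)
  drop(mo$mean + crossprod(U, stats::rnorm(length(mo$mean))))
}

#' @rdname beta_update
#' @export
beta_posterior <- function(psi_minus_ref, A_tilde_nr, tau2, v_beta0 = 100) {
  Tn <- ncol(A_tilde_nr)
  prec <- crossprod(A_tilde_nr) / tau2 + diag(1 / v_beta0, Tn)
  V <- chol2inv(chol(prec))
  m <- drop(V %*% (crossprod(A_tilde_nr, psi_minus_ref) / tau2))
  list(mean = m, cov = V)
}

#' Update of the logit-normal scale tau^2
#'
#' The conditional depends on the annotation-model residual sum of squares
#' `RSS = sum_j (psi_j - m0_j)^2` over the non-reference predictors.  Two
#' priors are supported: the conjugate inverse-gamma `IG(a0, b0)` on tau^2
#' (exact draw `IG(a0 + m/2, b0 + RSS/2)`), and the scaled half-t on tau,
#' sampled exactly by the standard parameter expansion
#' (`tau2 | aux ~ IG((df + m)/2, df/aux + RSS/2)`,
#' `aux | tau2 ~ IG((df + 1)/2, df/tau2 + 1/scale^2)`), whose marginal prior
#' on tau is half-t(df, scale).  With `m = 0` both reduce to prior draws.
#'
#' @param psi_minus_ref psi values for the non-reference predictors (possibly
#'   length zero).
#' @param m0_minus_ref prior means (annotation fit), scalar 0 or a vector.
#' @param prior a list: either `list(type = "ig", a0, b0)` or
#'   `list(type = "half-t", scale, df)`.
#' @param aux current parameter-expansion auxiliary (half-t prior only);
#'   `NULL` draws it from its prior.
#' @return list with the draw `tau2` and the updated `aux`.
#' @export
tau2_update <- function(psi_minus_ref, m0_minus_ref = 0,
                        prior = list(type = "half-t", scale = 1, df = 3),
                        aux = NULL) {
  m <- length(psi_minus_ref)
  rss <- sum((psi_minus_ref - m0_minus_ref)^2)
  if (identical(prior$type, "ig")) {
    par <- tau2_posterior_ig(rss, m, prior$a0, prior$b0)
    return(list(tau2 = rinvgamma(1, par$shape, par$rate), aux = NULL))
  }
  df <- prior$df
  A <- prior$scale
  if (is.null(aux)) aux <- rinvgamma(1, 0.5, 1 / A^2)
  tau2 <- rinvgamma(1, (df + m) / 2, df / aux + rss / 2)
  aux <- rinvgamma(1, (df + 1) / 2, df / tau2 + 1 / A^2)
  list(tau2 = tau2, aux = aux)
}

#' @rdname tau2_update
#' @param rss residual sum of squares.
#' @param m number of residuals.
#' @param a0,b0 inverse-gamma prior shape and rate.
#' @export
tau2_posterior_ig <- function(rss, m, a0, b0) {
  list(shape = a0 + m / 2, rate = b0 + rss / 2)
}

#' Create the logit-normal prior state
#'
#' Holds the current `psi` (reference element pinned at 0), its softmax `s`,
#' the scale `tau2`, the annotation design and coefficients (if any) and the
#' parameter-expansion auxiliary of the half-t update.  A user-specified
#' correlation structure for `psi` (`Sigma_psi0`) is stored as a
#' configuration field but sampling under a non-identity structure is not
#' implemented.
#'
#' @param p number of predictors.
#' @param annotations optional `lnbart_annotations` design (or a raw p x T
#'   matrix, which is passed to [annotation_design()]).
#' @param tau2 initial scale.
#' @param tau_prior prior for tau^2, see [tau2_update()].
#' @param reference reference predictor index; the last predictor by default.
#' @param Sigma_psi0 optional prior correlation for psi; only the identity
#'   (NULL) is supported.
#' @return an object of class `lnbart_ln_state`.
#' @export
ln_state <- function(p, annotations = NULL, tau2 = 1,
                     tau_prior = list(type = "half-t", scale = 1, df = 3),
                     reference = p, Sigma_psi0 = NULL) {
  if (!is.null(Sigma_psi0)) {
    if (!isTRUE(all.equal(Sigma_psi0, diag(p))))
      stop("correlated psi priors (non-identity Sigma_psi0) are not implemented")
  }
  if (!is.null(annotations) && !inherits(annotations, "lnbart_annotations"))
    annotations <- annotation_design(as.matrix(annotations), reference = reference)
  Tn <- if (is.null(annotations)) 0L else ncol(annotations$A_tilde_nr)
  psi <- numeric(p)
  structure(list(p = p, reference = reference, psi = psi,
                 s = rep(1 / p, p), tau2 = tau2, tau_prior = tau_prior,
                 annotations = annotations,
                 beta = if (Tn > 0) numeric(Tn) else NULL,
                 m0 = numeric(p), aux = NULL, Sigma_psi0 = Sigma_psi0),
            class = "lnbart_ln_state")
}

#' One full Gibbs sweep of the logit-normal split-prior state
#'
#' Performs, in order: for each non-reference predictor `j` (ascending), a
#' Polya-gamma draw of `omega_j` followed by the conditional normal draw of
#' `psi_j`; then, when an annotation design is present, the conjugate update
#' of `beta` and the recomputation of the prior means `m0 = A~ beta`; then
#' the `tau2` update; and finally the recomputation of `s` from `psi`.
#'
#' @param state an `lnbart_ln_state`.
#' @param counts per-predictor split counts freshly tallied from the
#'   ensemble.
#' @param pg_threshold exact-composition threshold for the Polya-gamma draws.
#' @param update_hyper set `FALSE` to freeze `beta` and `tau2` (used when
#'   studying the psi conditional in isolation).
#' @return the updated state.
#' @export
sweep_update <- function(state, counts, pg_threshold = 170L,
                         update_hyper = TRUE) {
  sw <- .ln_sweep_cpp(state$psi, as.integer(counts), state$reference,
                      state$m0, state$tau2, as.integer(pg_threshold))
  state$psi <- sw$psi
  state$omega <- sw$omega
  if (update_hyper) {
    ref <- state$reference
    if (!is.null(state$annotations)) {
      des <- state$annotations
      state$beta <- beta_update(state$psi[-ref], des$A_tilde_nr, state$tau2,
                                des$v_beta0)
      state$m0 <- numeric(state$p)
      state$m0[-ref] <- drop(des$A_tilde_nr %*% state$beta)
    }
    tu <- tau2_update(state$psi[-ref], state$m0[-ref], state$tau_prior,
                      state$aux)
    state$tau2 <- tu$tau2
    state$aux <- tu$aux
  }
  state$s <- logit_to_simplex(state$psi)
  state
}
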