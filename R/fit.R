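#' Build cutpoint grids for every predictor
#'
#' Continuous predictors get `n_cuts` equidistant interior cutpoints between
#' their observed minimum and maximum.  Additively coded genotypes (all
#' values in \{0, 1, 2\}) get the natural cutpoints 0.5 and 1.5; binary
#' predictors a single cutpoint.  A splitting rule sends `x <= cut` left.
#'
#' @param x predictor matrix.
#' @param n_cuts grid size for continuous predictors.
#' @return list of ascending numeric cutpoint vectors, one per column.
#' @export
make_cutpoints <- function(x, n_cuts = 100L) {
  lapply(seq_len(ncol(x)), function(j) {
    xj <- x[, j]
    ux <- unique(xj)
    if (all(ux %in% c(0, 1, 2))) {
      cuts <- c(0.5, 1.5)
      return(cuts[cuts >= min(xj) & cuts < max(xj)])
    }
    lo <- min(xj); hi <- max(xj)
    if (lo == hi) return(numeric(0))
    grid <- seq(lo, hi, length.out = n_cuts + 2L)
    grid[-c(1L, n_cuts + 2L)]
  })
}

#' Fit a BART model with a choice of split-probability prior
#'
#' Runs the Bayesian-backfitting MCMC for a sum of `n_trees` regression
#' trees: per iteration, each tree is updated by a GROW/PRUNE/CHANGE
#' Metropolis-Hastings step (probabilities 0.25/0.25/0.5) with terminal
#' values integrated out, followed by a conjugate Gibbs draw of its terminal
#' values, the noise variance, and the split-probability simplex under the
#' chosen prior:
#'
#' * `"uniform"` - standard BART, `s_j = 1/p` throughout;
#' * `"dirichlet"` - DART, conjugate Dirichlet update of `s` plus a
#'   grid Gibbs update of the concentration `theta`;
#' * `"logitnormal"` - `s = softmax(psi)` with Polya-gamma Gibbs updates of
#'   `psi` and, when `annotations` is supplied, a hierarchical regression of
#'   `psi` on the annotations (coefficients `beta`, scale `tau2`).
#'
#' The outcome is centered at its mean before fitting; the terminal-value
#' prior is `N(0, leaf_sd^2)` with `leaf_sd = range(y) / (2 k sqrt(H))`.
#' With the default settings (10000 iterations, half burn-in, thinning 5)
#' exactly 1000 posterior draws are retained.
#'
#' @param x numeric predictor matrix (n x p); genotypes may be coded 0/1/2.
#' @param y numeric outcome vector.
#' @param x_test optional matrix at which posterior draws of `f` are kept.
#' @param prior split-probability prior, see above.
#' @param annotations optional p x T annotation matrix (logit-normal prior
#'   only); rows aligned with the columns of `x`.
#' @param n_trees ensemble size H.
#' @param n_iter,burn,thin MCMC length, burn-in and thinning; draws kept are
#'   `burn + thin, burn + 2 thin, ...`.
#' @param alpha,lambda,depth_form depth-prior settings, see
#'   [depth_split_prob()].
#' @param k terminal-value prior calibration constant.
#' @param nu,sigma_quantile noise-prior settings, see
#'   [calibrate_noise_prior()].
#' @param n_cuts cutpoint grid size for continuous predictors.
#' @param dart list of DART hyperparameters `a`, `b`, `rho` (`rho = NULL`
#'   means `p`).
#' @param ln list of logit-normal settings: `v_beta0`, `tau_prior` (see
#'   [tau2_update()]), `tau2_init`, `reference` (`NULL` means `p`),
#'   `Sigma_psi0` (must be `NULL` or the identity).
#' @param pg_threshold exact-composition threshold for Polya-gamma draws
#'   inside the sweep; beyond it a moment-matched gamma is used (the total
#'   interior-node count of an ensemble routinely reaches hundreds).
#' @param seed optional integer seed set before sampling.
#' @param verbose print progress.
#' @return an object of class `lnbart` with retained draws: `yhat_train` and
#'   `yhat_test` (draws x observations, on the original outcome scale),
#'   `sigma2`, `s`, `varcount`, the per-draw pointwise log-likelihood matrix
#'   `loglik`, prior-specific draws (`theta`, or `psi`/`beta`/`tau2`), the
#'   final ensemble (`ensemble`), the outcome center and the configuration.
#' @export
lnbart <- function(x, y, x_test = NULL,
                   prior = c("logitnormal", "dirichlet", "uniform"),
                   annotations = NULL,
                   n_trees = 200L, n_iter = 10000L, burn = floor(n_iter / 2),
                   thin = 5L,
                   alpha = 0.95, lambda = 2,
                   depth_form = c("exponential", "power"),
                   k = 2, nu = 3, sigma_quantile = 0.95,
                   n_cuts = 100L,
                   dart = list(a = 0.5, b = 1, rho = NULL),
                   ln = list(v_beta0 = 100,
                             tau_prior = list(type = "half-t", scale = 1, df = 3),
                             tau2_init = 1, reference = NULL,
                             Sigma_psi0 = NULL),
                   pg_threshold = 30L,
                   seed = NULL, verbose = FALSE) {
  prior <- match.arg(prior)
  depth_form <- match.arg(depth_form)
  dart <- utils::modifyList(list(a = 0.5, b = 1, rho = NULL), dart)
  ln <- utils::modifyList(
    list(v_beta0 = 100, tau_prior = list(type = "half-t", scale = 1, df = 3),
         tau2_init = 1, reference = NULL, Sigma_psi0 = NULL), ln)
  if (!is.null(seed)) set.seed(seed)

  x <- as.matrix(x)
  if (!is.numeric(x) || !is.numeric(y)) stop("'x' and 'y' must be numeric")
  n <- nrow(x); p <- ncol(x)
  if (n == 0L || p == 0L) stop("'x' must have at least one row and column")
  if (length(y) != n) stop("length(y) must match nrow(x)")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (!is.null(x_test)) {
    x_test <- as.matrix(x_test)
    if (ncol(x_test) != p) stop("'x_test' must have the same columns as 'x'")
  }

  center <- mean(y)
  yc <- y - center
  noise_prior <- calibrate_noise_prior(y, x, nu = nu, quantile = sigma_quantile)
  leaf_sd <- diff(range(yc)) / (2 * k * sqrt(n_trees))
  if (leaf_sd <= 0) stop("'y' is constant")
  cutpoints <- make_cutpoints(x, n_cuts)

  ptr <- .bart_init_cpp(x, yc, cutpoints, as.integer(n_trees),
                        alpha, lambda,
                        if (depth_form == "exponential") 0L else 1L,
                        leaf_sd)

  s <- rep(1 / p, p)
  sigma2 <- noise_prior$sigma2_hat
  theta <- NULL
  state <- NULL
  if (prior == "dirichlet") {
    if (is.null(dart$rho)) dart$rho <- p
    theta <- p  # conventional starting value: prior mean scale
  } else if (prior == "logitnormal") {
    des <- if (is.null(annotations)) NULL else
      annotation_design(as.matrix(annotations),
                        reference = if (is.null(ln$reference)) p else ln$reference,
                        v_beta0 = if (is.null(ln$v_beta0)) 100 else ln$v_beta0)
    state <- ln_state(p, annotations = des,
                      tau2 = if (is.null(ln$tau2_init)) 1 else ln$tau2_init,
                      tau_prior = if (is.null(ln$tau_prior))
                        list(type = "half-t", scale = 1, df = 3) else ln$tau_prior,
                      reference = if (is.null(ln$reference)) p else ln$reference,
                      Sigma_psi0 = ln$Sigma_psi0)
  } else if (!is.null(annotations)) {
    warning("'annotations' are only used by the logitnormal prior; ignored")
  }

  keep_at <- seq.int(burn + thin, n_iter, by = thin)
  n_keep <- length(keep_at)
  if (n_keep == 0L) stop("no draws retained; check n_iter/burn/thin")
  Tn <- if (!is.null(state) && !is.null(state$annotations))
    ncol(state$annotations$A_tilde_nr) else 0L

  out_sigma2 <- numeric(n_keep)
  out_s <- matrix(NA_real_, n_keep, p)
  out_varcount <- matrix(NA_integer_, n_keep, p)
  out_train <- matrix(NA_real_, n_keep, n)
  out_test <- if (is.null(x_test)) NULL else matrix(NA_real_, n_keep, nrow(x_test))
  out_loglik <- matrix(NA_real_, n_keep, n)
  out_theta <- if (prior == "dirichlet") numeric(n_keep) else NULL
  out_psi <- if (prior == "logitnormal") matrix(NA_real_, n_keep, p) else NULL
  out_tau2 <- if (prior == "logitnormal") numeric(n_keep) else NULL
  out_beta <- if (Tn > 0) matrix(NA_real_, n_keep, Tn) else NULL

  ki <- 0L
  for (it in seq_len(n_iter)) {
    res <- .bart_iter_cpp(ptr, s, sigma2)
    sigma2 <- sigma2_update(res$rss, n, noise_prior)
    counts <- res$counts
    if (prior == "dirichlet") {
      s <- dirichlet_update(counts, theta, p)
      theta <- theta_update(s, a = dart$a, b = dart$b, rho = dart$rho)
    } else if (prior == "logitnormal") {
      state <- sweep_update(state, counts, pg_threshold = pg_threshold)
      s <- state$s
    }
    if (ki < n_keep && it == keep_at[ki + 1L]) {
      ki <- ki + 1L
      out_sigma2[ki] <- sigma2
      out_s[ki, ] <- s
      out_varcount[ki, ] <- counts
      fit <- res$fit
      out_train[ki, ] <- fit + center
      out_loglik[ki, ] <- dnorm(yc, fit, sqrt(sigma2), log = TRUE)
      if (!is.null(out_test))
        out_test[ki, ] <- .bart_predict_cpp(ptr, x_test) + center
      if (!is.null(out_theta)) out_theta[ki] <- theta
      if (!is.null(out_psi)) {
        out_psi[ki, ] <- state$psi
        out_tau2[ki] <- state$tau2
        if (Tn > 0) out_beta[ki, ] <- state$beta
      }
    }
    if (verbose && it %% 1000L == 0L)
      message("iteration ", it, "/", n_iter)
  }

  ensemble <- as_ensemble(.bart_trees_cpp(ptr), center = center)

  structure(list(yhat_train = out_train, yhat_test = out_test,
                 sigma2 = out_sigma2, s = out_s, varcount = out_varcount,
                 loglik = out_loglik, theta = out_theta, psi = out_psi,
                 tau2 = out_tau2, beta = out_beta,
                 ensemble = ensemble, center = center,
                 prior = prior, n_keep = n_keep, n = n, p = p,
                 noise_prior = noise_prior, leaf_sd = leaf_sd,
                 config = list(n_trees = n_trees, n_iter = n_iter,
                               burn = burn, thin = thin, alpha = alpha,
                               lambda = lambda, depth_form = depth_form,
                               k = k, n_cuts = n_cuts,
                               pg_threshold = pg_threshold)),
            class = "lnbart")
}

#' @export
print.lnbart <- function(x, ...) {
  cat("BART fit (", x$prior, " split prior): n = ", x$n, ", p = ", x$p,
      ", trees = ", x$config$n_trees, "\n", sep = "")
  cat(x$n_keep, "retained draws;",
      sprintf("posterior mean sigma^2 = %.4g", mean(x$sigma2)), "\n")
  invisible(x)
}

#' Wrap serialized trees into an ensemble object
#'
#' An ensemble is a list of tree tables plus the outcome center.  Each tree
#' table has one row per node with columns `node`, `parent`, `left`,
#' `right`, `var`, `cut`, `mu` and `depth`; interior rows carry the
#' splitting rule (`var`, `cut`), terminal rows the value `mu`.
#'
#' @param trees list of tree data frames.
#' @param center additive outcome center of the ensemble.
#' @return an object of class `lnbart_ensemble`.
#' @export
as_ensemble <- function(trees, center = 0) {
  structure(list(trees = trees, H = length(trees), center = center),
            class = "lnbart_ensemble")
}

#' Evaluate an ensemble at new points
#'
#' Routes each row of `x` through every tree (rule `x <= cut` goes left),
#' sums the terminal values and adds the outcome center.
#'
#' @param ensemble an `lnbart_ensemble`.
#' @param x numeric matrix of points.
#' @return numeric vector of predictions.
#' @export
predict_ensemble <- function(ensemble, x) {
  x <- as.matrix(x)
  out <- rep(ensemble$center, nrow(x))
  for (tr in ensemble$trees) {
    for (i in seq_len(nrow(x))) {
      id <- 1L
      while (!is.na(tr$var[id])) {
        id <- if (x[i, tr$var[id]] <= tr$cut[id]) tr$left[id] else tr$right[id]
      }
      out[i] <- out[i] + tr$mu[id]
    }
  }
  out
}
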