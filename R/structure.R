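#' Depth-dependent split probability of the tree-structure prior
#'
#' The probability that a node at depth `d` (root at 0) is split is
#' `alpha * (1 + lambda)^(-d)` under the default exponential-decay form.
#' The classical power-law form `alpha * (1 + d)^(-lambda)` is available
#' behind `form = "power"`; the two coincide at the root but the exponential
#' form decays faster (0.95, 0.3167, 0.1056, ... with the defaults).
#'
#' @param d node depth, nonnegative integer (vectorized).
#' @param alpha base split probability at the root, in (0, 1).
#' @param lambda decay parameter, positive.
#' @param form `"exponential"` for `alpha (1+lambda)^-d` (default) or
#'   `"power"` for the classical `alpha (1+d)^-lambda`.
#' @return vector of probabilities in (0, 1].
#' @examples
#' depth_split_prob(0:3)
#' @export
depth_split_prob <- function(d, alpha = 0.95, lambda = 2,
                             form = c("exponential", "power")) {
  form <- match.arg(form)
  if (any(d < 0)) stop("'d' must be nonnegative")
  if (alpha < 0 || alpha >= 1) stop("'alpha' must be in [0, 1)")
  if (lambda <= 0) stop("'lambda' must be positive")
  if (form == "exponential") alpha * (1 + lambda)^(-d) else alpha * (1 + d)^(-lambda)
}

#' Calibrate the scaled-inverse-chi-squared noise prior
#'
#' The noise variance prior is sigma^2 ~ nu * lambda / chi^2_nu.  The scale
#' `lambda` is set so that a data-based estimate of sigma^2 sits at the
#' `quantile` (default 0.95) percentile of the prior.  The estimate is the
#' residual variance of a linear regression of `y` on `x` when the
#' coefficient count is below the sample size, and the sample variance of
#' `y` otherwise (or when `x` is not supplied).
#'
#' @param y outcome vector (length >= 2, non-constant).
#' @param x optional predictor matrix used for the regression-based estimate.
#' @param nu prior degrees of freedom (small integer, conventionally 1-5).
#' @param quantile prior percentile at which the data-based estimate is
#'   placed.
#' @return an object of class `lnbart_noise_prior`: a list with `nu`,
#'   `quantile`, `sigma2_hat` and the prior scale `lambda`.
#' @export
calibrate_noise_prior <- function(y, x = NULL, nu = 3, quantile = 0.95) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2) stop("need at least two observations")
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) stop("'y' is constant; noise variance cannot be calibrated")
  sigma2_hat <- vy
  if (!is.null(x)) {
    x <- as.matrix(x)
    p <- ncol(x)
    if (p + 1L < n) {
      fit <- stats::lm.fit(cbind(1, x), y)
      df <- n - fit$rank
      if (df > 0) {
        s2 <- sum(fit$residuals^2) / df
        if (is.finite(s2) && s2 > 0) sigma2_hat <- s2
      }
    }
  }
  lambda <- sigma2_hat * stats::qchisq(1 - quantile, df = nu) / nu
  structure(list(nu = nu, quantile = quantile, sigma2_hat = sigma2_hat,
                 lambda = lambda),
            class = "lnbart_noise_prior")
}

#' Conjugate draw of the noise variance
#'
#' Given the residual sum of squares of the current ensemble fit, draws
#' sigma^2 from the scaled-inverse-chi-squared posterior
#' `(nu * lambda + rss) / chi^2_{nu + n}`.  With `n = 0` this reproduces a
#' prior draw.
#'
#' @param rss residual sum of squares.
#' @param n number of observations contributing to `rss`.
#' @param prior an `lnbart_noise_prior` from [calibrate_noise_prior()].
#' @return a positive scalar draw of sigma^2.
#' @export
sigma2_update <- function(rss, n, prior) {
  (prior$nu * prior$lambda + rss) / stats::rchisq(1, df = prior$nu + n)
}
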