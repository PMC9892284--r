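#' Out-of-sample R-squared, in percent
#'
#' `100 * (1 - sum((y - yhat)^2) / sum((y - mean(y))^2))` for the default
#' `type = "sse"`; negative values indicate a predictor worse than the
#' test-set mean.  `type = "cor"` returns the squared Pearson correlation
#' (also in percent), a scale-free alternative.
#'
#' @param y_test observed test outcomes.
#' @param y_pred predictions (e.g. the posterior mean of `f`).
#' @param type `"sse"` (default) or `"cor"`.
#' @return a percentage.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))
#' @export
r_squared <- function(y_test, y_pred, type = c("sse", "cor")) {
  type <- match.arg(type)
  if (length(y_test) != length(y_pred)) stop("length mismatch")
  if (length(y_test) < 2) stop("need at least two observations")
  sst <- sum((y_test - mean(y_test))^2)
  if (sst <= 0) stop("'y_test' is constant")
  if (type == "sse") 100 * (1 - sum((y_test - y_pred)^2) / sst)
  else 100 * stats::cor(y_test, y_pred)^2
}

# fit one method on one simulated dataset; returns test-set predictions
fit_method <- function(method, ds, mcmc) {
  fit_bart <- function(prior, annotations = NULL)
    do.call(lnbart, c(list(x = ds$X_train, y = ds$y_train,
                           x_test = ds$X_test, prior = prior,
                           annotations = annotations), mcmc))
  switch(method,
    oracle = ds$f_test,
    bart = colMeans(fit_bart("uniform")$yhat_test),
    dart = colMeans(fit_bart("dirichlet")$yhat_test),
    ln0 = colMeans(fit_bart("logitnormal")$yhat_test),
    lna = colMeans(fit_bart("logitnormal", annotations = ds$A)$yhat_test),
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("method 'rf' needs the randomForest package")
      rf <- randomForest::randomForest(ds$X_train, ds$y_train)
      as.numeric(stats::predict(rf, ds$X_test))
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("method 'svm' needs the e1071 package")
      sv <- e1071::svm(ds$X_train, ds$y_train)
      as.numeric(stats::predict(sv, ds$X_test))
    },
    stop("unknown method: ", method)
  )
}

#' Benchmark prediction methods over simulation scenarios
#'
#' For each scenario and replicate, simulates one dataset (per-replicate
#' seeds derived deterministically from the master seed, so two runs with
#' the same seed give identical tables) and fits every requested method on
#' the same data; reports the per-replicate and mean out-of-sample
#' R-squared.  Methods: `"lna"`, `"ln0"`, `"dart"`, `"bart"`, `"oracle"`
#' (predicts with the true `f`) and, if the corresponding packages are
#' installed, `"rf"` and `"svm"` at their default settings.  A method
#' failure on a replicate is recorded as `NA`, excluded from the mean and
#' counted in `n_fail`.
#'
#' @param scenarios a single `lnbart_scenario` or a list of them.
#' @param methods character vector of method names.
#' @param n_reps replicates per scenario.
#' @param mcmc list of arguments passed to [lnbart()] (e.g. `n_iter`,
#'   `n_trees`).
#' @param seed master seed.
#' @param mc_draws Monte-Carlo size for the noise calibration of each
#'   simulated dataset.
#' @param verbose print progress.
#' @return an object of class `lnbart_benchmark`: list with `table` (one row
#'   per scenario x method: settings, `r2_mean`, `n_reps`, `n_fail`) and
#'   `per_rep` (per-scenario replicate x method matrices).
#' @export
run_benchmark <- function(scenarios, methods = c("lna", "ln0", "dart", "bart"),
                          n_reps = 10L, mcmc = list(), seed = 1L,
                          mc_draws = 1e5, verbose = FALSE) {
  if (inherits(scenarios, "lnbart_scenario")) scenarios <- list(scenarios)
  per_rep <- vector("list", length(scenarios))
  rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    r2 <- matrix(NA_real_, n_reps, length(methods),
                 dimnames = list(NULL, methods))
    for (rep in seq_len(n_reps)) {
      sc$seed <- (seed * 1009L + si * 101L + rep) %% 2147483647L
      ds <- simulate_dataset(sc, mc_draws = mc_draws)
      for (mi in seq_along(methods)) {
        pred <- tryCatch(fit_method(methods[mi], ds, mcmc),
                         error = function(e) {
                           warning("method ", methods[mi], " failed on rep ",
                                   rep, ": ", conditionMessage(e))
                           NULL
                         })
        if (!is.null(pred)) r2[rep, mi] <- r_squared(ds$y_test, pred)
      }
      if (verbose)
        message(sprintf("scenario %d rep %d: %s", si, rep,
                        paste(sprintf("%s=%.1f", methods, r2[rep, ]),
                              collapse = " ")))
    }
    per_rep[[si]] <- r2
    for (mi in seq_along(methods)) {
      vals <- r2[, mi]
      rows[[length(rows) + 1L]] <- data.frame(
        informative = sc$informative, p = sc$p, tau2 = sc$tau2,
        correlation = sc$correlation, method = methods[mi],
        r2_mean = mean(vals, na.rm = TRUE),
        n_reps = sum(!is.na(vals)), n_fail = sum(is.na(vals)))
    }
  }
  structure(list(table = do.call(rbind, rows), per_rep = per_rep,
                 methods = methods, n_reps = n_reps, seed = seed,
                 mcmc = mcmc),
            class = "lnbart_benchmark")
}

#' @export
print.lnbart_benchmark <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
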