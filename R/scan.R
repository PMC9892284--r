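#' ELPD model scan across many datasets
#'
#' The batch counterpart of a per-gene genome scan: for every dataset, fit
#' each requested model on the training data, compute its PSIS-LOO ELPD and
#' report pairwise differences against the first (reference) model.  In the
#' genome-scan workflow the reference is the covariate-free null model and
#' the datasets are one gene's cis-SNP matrix each; the dataset with the
#' largest ELPD difference identifies the most predictable outcome.
#'
#' @param datasets list of datasets; each element either an
#'   `lnbart_dataset` or a list with elements `x`, `y` (and optionally `A`
#'   for the annotation-informed prior).
#' @param methods character vector: `"null"`, `"bart"`, `"dart"`, `"ln0"`,
#'   `"lna"`.  The first entry is the comparison reference.
#' @param mcmc list of arguments passed to [lnbart()].
#' @param n_null_draws posterior draws for the null model.
#' @param seed master seed; per-dataset seeds are derived from it.
#' @return a data frame with one row per dataset x method: `dataset`,
#'   `method`, `elpd`, `se`, `n_high_khat`, and `elpd_diff` (ELPD minus the
#'   reference method's ELPD on the same dataset).
#' @export
elpd_scan <- function(datasets, methods = c("null", "bart"), mcmc = list(),
                      n_null_draws = 1000L, seed = 1L) {
  rows <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    x <- if (!is.null(ds$X_train)) ds$X_train else ds$x
    y <- if (!is.null(ds$y_train)) ds$y_train else ds$y
    elpds <- list()
    for (m in methods) {
      ll <- if (m == "null") {
        fit_null_model(y, n_draws = n_null_draws,
                       seed = (seed * 613 + di) %% 2147483647)$loglik
      } else {
        prior <- switch(m, bart = "uniform", dart = "dirichlet",
                        ln0 = "logitnormal", lna = "logitnormal",
                        stop("unknown method: ", m))
        ann <- if (m == "lna") ds$A else NULL
        do.call(lnbart, c(list(x = x, y = y, prior = prior,
                               annotations = ann,
                               seed = (seed * 613 + di) %% 2147483647),
                          mcmc))$loglik
      }
      elpds[[m]] <- loo_elpd(ll)
    }
    ref <- elpds[[methods[1]]]$elpd
    for (m in methods) {
      e <- elpds[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = di, method = m, elpd = e$elpd, se = e$se,
        n_high_khat = sum(e$khat > 0.5), elpd_diff = e$elpd - ref)
    }
  }
  do.call(rbind, rows)
}
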