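test_that("input validation rejects degenerate problems", {
  expect_error(lnbart(matrix(numeric(0), 0, 0), numeric(0)), "at least one")
  expect_error(lnbart(matrix("a", 2, 1), c(1, 2)), "numeric")
  expect_error(lnbart(matrix(1:4, 2, 2), c(1, 2, 3)), "match")
  expect_error(lnbart(matrix(rnorm(10), 5, 2), rep(1, 5)), "constant")
})

test_that("a stump-only ensemble predicts the outcome mean everywhere", {
  set.seed(31)
  n <- 40
  x <- matrix(runif(n * 2), n, 2)
  y <- rnorm(n, 3, 1)
  f <- lnbart(x, y, x_test = x[1:5, ], prior = "uniform", alpha = 1e-8,
              n_trees = 1, n_iter = 400, burn = 200, thin = 2, seed = 1)
  expect_equal(unname(colMeans(f$yhat_test)), rep(mean(y), 5), tolerance = 0.05)
  expect_true(all(rowSums(f$varcount) == 0))
})

test_that("the reference MCMC schedule retains exactly 1000 draws", {
  set.seed(32)
  x <- matrix(runif(20), 10, 2)
  y <- rnorm(10)
  f <- lnbart(x, y, prior = "uniform", n_trees = 2, n_iter = 10000, seed = 1)
  # 10000 iterations, first half burn-in, every fifth of the second half
  expect_identical(f$n_keep, 1000L)
  expect_identical(nrow(f$yhat_train), 1000L)
})

test_that("fits are reproducible given a seed", {
  set.seed(33)
  x <- matrix(runif(60), 30, 2)
  y <- x[, 1] + rnorm(30, 0, 0.3)
  args <- c(list(x = x, y = y, x_test = x, prior = "dirichlet", seed = 77),
            quick_mcmc)
  f1 <- do.call(lnbart, args)
  f2 <- do.call(lnbart, args)
  expect_identical(f1$yhat_test, f2$yhat_test)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_identical(f1$s, f2$s)
})

test_that("terminal-value draws follow the normal conjugate posterior", {
  set.seed(34)
  n <- 25
  x <- matrix(runif(n), n, 1)
  y <- rnorm(n, 1.5, 0.4)
  yc <- y - mean(y)
  leaf_sd <- 0.3
  sigma2 <- 0.16
  ptr <- lnbart:::.bart_init_cpp(x, yc, make_cutpoints(x), 1L,
                                 1e-9, 2, 0L, leaf_sd)  # alpha ~ 0: stump
  draws <- replicate(2e4, lnbart:::.bart_iter_cpp(ptr, 1, sigma2)$fit[1])
  prec <- n / sigma2 + 1 / leaf_sd^2
  expect_equal(mean(draws), (sum(yc) / sigma2) / prec, tolerance = 5e-3)
  expect_equal(var(draws), 1 / prec, tolerance = 0.05)
})

test_that("a point-mass split-probability vector restricts splits to that predictor", {
  set.seed(35)
  n <- 60
  x <- matrix(runif(n * 4), n, 4)
  y <- ifelse(x[, 3] <= 0.5, 0, 2) + rnorm(n, 0, 0.2)
  ptr <- lnbart:::.bart_init_cpp(x, y - mean(y), make_cutpoints(x), 10L,
                                 0.95, 2, 0L, 0.2)
  s <- c(0, 0, 1, 0)
  for (it in 1:200) res <- lnbart:::.bart_iter_cpp(ptr, s, 0.04)
  expect_gt(res$R, 0)
  expect_identical(sum(res$counts[-3]), 0L)
})

test_that("trees sampled from the structure prior alone stay shallow", {
  # direct recursion on the depth prior: split a node at depth d with
  # probability delta(d); depth >= 3 should be rare with the defaults
  set.seed(36)
  sample_depths <- function(d) {
    if (runif(1) < depth_split_prob(d)) c(sample_depths(d + 1), sample_depths(d + 1))
    else d
  }
  depths <- unlist(replicate(3000, sample_depths(0)))
  # analytic leaf-depth distribution of the default prior puts ~10% of
  # leaves at depth >= 3 and mean depth ~1.7
  expect_lt(mean(depths >= 3), 0.13)
  expect_lt(mean(depths), 2)
  expect_lt(mean(depths >= 5), 0.005)
})

test_that("every point is routed to exactly one terminal region per tree", {
  set.seed(37)
  n <- 80
  x <- matrix(runif(n * 3), n, 3)
  y <- sin(2 * pi * x[, 1]) + rnorm(n, 0, 0.3)
  f <- do.call(lnbart, c(list(x = x, y = y, prior = "uniform", seed = 5), quick_mcmc))
  # independent region predicate: constraints collected on the path from root
  region_count <- function(tr, xrow) {
    hits <- 0L
    walk <- function(id, ok) {
      if (is.na(tr$var[id])) {
        if (ok) hits <<- hits + 1L
        return(invisible())
      }
      left_ok <- ok && xrow[tr$var[id]] <= tr$cut[id]
      right_ok <- ok && xrow[tr$var[id]] > tr$cut[id]
      walk(tr$left[id], left_ok)
      walk(tr$right[id], right_ok)
    }
    walk(1L, TRUE)
    hits
  }
  xnew <- matrix(runif(60), 20, 3)
  for (tr in f$ensemble$trees[1:10])
    for (i in 1:nrow(xnew))
      expect_identical(region_count(tr, xnew[i, ]), 1L)
})

test_that("the serialized ensemble reproduces the final retained fit", {
  set.seed(38)
  n <- 50
  x <- matrix(runif(n * 2), n, 2)
  y <- x[, 1] * 2 + rnorm(n, 0, 0.3)
  # thinning chosen so the last retained draw is the final MCMC state
  f <- lnbart(x, y, x_test = x, prior = "uniform", n_trees = 20,
              n_iter = 600, burn = 300, thin = 3, seed = 9)
  expect_equal(predict_ensemble(f$ensemble, x),
               unname(f$yhat_test[nrow(f$yhat_test), ]), tolerance = 1e-10)
})

test_that("MH tree moves target the exactly enumerable two-observation posterior", {
  set.seed(39)
  x <- matrix(c(0, 1), 2, 1)
  y <- c(-1, 1)
  f <- lnbart(x, y, prior = "uniform", n_trees = 1, n_iter = 60000,
              burn = 5000, thin = 1, seed = 4)
  p_split_chain <- mean(rowSums(f$varcount) == 1)
  # enumerate both tree states, integrating the leaves in closed form and
  # sigma2 numerically against its scaled-inverse-chi-squared prior
  v <- f$leaf_sd^2
  np <- f$noise_prior
  yc <- y - mean(y)
  mleaf <- function(r, s2) {
    m <- length(r)
    -m / 2 * log(2 * pi * s2) + 0.5 * log(s2 / (s2 + m * v)) -
      sum(r^2) / (2 * s2) + v * sum(r)^2 / (2 * s2 * (s2 + m * v))
  }
  lg <- seq(log(1e-4), log(50), length.out = 4000)
  s2g <- exp(lg)
  lp_s2 <- np$nu / 2 * log(np$nu * np$lambda / 2) - lgamma(np$nu / 2) -
    (np$nu / 2 + 1) * log(s2g) - np$nu * np$lambda / (2 * s2g) + lg
  d0 <- depth_split_prob(0); d1 <- depth_split_prob(1)
  lm0 <- sapply(s2g, function(s2) mleaf(yc, s2)) + log(1 - d0)
  lm1 <- sapply(s2g, function(s2) mleaf(yc[1], s2) + mleaf(yc[2], s2)) +
    log(d0) + 2 * log(1 - d1)
  M <- max(c(lm0 + lp_s2, lm1 + lp_s2))
  I0 <- sum(exp(lm0 + lp_s2 - M))
  I1 <- sum(exp(lm1 + lp_s2 - M))
  expect_equal(p_split_chain, I1 / (I0 + I1), tolerance = 0.02)
})

test_that("a sharp step function is recovered within posterior uncertainty", {
  set.seed(40)
  n <- 150
  x <- matrix(runif(n * 2), n, 2)
  f_true <- ifelse(x[, 1] <= 0.4, 1, 3)
  y <- f_true + rnorm(n, 0, 0.1)
  fit <- lnbart(x, y, x_test = x, prior = "uniform", n_trees = 50,
                n_iter = 1200, burn = 600, thin = 3, seed = 2)
  pm <- colMeans(fit$yhat_test)
  psd <- apply(fit$yhat_test, 2, sd)
  interior <- abs(x[, 1] - 0.4) > 0.05   # away from the boundary
  expect_true(all(abs(pm - f_true)[interior] <= 3 * psd[interior] + 0.05))
})
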