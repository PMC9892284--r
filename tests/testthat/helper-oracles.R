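# shared fixtures and independent oracles, built in code

# build a tree table row by row; interior rows give var/cut, leaves give mu
toy_tree <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(node = r[["node"]], parent = r[["parent"]],
               left = r[["left"]], right = r[["right"]],
               var = r[["var"]], cut = r[["cut"]],
               mu = r[["mu"]], depth = r[["depth"]])))
}

nd_int <- function(node, parent, left, right, var, cut, depth)
  list(node = node, parent = parent, left = left, right = right,
       var = var, cut = cut, mu = NA_real_, depth = depth)
nd_leaf <- function(node, parent, mu, depth)
  list(node = node, parent = parent, left = NA_integer_, right = NA_integer_,
       var = NA_integer_, cut = NA_real_, mu = mu, depth = depth)

# the ensemble of the three-tree toy example: splits in x1 at 0.3, 0.5, 0.7
# and in x2 at 0.25, 0.75
figure_toy_ensemble <- function() {
  t1 <- toy_tree(nd_int(1, NA, 2, 3, 1L, 0.5, 0),
                 nd_leaf(2, 1, 1, 1),
                 nd_int(3, 1, 4, 5, 2L, 0.25, 1),
                 nd_leaf(4, 3, 2, 2), nd_leaf(5, 3, 3, 2))
  t2 <- toy_tree(nd_int(1, NA, 2, 3, 1L, 0.3, 0),
                 nd_leaf(2, 1, -1, 1),
                 nd_int(3, 1, 4, 5, 1L, 0.7, 1),
                 nd_leaf(4, 3, 0.5, 2), nd_leaf(5, 3, -0.5, 2))
  t3 <- toy_tree(nd_int(1, NA, 2, 3, 2L, 0.75, 0),
                 nd_leaf(2, 1, 0.25, 1), nd_leaf(3, 1, -0.25, 1))
  as_ensemble(list(t1, t2, t3), center = 0)
}

# brute-force recursive split tally, independent of count_splits()
count_splits_walk <- function(ensemble, p) {
  counts <- integer(p)
  walk <- function(tr, id) {
    if (is.na(tr$var[id])) return(invisible())
    counts[tr$var[id]] <<- counts[tr$var[id]] + 1L
    walk(tr, tr$left[id])
    walk(tr, tr$right[id])
  }
  for (tr in ensemble$trees) walk(tr, 1L)
  list(counts = counts, R = sum(counts))
}

# independent re-implementation of the ten signal pieces (direct formulas,
# evaluated pointwise) for the dual-implementation check
true_function_oracle <- function(X, s) {
  f_j <- function(x, k) {
    switch(k,
           sin(pi * (x - 1)),
           -x^2,
           exp(x),
           if (x <= 1) 1 else 0,
           if (x >= 1) 1 else 0,
           x^2 - x,
           -log(x + 1),
           cos(pi * (x - 1)),
           -x * (x^2 - 1),
           (if (x != 0) 1 else 0) * sin(pi * (x - 1)) -
             (if (x == 0) 1 else 0) * sin(pi * (x - 1)))
  }
  vapply(seq_len(nrow(X)), function(i) {
    tot <- 0
    for (j in seq_len(ncol(X)))
      tot <- tot + s[j] * f_j(X[i, j], ((j - 1) %% 10) + 1)
    0.5 * tot + 4.5
  }, numeric(1))
}

# small quick-fit settings reused across MCMC tests
quick_mcmc <- list(n_trees = 50, n_iter = 600, burn = 300, thin = 3)

# Kolmogorov-Smirnov distance between a sample and a discrete-grid cdf
ks_against_grid <- function(samp, grid, cdf) {
  max(abs(stats::ecdf(samp)(grid) - cdf))
}
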