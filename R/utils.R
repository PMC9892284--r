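# numeric helpers shared across modules

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

# inverse-gamma draw parameterized by shape and rate
rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)
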