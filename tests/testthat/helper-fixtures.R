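# Shared fixtures and small independent oracles used across test files.

# leatherback-like parameter sets
fx_params <- function() flexit_params(P = 29.49, S = 2.34, dS = 0.49)
fx_growth <- function() default_growth_params()

# brute-force per-egg Bernoulli log-likelihood (independent of loglik_counts,
# which works on binomial counts); valid for integer counts
brute_loglik <- function(params, data) {
  tot <- 0
  for (i in seq_len(nrow(data))) {
    p <- sex_ratio(params, data$temperature_C[i])
    p <- min(max(p, 1e-15), 1 - 1e-15)
    eggs <- c(rep(TRUE, data$females[i]), rep(FALSE, data$males[i]))
    for (e in eggs) tot <- tot + if (e) log(p) else log(1 - p)
  }
  tot
}

# closed-form incubation duration at constant temperature (exponential growth)
closed_duration_days <- function(params, temp, scl0 = 1.7, scl_hatch = 59.3) {
  log(scl_hatch / scl0) / schoolfield_rate(params, temp) / 1440
}

# random valid flexit parameter set
rand_flexit <- function() {
  P <- runif(1, 26, 33)
  S <- runif(1, 0.2, 8)
  dS <- runif(1, -0.8 * S, 4)
  flexit_params(P, S, dS)
}

# short reduced MCMC settings for tests that only need a functioning chain
fast_settings <- function() mcmc_settings(burnin = 200, iter = 1000, thin = 5)
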