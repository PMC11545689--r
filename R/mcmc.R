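#' MCMC sampler settings
#'
#' Defaults follow the study protocol used throughout the package:
#' 1000 burn-in iterations, 10,000 sampling iterations, thinning of 10
#' (so 1000 retained draws).
#'
#' @param burnin burn-in iterations (proposal scales adapt only here).
#' @param iter post-burn-in iterations.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @return A validated list of class `"mcmc_settings"`.
#' @export
mcmc_settings <- function(burnin = 1000, iter = 10000, thin = 10) {
  stopifnot(burnin >= 0, iter >= 1, thin >= 1, iter >= thin)
  structure(list(burnin = as.integer(burnin), iter = as.integer(iter),
                 thin = as.integer(thin)),
            class = "mcmc_settings")
}

## Adaptive Metropolis-within-Gibbs with a joint block refresher.
##
## Each iteration makes one Gaussian random-walk update per parameter;
## single-site proposal scales are adapted in batches of 50 during burn-in
## toward a 0.44 acceptance rate and then frozen. In addition, `n_joint`
## multivariate random-walk proposals per iteration are made on the
## parameters in `joint_block`, with covariance (2.38^2/d) * Sigma_hat where
## Sigma_hat is the running empirical covariance of the whole chain history
## (Haario-type adaptation; the recursive update makes the adaptation
## diminish, and it decorrelates strongly correlated parameters such as the
## pivotal temperature and the limb slopes). Fully deterministic given
## `seed`.
run_adaptive_mwg <- function(loglik, logprior, init, settings, seed,
                             scales, adapt_batch = 50L, target_accept = 0.44,
                             joint_block = NULL, n_joint = 3L,
                             joint_start = 300L) {
  stopifnot(inherits(settings, "mcmc_settings"))
  set.seed(as.integer(seed))
  p <- length(init)
  stopifnot(length(scales) == p, !is.null(names(init)))
  if (is.null(joint_block)) joint_block <- seq_len(min(p, 12L))
  d <- length(joint_block)
  theta <- init
  lp <- logprior(theta)
  ll <- if (is.finite(lp)) loglik(theta) else -Inf
  if (!is.finite(lp + ll))
    stop("non-finite posterior at initial values")
  nkeep <- settings$iter %/% settings$thin
  draws <- matrix(NA_real_, nkeep, p, dimnames = list(NULL, names(init)))
  ll_out <- numeric(nkeep)
  acc_batch <- numeric(p)
  acc_post <- numeric(p)
  kept <- 0L
  total <- settings$burnin + settings$iter
  mu <- theta[joint_block]
  Cv <- matrix(0, d, d)
  sd_j <- 2.38^2 / d
  for (it in seq_len(total)) {
    for (j in seq_len(p)) {
      prop <- theta
      prop[j] <- theta[j] + stats::rnorm(1, 0, scales[j])
      lp2 <- logprior(prop)
      if (lp2 > -Inf) {
        ll2 <- loglik(prop)
        if (is.finite(ll2) &&
            log(stats::runif(1)) < (ll2 + lp2) - (ll + lp)) {
          theta <- prop; ll <- ll2; lp <- lp2
          acc_batch[j] <- acc_batch[j] + 1
          if (it > settings$burnin) acc_post[j] <- acc_post[j] + 1
        }
      }
    }
    if (it <= settings$burnin && it %% adapt_batch == 0L) {
      rate <- acc_batch / adapt_batch
      scales <- scales * exp(rate - target_accept)
      acc_batch[] <- 0
    }
    ## running mean / covariance of the joint block over the whole history
    dev <- theta[joint_block] - mu
    mu <- mu + dev / it
    Cv <- Cv * (it - 1) / it + tcrossprod(dev, theta[joint_block] - mu) / it
    if (it > joint_start && d > 1L) {
      L <- tryCatch(t(chol(sd_j * (Cv + diag(1e-8, d)))),
                    error = function(e) NULL)
      if (!is.null(L)) {
        for (rep_j in seq_len(n_joint)) {
          prop <- theta
          prop[joint_block] <- theta[joint_block] +
            as.vector(L %*% stats::rnorm(d))
          lp2 <- logprior(prop)
          if (lp2 > -Inf) {
            ll2 <- loglik(prop)
            if (is.finite(ll2) &&
                log(stats::runif(1)) < (ll2 + lp2) - (ll + lp)) {
              theta <- prop; ll <- ll2; lp <- lp2
            }
          }
        }
      }
    }
    if (it > settings$burnin && (it - settings$burnin) %% settings$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- theta
      ll_out[kept] <- ll
    }
  }
  list(draws = draws, loglik = ll_out, scales = scales,
       accept = acc_post / settings$iter,
       meta = list(seed = as.integer(seed), settings = settings))
}

#' Effective sample size of a chain
#'
#' Spectral estimate (as in standard MCMC diagnostics): the chain length
#' divided by the integrated autocorrelation time, with the spectral density
#' at frequency zero estimated from an AR fit. A constant chain returns its
#' length.
#'
#' @param x numeric vector of draws.
#' @return Effective sample size (between 1 and `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(n)
  s0 <- tryCatch({
    fit <- stats::ar(x, aic = TRUE)
    if (length(fit$ar) == 0) v else fit$var.pred / (1 - sum(fit$ar))^2
  }, error = function(e) v)
  max(1, min(n, n * v / s0))
}
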