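#' Akaike information criterion corrected for small samples
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`; vectorised over `loglik`.
#'
#' @param loglik log-likelihood value(s).
#' @param k number of estimated parameters.
#' @param n sample size; must exceed `k + 1`.
#' @return AICc value(s).
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(is.numeric(loglik), length(k) == 1L, length(n) == 1L)
  if (n <= k + 1)
    stop(errorCondition(
      sprintf("AICc undefined for n = %g <= k + 1 = %g", n, k + 1),
      class = c("tsdnorm_small_sample", "error", "condition")))
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AICc_i - min(AICc)`; interpreted as the probability that model
#' i is the best of those compared. Overflow-safe for large deltas.
#'
#' @param aiccs numeric vector of AICc values (at least two, finite).
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aiccs) {
  if (length(aiccs) < 2L) stop("need at least two models to compare")
  if (any(!is.finite(aiccs))) stop("non-finite AICc value(s)")
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Posterior-predictive AICc and Akaike weights across models
#'
#' For each retained MCMC draw, evaluates every model's AICc at its own
#' draw-d parameters (via the per-draw log-likelihood stored with the fit),
#' converts the set to Akaike weights, and reports the across-draw mean and
#' standard error of both quantities. Models must be fitted to the same
#' data and retain the same number of draws; draws are paired by index.
#'
#' @param models named list; each element either a `posterior_draws` fit
#'   (its `$loglik` and `$meta$k` are used) or a list with elements
#'   `loglik` (numeric vector, one value per retained draw) and `k`.
#' @param n sample size shared by all models (e.g. number of sexed eggs for
#'   TSD models, number of duration observations for growth models).
#' @return A data frame of class `"model_scores"` with columns `model`,
#'   `k`, `n`, `aicc_mean`, `aicc_se`, `weight_mean`, `weight_se`.
#' @export
posterior_model_weights <- function(models, n) {
  stopifnot(is.list(models), length(models) >= 2L, !is.null(names(models)))
  comp <- lapply(models, function(m) {
    if (inherits(m, "posterior_draws"))
      list(loglik = m$loglik, k = m$meta$k)
    else {
      stopifnot(is.numeric(m$loglik), length(m$k) == 1L)
      list(loglik = m$loglik, k = m$k)
    }
  })
  nd <- vapply(comp, function(m) length(m$loglik), integer(1))
  if (length(unique(nd)) != 1L)
    stop("models retain different numbers of draws: ",
         paste(nd, collapse = ", "))
  nd <- nd[1L]
  A <- sapply(comp, function(m) aicc(m$loglik, m$k, n))
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L, dimnames = list(NULL, names(comp)))
  W <- t(apply(A, 1, akaike_weights))
  if (ncol(W) != ncol(A)) W <- t(W)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  out <- data.frame(model = names(models),
                    k = vapply(comp, `[[`, numeric(1), "k"),
                    n = n,
                    aicc_mean = colMeans(A),
                    aicc_se = apply(A, 2, se),
                    weight_mean = colMeans(W),
                    weight_se = apply(W, 2, se),
                    row.names = NULL)
  class(out) <- c("model_scores", "data.frame")
  out
}
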