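#' Summarise posterior draws
#'
#' Median, mean, posterior SD, Monte-Carlo standard error (SD over the
#' square root of the effective sample size), 95% credible limits and
#' effective sample size, for selected parameters or for an arbitrary
#' functional of the parameter vector.
#'
#' @param x a `posterior_draws` object ([fit_tsd()], [fit_growth()]) or a
#'   numeric matrix of draws with named columns.
#' @param pars character vector of parameter names to summarise (default:
#'   all columns). Unknown names are an error.
#' @param functional optional function applied to each draw (a named
#'   parameter vector), returning a (preferably named) numeric vector, e.g.
#'   per-draw TRT limits. Overrides `pars`.
#' @param probs credible-interval probabilities.
#' @return A data frame with one row per summarised quantity and columns
#'   `parameter`, `median`, `mean`, `sd`, `mcse`, `q2.5`, `q97.5`, `ess`.
#' @examples
#' m <- cbind(P = rnorm(500, 29.5, 0.1), S = rexp(500))
#' posterior_summary(m, "P")
#' @export
posterior_summary <- function(x, pars = NULL, functional = NULL,
                              probs = c(0.025, 0.975)) {
  m <- if (inherits(x, "posterior_draws")) x$draws else as.matrix(x)
  if (is.null(colnames(m))) stop("draws must have named columns")
  if (!is.null(functional)) {
    if (!is.function(functional))
      stop("'functional' must be a function of the parameter vector")
    vals <- t(apply(m, 1, functional))
    if (nrow(vals) == 1L && nrow(m) > 1L) vals <- t(vals)
    if (is.null(colnames(vals)))
      colnames(vals) <- paste0("f", seq_len(ncol(vals)))
    m <- vals
    pars <- colnames(m)
  } else {
    if (is.null(pars)) pars <- colnames(m)
    unknown <- setdiff(pars, colnames(m))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    m <- m[, pars, drop = FALSE]
  }
  out <- lapply(seq_along(pars), function(j) {
    v <- m[, j]
    e <- ess(v)
    q <- stats::quantile(v, probs, names = FALSE)
    data.frame(parameter = pars[j], median = stats::median(v),
               mean = mean(v), sd = stats::sd(v),
               mcse = stats::sd(v) / sqrt(e),
               q2.5 = q[1], q97.5 = q[2], ess = e)
  })
  do.call(rbind, out)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d draws of %d parameters (seed %d)\n",
              nrow(x$draws), ncol(x$draws), x$meta$seed))
  invisible(x)
}
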