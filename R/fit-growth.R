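#' Priors for the growth reaction-norm fit
#'
#' Wide uniform boxes on the four Schoolfield parameters.
#'
#' @param rho25,dHA,dHL,T12L length-2 ranges of the uniform priors
#'   (units as in [schoolfield_params()]).
#' @return A list of class `"growth_priors"`.
#' @export
growth_priors <- function(rho25 = c(1e-6, 1e-3), dHA = c(5e3, 2e5),
                          dHL = c(-4e5, -5e3), T12L = c(270, 310)) {
  for (r in list(rho25, dHA, dHL, T12L))
    stopifnot(length(r) == 2L, r[1] < r[2])
  structure(list(rho25 = rho25, dHA = dHA, dHL = dHL, T12L = T12L),
            class = "growth_priors")
}

#' Bayesian fit of the Schoolfield growth reaction norm to incubation durations
#'
#' Fits the 4-parameter thermal reaction norm of embryonic growth to
#' incubation-duration summaries by adaptive Metropolis-within-Gibbs MCMC
#' with wide uniform priors. Each summary row provides the mean duration,
#' its SD and the number of eggs for either a constant incubation
#' temperature (`temp_C`) or a recorded nest temperature series
#' (`series_id`); the likelihood is Gaussian on each group mean with
#' standard error `sd_days / sqrt(n)`. Predicted durations come from the
#' exponential-growth integral of the reaction norm over the group's
#' temperatures; a series that ends before hatching is extended at its last
#' temperature.
#'
#' @param durations data frame with columns `mean_days`, `sd_days` (> 0),
#'   `n` (>= 1) and one of `temp_C` (constant incubation) or `series_id`
#'   (naming an element of `series`); use `NA` in the unused column. An
#'   optional `scl_hatch` column overrides the function argument per row
#'   (datasets from different regions have different hatchling sizes).
#' @param series named list of [temperature_series()] for the `series_id`
#'   rows.
#' @param priors a [growth_priors()] object.
#' @param settings an [mcmc_settings()] object.
#' @param seed integer seed (bit-reproducible draws).
#' @param scl0,scl_hatch initial and hatchling SCL, mm.
#' @param step_min integration step for series rows, minutes.
#' @return An object of classes `"growth_fit"` and `"posterior_draws"`,
#'   with `draws` (columns `rho25`, `dHA`, `dHL`, `T12L`), per-draw
#'   `loglik`, `accept`, and `meta` (`k = 4`, `n =` total number of
#'   duration observations).
#' @export
fit_growth <- function(durations, series = NULL, priors = growth_priors(),
                       settings = mcmc_settings(), seed = 1L,
                       scl0 = 1.7, scl_hatch = 59.3, step_min = 60) {
  stopifnot(inherits(priors, "growth_priors"))
  df <- as.data.frame(durations)
  need <- c("mean_days", "sd_days", "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("duration table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$temp_C)) df$temp_C <- NA_real_
  if (is.null(df$series_id)) df$series_id <- NA_character_
  is_series <- !is.na(df$series_id)
  if (any(!is_series & !is.finite(df$temp_C)))
    stop("row(s) without temp_C or series_id: ",
         paste(which(!is_series & !is.finite(df$temp_C)), collapse = ", "))
  if (any(!is.finite(df$mean_days) | df$mean_days <= 0))
    stop("mean_days must be positive and finite")
  if (any(!is.finite(df$sd_days) | df$sd_days <= 0))
    stop("sd_days must be positive (needed for the Gaussian likelihood)")
  if (any(df$n < 1)) stop("n must be >= 1")
  if (any(is_series)) {
    ids <- unique(df$series_id[is_series])
    if (is.null(series) || !all(ids %in% names(series)))
      stop("series_id values without a matching temperature series: ",
           paste(setdiff(ids, names(series)), collapse = ", "))
  }
  n_ct <- length(unique(df$temp_C[!is_series]))
  n_ser <- length(unique(df$series_id[is_series]))
  if (n_ct < 3 && n_ser < 2)
    stop("need at least 3 distinct constant temperatures or 2 series")

  if (is.null(df$scl_hatch)) df$scl_hatch <- scl_hatch
  df$scl_hatch[is.na(df$scl_hatch)] <- scl_hatch
  if (any(df$scl_hatch <= scl0)) stop("scl_hatch must exceed scl0")
  target_row <- log(df$scl_hatch / scl0)
  ## pre-grid each series once
  grids <- list()
  for (id in unique(df$series_id[is_series])) {
    s <- series[[id]]
    if (!inherits(s, "temperature_series"))
      s <- temperature_series(s$time_min, s$temp_C)
    g <- time_grid(s$time_min[1], s$time_min[nrow(s)], step_min)
    grids[[id]] <- list(t = g, temp = stats::approx(s$time_min, s$temp_C, g)$y)
  }
  temps_c <- df$temp_C[!is_series]
  mean_c <- df$mean_days[!is_series]
  se_c <- df$sd_days[!is_series] / sqrt(df$n[!is_series])
  target_c <- target_row[!is_series]
  ser_rows <- which(is_series)

  predict_series_days <- function(params, gr, target) {
    r <- schoolfield_rate(params, gr$temp)
    n <- length(gr$t)
    G <- c(0, cumsum((r[-1] + r[-n]) / 2 * diff(gr$t)))
    if (G[n] >= target) {
      i <- which(G >= target)[1L]
      t <- if (i == 1L) gr$t[1L] else
        gr$t[i - 1L] + (target - G[i - 1L]) / (G[i] - G[i - 1L]) *
          (gr$t[i] - gr$t[i - 1L])
    } else {
      t <- gr$t[n] + (target - G[n]) / r[n]
    }
    t / 1440
  }

  loglik <- function(th) {
    params <- structure(list(rho25 = th[1L], dHA = th[2L], dHL = th[3L],
                             T12L = th[4L]), class = "schoolfield_params")
    out <- 0
    if (length(temps_c)) {
      r <- schoolfield_rate(params, temps_c)
      if (any(!is.finite(r)) || any(r <= 0)) return(-Inf)
      pred <- target_c / r / 1440
      out <- out + sum(stats::dnorm(mean_c, pred, se_c, log = TRUE))
    }
    for (k in ser_rows) {
      pred <- predict_series_days(params, grids[[df$series_id[k]]],
                                  target_row[k])
      if (!is.finite(pred)) return(-Inf)
      out <- out + stats::dnorm(df$mean_days[k], pred,
                                df$sd_days[k] / sqrt(df$n[k]), log = TRUE)
    }
    out
  }

  lo <- c(priors$rho25[1], priors$dHA[1], priors$dHL[1], priors$T12L[1])
  hi <- c(priors$rho25[2], priors$dHA[2], priors$dHL[2], priors$T12L[2])
  logprior <- function(th) {
    if (any(th < lo) || any(th > hi)) return(-Inf)
    0
  }

  ## data-informed start: growth rate implied by the mean duration
  t_ref <- if (length(temps_c)) stats::median(temps_c) else 29.5
  r_guess <- stats::median(target_row) / (stats::median(df$mean_days) * 1440)
  init <- c(rho25 = min(max(r_guess, lo[1] * 2), hi[1] / 2),
            dHA = 5e4, dHL = -1e5, T12L = 290)
  init <- redraw_if_needed(init, loglik, logprior, function() {
    stats::setNames(stats::runif(4, lo, hi), names(init))
  }, seed)

  scales <- (hi - lo) / 50
  names(scales) <- names(init)

  run <- run_adaptive_mwg(loglik, logprior, init, settings, seed, scales)
  structure(list(draws = run$draws, loglik = run$loglik,
                 accept = run$accept, scales = run$scales,
                 meta = list(seed = as.integer(seed), settings = settings,
                             k = 4L, n = sum(df$n),
                             n_rows = nrow(df), t_ref = t_ref,
                             scl0 = scl0, scl_hatch = scl_hatch),
                 data = df),
            class = c("growth_fit", "posterior_draws"))
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Schoolfield growth fit: %d duration groups (%g eggs), %d retained draws\n",
    x$meta$n_rows, x$meta$n, nrow(x$draws)))
  print(posterior_summary(x))
  invisible(x)
}
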