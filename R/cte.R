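#' Growth-rate-weighted constant-temperature equivalent (CTE)
#'
#' Summarises a fluctuating nest temperature series by the single constant
#' temperature with the same sexualizing effect: the time-average of
#' temperature within the thermosensitive period (TSP), weighted by the
#' instantaneous embryonic growth rate at each recorded temperature
#' ("model 6" weighting). Because the growth rate increases with
#' temperature, warm moments are up-weighted and the weighted CTE is at
#' least the plain mean for any non-constant series.
#'
#' @param params a [schoolfield_params()] object.
#' @param series a [temperature_series()].
#' @param tsp a [tsp_window()] delimiting the TSP; must overlap the series.
#' @param step_min quadrature step, minutes.
#' @return An object of class `"cte_result"`: list with `cte` (degrees C),
#'   `tsp` and `method`.
#' @seealso [cte_mean()], [cte_posterior()]
#' @export
cte_weighted <- function(params, series, tsp, step_min = 60) {
  stopifnot(inherits(params, "schoolfield_params"))
  cte_core(series, tsp, step_min,
           weight = function(tempg) schoolfield_rate(params, tempg),
           method = "weighted")
}

#' Unweighted mean temperature within the TSP
#'
#' Comparator to [cte_weighted()]: the plain time-average of the series
#' within the TSP window. The mean is known to be a poor proxy of the true
#' constant-temperature equivalent for fluctuating series.
#'
#' @inheritParams cte_weighted
#' @return An object of class `"cte_result"`.
#' @export
cte_mean <- function(series, tsp, step_min = 60) {
  cte_core(series, tsp, step_min,
           weight = function(tempg) rep(1, length(tempg)),
           method = "mean")
}

cte_core <- function(series, tsp, step_min, weight, method) {
  if (!inherits(series, "temperature_series"))
    series <- temperature_series(series$time_min, series$temp_C)
  stopifnot(inherits(tsp, "tsp_window"))
  t0 <- max(tsp$t_start, series$time_min[1])
  t1 <- min(tsp$t_end, series$time_min[nrow(series)])
  if (!(t1 > t0))
    stop(errorCondition("TSP window does not overlap the temperature series",
                        class = c("tsdnorm_empty_tsp", "error", "condition")))
  grid <- time_grid(t0, t1, step_min)
  tempg <- stats::approx(series$time_min, series$temp_C, grid)$y
  w <- weight(tempg)
  num <- trapz(grid, tempg * w)
  den <- trapz(grid, w)
  structure(list(cte = num / den, tsp = tsp, method = method),
            class = "cte_result")
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' @export
print.cte_result <- function(x, ...) {
  cat(sprintf("CTE|TSP (%s): %.3f degC\n", x$method, x$cte))
  invisible(x)
}

#' Posterior distribution of the CTE for one nest
#'
#' Propagates posterior uncertainty in the growth reaction norm into the
#' CTE: for each retained draw of Schoolfield parameters the embryo
#' trajectory is re-integrated, the TSP re-delineated (the timing of the
#' window shifts with the growth parameters), and the weighted CTE
#' recomputed. The reported point estimate is the posterior median; for
#' near-constant tropical nest series the credible interval is typically
#' very narrow.
#'
#' @param draws a `growth_fit` (see [fit_growth()]) or a numeric matrix of
#'   draws with columns `rho25`, `dHA`, `dHL`, `T12L`.
#' @param series a [temperature_series()].
#' @param scl0,scl_hatch,step_min passed to [integrate_trajectory()].
#' @param stage_fracs passed to [tsp_window()].
#' @param probs credible-interval probabilities.
#' @return List with per-draw `cte` values, `median`, `ci` and the number of
#'   draws whose embryo failed to hatch within the series (`n_failed`,
#'   dropped from the summaries).
#' @export
cte_posterior <- function(draws, series, scl0 = 1.7, scl_hatch = 59.3,
                          stage_fracs = c(1 / 3, 2 / 3), step_min = 60,
                          probs = c(0.025, 0.975)) {
  m <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  need <- c("rho25", "dHA", "dHL", "T12L")
  if (!all(need %in% colnames(m)))
    stop("draws must have columns ", paste(need, collapse = ", "))
  vals <- apply(m[, need, drop = FALSE], 1, function(th) {
    p <- schoolfield_params(th[["rho25"]], th[["dHA"]], th[["dHL"]], th[["T12L"]])
    tryCatch({
      traj <- integrate_trajectory(p, series, scl0, scl_hatch, step_min)
      tsp <- tsp_window(traj, stage_fracs)
      cte_weighted(p, series, tsp, step_min)$cte
    }, tsdnorm_no_hatch = function(e) NA_real_)
  })
  ok <- vals[!is.na(vals)]
  if (!length(ok)) stop("no posterior draw produced a hatching embryo")
  list(cte = vals, median = stats::median(ok),
       ci = stats::quantile(ok, probs, names = FALSE),
       n_failed = sum(is.na(vals)))
}

#' CTE summary table for a set of nests
#'
#' Applies [cte_posterior()] to each nest and returns one row per nest with
#' the series mean temperature within the (median-parameter) TSP, the
#' posterior median CTE, its credible interval, and the nest's sex counts.
#'
#' @param nests a named list; each element a list with `series`
#'   (a [temperature_series()]), `males`, `females`.
#' @param draws as in [cte_posterior()].
#' @inheritParams cte_posterior
#' @return A data frame with columns `nest_id`, `mean_tempC`, `median_cte`,
#'   `ci95_low`, `ci95_high`, `males`, `females`.
#' @export
cte_table <- function(nests, draws, scl0 = 1.7, scl_hatch = 57.3,
                      stage_fracs = c(1 / 3, 2 / 3), step_min = 60) {
  stopifnot(is.list(nests), length(nests) >= 1L, !is.null(names(nests)))
  rows <- lapply(names(nests), function(id) {
    nest <- nests[[id]]
    post <- cte_posterior(draws, nest$series, scl0, scl_hatch, stage_fracs,
                          step_min)
    m <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
    med <- apply(m[, c("rho25", "dHA", "dHL", "T12L"), drop = FALSE], 2,
                 stats::median)
    p_med <- schoolfield_params(med[["rho25"]], med[["dHA"]], med[["dHL"]],
                                med[["T12L"]])
    mean_t <- tryCatch({
      traj <- integrate_trajectory(p_med, nest$series, scl0, scl_hatch, step_min)
      tsp <- tsp_window(traj, stage_fracs)
      cte_mean(nest$series, tsp, step_min)$cte
    }, tsdnorm_no_hatch = function(e) NA_real_)
    data.frame(nest_id = id, mean_tempC = mean_t, median_cte = post$median,
               ci95_low = post$ci[1], ci95_high = post$ci[2],
               males = nest$males, females = nest$females)
  })
  do.call(rbind, rows)
}
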