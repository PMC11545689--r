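#' Parameters of the 4-parameter Schoolfield growth reaction norm
#'
#' Thermal reaction norm of the instantaneous embryonic growth rate
#' `r(T)` (per minute), in the low-temperature-inhibition form:
#' \deqn{r(T) = \rho_{25} \frac{T_K}{298.15}
#'   \frac{\exp[(\Delta H_A / R)(1/298.15 - 1/T_K)]}
#'        {1 + \exp[(\Delta H_L / R)(1/T_{1/2L} - 1/T_K)]}}
#' with `T_K = T + 273.15` K and `R = 8.314` J/mol/K.
#'
#' @param rho25 growth rate at the 25 degrees C reference temperature,
#'   per minute; positive.
#' @param dHA activation-enthalpy-like parameter, J/mol.
#' @param dHL low-temperature-inhibition enthalpy-like parameter, J/mol
#'   (negative for inhibition at low temperature).
#' @param T12L low-temperature half-inhibition temperature, Kelvin; must lie
#'   in (270, 310).
#' @return An object of class `"schoolfield_params"`.
#' @seealso [schoolfield_rate()], [integrate_trajectory()]
#' @export
schoolfield_params <- function(rho25, dHA, dHL, T12L) {
  if (!is.numeric(rho25) || length(rho25) != 1L || !is.finite(rho25) || rho25 <= 0)
    stop("'rho25' must be a single positive number (rate per minute)")
  for (nm in c("dHA", "dHL")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number (J/mol)", nm))
  }
  if (!is.numeric(T12L) || length(T12L) != 1L || !is.finite(T12L) ||
      T12L <= 270 || T12L >= 310)
    stop("'T12L' must lie in (270, 310) K")
  structure(list(rho25 = rho25, dHA = dHA, dHL = dHL, T12L = T12L),
            class = "schoolfield_params")
}

#' @export
print.schoolfield_params <- function(x, ...) {
  cat(sprintf(
    "Schoolfield growth norm: rho25 = %.3g /min, dHA = %.4g, dHL = %.4g J/mol, T12L = %.2f K\n",
    x$rho25, x$dHA, x$dHL, x$T12L))
  invisible(x)
}

GAS_CONSTANT <- 8.314
KELVIN0 <- 273.15
TREF_K <- 298.15

#' Instantaneous embryonic growth rate at a temperature
#'
#' Evaluates the Schoolfield reaction norm (see [schoolfield_params()]) at
#' one or more temperatures in degrees Celsius. Always positive.
#'
#' @param params a [schoolfield_params()] object.
#' @param temp_C temperature(s), degrees C; vectorised.
#' @return Growth rate(s), per minute.
#' @export
schoolfield_rate <- function(params, temp_C) {
  stopifnot(inherits(params, "schoolfield_params"))
  TK <- temp_C + KELVIN0
  num <- params$rho25 * (TK / TREF_K) *
    exp((params$dHA / GAS_CONSTANT) * (1 / TREF_K - 1 / TK))
  den <- 1 + exp((params$dHL / GAS_CONSTANT) * (1 / params$T12L - 1 / TK))
  num / den
}

#' Nest temperature time series
#'
#' @param time_min times in minutes since the start of incubation; strictly
#'   increasing, at least two points.
#' @param temp_C temperatures in degrees C, same length; must lie in
#'   \[15, 45\].
#' @return A data frame of class `"temperature_series"`.
#' @export
temperature_series <- function(time_min, temp_C) {
  if (length(time_min) < 2L || length(time_min) != length(temp_C))
    stop("need at least two (time, temperature) points of equal length")
  if (any(!is.finite(time_min)) || any(diff(time_min) <= 0))
    stop("'time_min' must be finite and strictly increasing")
  if (any(!is.finite(temp_C)) || any(temp_C < 15) || any(temp_C > 45))
    stop("'temp_C' must be finite and within [15, 45] degrees C")
  structure(data.frame(time_min = as.numeric(time_min),
                       temp_C = as.numeric(temp_C)),
            class = c("temperature_series", "data.frame"))
}

## fixed-step grid over [t0, t1] including both endpoints
time_grid <- function(t0, t1, step_min) {
  g <- seq(t0, t1, by = step_min)
  if (g[length(g)] < t1) g <- c(g, t1)
  g
}

#' Integrate embryo growth over a temperature series
#'
#' Integrates exponential growth in straight carapace length (SCL),
#' `dSCL/dt = r(T(t)) * SCL`, with `T(t)` piecewise-linear between the
#' recorded points, using a fixed-step trapezoidal update on log-SCL
#' (default step 60 min). Integration stops when the hatchling size
#' `scl_hatch` is reached.
#'
#' @param params a [schoolfield_params()] object.
#' @param series a [temperature_series()].
#' @param scl0 initial embryo SCL, mm (default 1.7).
#' @param scl_hatch hatchling SCL, mm; must exceed `scl0`. Default 59.3
#'   (pooled Northwest Atlantic leatherback mean).
#' @param step_min integration step, minutes.
#' @return An object of class `"growth_trajectory"`: list with `times`
#'   (minutes), `scl` (mm, non-decreasing, ends at `scl_hatch`),
#'   `log_growth` (integrated log-size increase at `times`), `scl0`,
#'   `scl_hatch` and `t_hatch_min`.
#' @section Errors: if the series ends before the embryo reaches
#'   `scl_hatch`, an error of class `"tsdnorm_no_hatch"` is signalled whose
#'   condition carries the attained SCL in `$attained_scl`.
#' @export
integrate_trajectory <- function(params, series, scl0 = 1.7, scl_hatch = 59.3,
                                 step_min = 60) {
  stopifnot(inherits(params, "schoolfield_params"))
  if (!inherits(series, "temperature_series"))
    series <- temperature_series(series$time_min, series$temp_C)
  if (!is.finite(scl0) || !is.finite(scl_hatch) || scl0 <= 0 || scl0 >= scl_hatch)
    stop("need 0 < scl0 < scl_hatch")
  grid <- time_grid(series$time_min[1], series$time_min[nrow(series)], step_min)
  tempg <- stats::approx(series$time_min, series$temp_C, grid)$y
  r <- schoolfield_rate(params, tempg)
  n <- length(grid)
  G <- c(0, cumsum((r[-1] + r[-n]) / 2 * diff(grid)))
  target <- log(scl_hatch / scl0)
  if (G[n] < target) {
    att <- scl0 * exp(G[n])
    stop(errorCondition(
      sprintf("embryo did not hatch within the series (attained SCL %.2f mm of %.2f mm)",
              att, scl_hatch),
      attained_scl = att,
      class = c("tsdnorm_no_hatch", "error", "condition")))
  }
  i <- which(G >= target)[1L]
  t_hatch <- if (i == 1L) grid[1L] else
    grid[i - 1L] + (target - G[i - 1L]) / (G[i] - G[i - 1L]) *
      (grid[i] - grid[i - 1L])
  keep <- seq_len(i - 1L)
  times <- c(grid[keep], t_hatch)
  logg <- c(G[keep], target)
  structure(list(times = times, scl = scl0 * exp(logg), log_growth = logg,
                 scl0 = scl0, scl_hatch = scl_hatch, t_hatch_min = t_hatch),
            class = "growth_trajectory")
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf("Embryo growth trajectory: %.1f -> %.1f mm in %.1f days\n",
              x$scl0, x$scl_hatch, x$t_hatch_min / 1440))
  invisible(x)
}

#' Predicted incubation duration
#'
#' Wrapper over [integrate_trajectory()] returning the time (days) needed to
#' grow from `scl0` to `scl_hatch`. `x` may be a [temperature_series()] or a
#' single constant temperature, in which case a constant series of generous
#' length is built internally.
#'
#' @inheritParams integrate_trajectory
#' @param x a [temperature_series()] or a single temperature in degrees C.
#' @return Duration in days.
#' @export
predict_duration <- function(params, x, scl0 = 1.7, scl_hatch = 59.3,
                             step_min = 60) {
  if (is.numeric(x) && length(x) == 1L) {
    r <- schoolfield_rate(params, x)
    if (!is.finite(r) || r <= 0)
      stop(errorCondition("growth rate is not positive at this temperature",
                          attained_scl = scl0,
                          class = c("tsdnorm_no_hatch", "error", "condition")))
    span <- 2 * log(scl_hatch / scl0) / r
    x <- temperature_series(c(0, span), c(x, x))
  }
  traj <- integrate_trajectory(params, x, scl0 = scl0, scl_hatch = scl_hatch,
                               step_min = step_min)
  traj$t_hatch_min / 1440
}

#' Thermosensitive period (TSP) window of a growth trajectory
#'
#' Delineates the developmental window during which sex is sensitive to
#' temperature (embryonic stages 23 to 27 in leatherbacks) as the times at
#' which the embryo first crosses two SCL thresholds expressed as fractions
#' of hatchling size. The stage-to-SCL mapping is taken from an external
#' staging table; the defaults (1/3, 2/3) are placeholder fractions and
#' should be overridden when better stage landmarks are available.
#'
#' @param traj a [integrate_trajectory()] result.
#' @param stage_fracs fractions of `scl_hatch` delimiting the start and end
#'   stages, `0 < f1 < f2 <= 1`.
#' @return An object of class `"tsp_window"`: list with `t_start`, `t_end`
#'   (minutes) and `scl_start`, `scl_end` (mm).
#' @export
tsp_window <- function(traj, stage_fracs = c(1 / 3, 2 / 3)) {
  stopifnot(inherits(traj, "growth_trajectory"))
  f <- stage_fracs
  if (length(f) != 2L || any(!is.finite(f)) || f[1] <= 0 || f[1] >= f[2] || f[2] > 1)
    stop("'stage_fracs' must satisfy 0 < f1 < f2 <= 1")
  targets <- log(f * traj$scl_hatch / traj$scl0)
  if (any(targets < 0))
    stop("stage threshold lies below the initial embryo size")
  if (any(targets > traj$log_growth[length(traj$log_growth)] + 1e-12))
    stop("trajectory does not cross the stage SCL threshold")
  tt <- stats::approx(traj$log_growth, traj$times, xout = targets, ties = "ordered")$y
  structure(list(t_start = tt[1], t_end = tt[2],
                 scl_start = f[1] * traj$scl_hatch,
                 scl_end = f[2] * traj$scl_hatch),
            class = "tsp_window")
}

#' @export
print.tsp_window <- function(x, ...) {
  cat(sprintf("TSP window: day %.1f to %.1f (SCL %.1f to %.1f mm)\n",
              x$t_start / 1440, x$t_end / 1440, x$scl_start, x$scl_end))
  invisible(x)
}
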