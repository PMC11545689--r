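#' Default flexit* parameters for simulation
#'
#' The leatherback-like TSD curve used as the generator truth throughout
#' the package: pivotal temperature 29.49 degrees C, limb slopes 2.34
#' (lower) and 2.83 (upper), giving a TRT95 of about 0.6 degrees C — the
#' thinnest among sea turtles.
#'
#' @return A [flexit_params()] object.
#' @export
default_flexit_params <- function() flexit_params(P = 29.49, S = 2.34, dS = 0.49)

#' Default Schoolfield growth parameters for simulation
#'
#' A leatherback-like thermal reaction norm of embryonic growth: about 60
#' days of incubation at 29.5 degrees C (SCL 1.7 -> 59.3 mm), rate strictly
#' increasing over 25-35 degrees C, roughly 75 days at 27 degrees C and 53
#' at 31 degrees C.
#'
#' @return A [schoolfield_params()] object.
#' @export
default_growth_params <- function()
  schoolfield_params(rho25 = 4.63e-5, dHA = 3.5e4, dHL = -1e5, T12L = 296)

#' Configuration of the synthetic sex-count generator
#'
#' Describes a nested sampling design (RMUs containing studies containing
#' clutches of eggs), the true flexit* curve, per-level random-effect SDs
#' on each curve parameter, and the temperatures at which clutches are
#' incubated.
#'
#' @param params true [flexit_params()].
#' @param n_rmu number of regional management units.
#' @param ids_per_rmu studies per RMU.
#' @param clutches_per_id clutches per study.
#' @param eggs_per_clutch sexed eggs per clutch.
#' @param temps vector of incubation temperatures, recycled across clutches
#'   in order.
#' @param re_sd named list with elements `rmu`, `id`, `clutch`, each a
#'   named numeric vector `c(P=, S=, dS=)` of random-effect SDs (defaults
#'   all zero).
#' @param seed integer seed recorded in the output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(params = default_flexit_params(), n_rmu = 1L,
                       ids_per_rmu = 1L, clutches_per_id = 1L,
                       eggs_per_clutch = 10L,
                       temps = seq(27, 32, by = 0.5),
                       re_sd = list(), seed = 1L) {
  stopifnot(inherits(params, "flexit_params"),
            n_rmu >= 1, ids_per_rmu >= 1, clutches_per_id >= 1,
            eggs_per_clutch >= 1, length(temps) >= 1, all(is.finite(temps)))
  zero <- c(P = 0, S = 0, dS = 0)
  sdl <- list(rmu = zero, id = zero, clutch = zero)
  for (lv in names(re_sd)) {
    stopifnot(lv %in% names(sdl))
    v <- re_sd[[lv]]
    sdl[[lv]][names(v)] <- v
    stopifnot(all(sdl[[lv]] >= 0))
  }
  structure(list(params = params, n_rmu = as.integer(n_rmu),
                 ids_per_rmu = as.integer(ids_per_rmu),
                 clutches_per_id = as.integer(clutches_per_id),
                 eggs_per_clutch = as.integer(eggs_per_clutch),
                 temps = temps, re_sd = sdl, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate synthetic clutch-level sex counts
#'
#' Generative twin of the hierarchical flexit* model: each RMU, study and
#' clutch receives independent Gaussian deviations on `P`, `S` and `dS`
#' (scaled by the configured SDs); each clutch's female count is then a
#' binomial draw at its assigned temperature. Labels carry the full
#' RMU/study/clutch nesting. Pure function of the configuration (the seed
#' is part of the configuration).
#'
#' @param cfg a [sim_config()] object.
#' @return A `"sexcounts"` data frame (one row per clutch) with attribute
#'   `"sim_seed"`.
#' @export
gen_sexcounts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p0 <- cfg$params
  rows <- list()
  ci <- 0L
  for (r in seq_len(cfg$n_rmu)) {
    dev_r <- stats::rnorm(3, 0, cfg$re_sd$rmu)
    for (i in seq_len(cfg$ids_per_rmu)) {
      dev_i <- stats::rnorm(3, 0, cfg$re_sd$id)
      for (cl in seq_len(cfg$clutches_per_id)) {
        dev_c <- stats::rnorm(3, 0, cfg$re_sd$clutch)
        ci <- ci + 1L
        th <- c(p0$P, p0$S, p0$dS) + dev_r + dev_i + dev_c
        S_eff <- max(th[2], 0.01)
        dS_eff <- max(th[3], -S_eff + 0.01)
        pc <- flexit_params(th[1], S_eff, dS_eff, p0$l)
        tc <- cfg$temps[((ci - 1L) %% length(cfg$temps)) + 1L]
        pf <- sex_ratio(pc, tc)
        f <- stats::rbinom(1, cfg$eggs_per_clutch, pf)
        rows[[ci]] <- data.frame(
          temperature_C = tc, males = cfg$eggs_per_clutch - f, females = f,
          intersex = 0,
          rmu = sprintf("RMU%02d", r),
          study_id = sprintf("S%02d.%02d", r, i),
          clutch = sprintf("C%02d.%02d.%02d", r, i, cl))
      }
    }
  }
  out <- as_sexcounts(do.call(rbind, rows))
  attr(out, "sim_seed") <- cfg$seed
  out
}

#' Generate a synthetic nest temperature series
#'
#' Emulates tropical incubation-box records: a mean level plus a small
#' sinusoidal day-night (nychthemeral) cycle, a smooth linear drift, and
#' Gaussian measurement jitter, sampled at a fixed cadence (default one
#' record per day, as in the historical Malaysian series).
#'
#' @param days length of the series, days.
#' @param mean_C mean temperature, degrees C.
#' @param amplitude half-amplitude of the daily cycle, degrees C.
#' @param drift total linear temperature change over the series, degrees C.
#' @param jitter_sd SD of additive Gaussian noise, degrees C.
#' @param interval_min sampling interval, minutes (default 1440 = daily).
#' @param seed integer seed.
#' @return A [temperature_series()].
#' @export
gen_temperature_series <- function(days = 70, mean_C = 29.5, amplitude = 0.2,
                                   drift = 0, jitter_sd = 0.05,
                                   interval_min = 1440, seed = 1L) {
  stopifnot(days > 0, amplitude >= 0, jitter_sd >= 0, interval_min > 0)
  set.seed(as.integer(seed))
  t <- seq(0, days * 1440, by = interval_min)
  temp <- mean_C + amplitude * sin(2 * pi * t / 1440) +
    drift * (t / max(t)) + stats::rnorm(length(t), 0, jitter_sd)
  temperature_series(t, pmin(pmax(temp, 15), 45))
}

#' Generate incubation-duration summaries
#'
#' For each constant temperature (or temperature series), predicts the
#' deterministic incubation duration under a growth reaction norm and draws
#' `n` durations with Gaussian noise, returning per-group summaries
#' suitable for [fit_growth()].
#'
#' @param x numeric vector of constant temperatures, or a named list of
#'   [temperature_series()].
#' @param params a [schoolfield_params()] object.
#' @param sd_days SD of the Gaussian duration noise (recycled per group).
#' @param n number of eggs per group (recycled).
#' @param seed integer seed.
#' @param scl0,scl_hatch,step_min passed to [predict_duration()].
#' @return Data frame with columns `temp_C`, `series_id`, `mean_days`,
#'   `sd_days` (observed; the nominal value if `sd_days = 0` or `n = 1`),
#'   `n`.
#' @export
gen_durations <- function(x, params, sd_days = 2, n = 20, seed = 1L,
                          scl0 = 1.7, scl_hatch = 59.3, step_min = 60) {
  stopifnot(inherits(params, "schoolfield_params"), all(n >= 1))
  set.seed(as.integer(seed))
  if (is.numeric(x)) {
    groups <- lapply(x, identity)
    ids <- rep(NA_character_, length(x))
    temps <- x
  } else {
    stopifnot(is.list(x), !is.null(names(x)))
    groups <- x
    ids <- names(x)
    temps <- rep(NA_real_, length(x))
  }
  sd_days <- rep_len(sd_days, length(groups))
  n <- rep_len(as.integer(n), length(groups))
  rows <- lapply(seq_along(groups), function(j) {
    mu <- predict_duration(params, groups[[j]], scl0 = scl0,
                           scl_hatch = scl_hatch, step_min = step_min)
    d <- mu + stats::rnorm(n[j], 0, sd_days[j])
    obs_sd <- if (n[j] > 1 && sd_days[j] > 0) stats::sd(d) else
      max(sd_days[j], 1e-6)
    data.frame(temp_C = temps[j], series_id = ids[j],
               mean_days = mean(d), sd_days = obs_sd, n = n[j])
  })
  do.call(rbind, rows)
}

#' Estimate a standard deviation from a sample range
#'
#' Two conventions used when literature reports only a range:
#' `"z196"` treats the range as a 95% interval, `SD = range / (2 * 1.96)`;
#' `"expected_range"` divides by the expected range of `n` standard normal
#' observations, estimated by seeded Monte-Carlo simulation (the global RNG
#' state is preserved).
#'
#' @param range_width observed maximum minus minimum (positive).
#' @param n sample size (required for `"expected_range"`, >= 2).
#' @param method `"z196"` or `"expected_range"`.
#' @param reps Monte-Carlo replicates for `"expected_range"`.
#' @param seed Monte-Carlo seed.
#' @return The SD estimate.
#' @examples
#' sd_from_range(3.92)                                  # 1.0
#' sd_from_range(13.8, n = 200, method = "expected_range")
#' @export
sd_from_range <- function(range_width, n = NULL,
                          method = c("z196", "expected_range"),
                          reps = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.numeric(range_width), range_width > 0)
  if (method == "z196") return(range_width / (2 * 1.96))
  if (is.null(n) || n < 2) stop("'expected_range' needs n >= 2")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  m <- matrix(stats::rnorm(reps * n), nrow = n)
  er <- mean(apply(m, 2, function(z) max(z) - min(z)))
  range_width / er
}

#' Probability of observing a single sex in a clutch
#'
#' If the minority sex is produced with probability `p_minor`, the
#' probability that none of `n_eggs` sexed eggs is of that sex is
#' `(1 - p_minor)^n_eggs`. With small clutches this probability is large,
#' which is why the limits of the transitional range of temperatures are
#' hard to establish: e.g. 10 eggs at a temperature producing 10% males
#' fail to show any male about a third of the time.
#'
#' @param p_minor probability of the minority sex, in \[0, 1\].
#' @param n_eggs number of sexed eggs, >= 1.
#' @return Probability the minority sex is unobserved; vectorised.
#' @examples
#' prob_all_one_sex(0.1, 10)    # ~0.349
#' prob_all_one_sex(0.1, 100)   # ~2.7e-5
#' @export
prob_all_one_sex <- function(p_minor, n_eggs) {
  stopifnot(all(p_minor >= 0), all(p_minor <= 1), all(n_eggs >= 1))
  (1 - p_minor)^n_eggs
}
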