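#' Read and write sex-count CSV files
#'
#' The sex-count dialect is comma-separated with a mandatory header and
#' columns `temperature_C, males, females, intersex, rmu, study_id,
#' clutch` (decimal point, UTF-8; `clutch` may be empty). Errors name the
#' offending column or row.
#'
#' @param path CSV file path.
#' @param intersex rule passed to [as_sexcounts()].
#' @return [read_sexcounts()] returns a `"sexcounts"` data frame.
#' @export
read_sexcounts <- function(path, intersex = "exclude") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (lab in intersect(c("rmu", "study_id", "clutch"), names(df))) {
    df[[lab]] <- as.character(df[[lab]])
    df[[lab]][is.na(df[[lab]])] <- ""
  }
  as_sexcounts(df, intersex = intersex)
}

#' @rdname read_sexcounts
#' @param x a `"sexcounts"` data frame (or coercible).
#' @export
write_sexcounts <- function(x, path) {
  df <- as.data.frame(as_sexcounts(x))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write temperature-series CSV files
#'
#' Columns `time_min, temp_C` with a mandatory header.
#'
#' @param path CSV file path.
#' @return [read_temperature_series()] returns a [temperature_series()].
#' @export
read_temperature_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_min", "temp_C")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("temperature-series file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  temperature_series(df$time_min, df$temp_C)
}

#' @rdname read_temperature_series
#' @param x a [temperature_series()].
#' @export
write_temperature_series <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x))[c("time_min", "temp_C")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read and write incubation-duration summary CSV files
#'
#' Columns `temp_C, series_id, mean_days, sd_days, n` (either of the first
#' two may be empty per row), as consumed by [fit_growth()].
#'
#' @param path CSV file path.
#' @return [read_duration_summaries()] returns a data frame.
#' @export
read_duration_summaries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mean_days", "sd_days", "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("duration-summary file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$temp_C)) df$temp_C <- NA_real_
  if (is.null(df$series_id)) df$series_id <- NA_character_
  df$series_id[df$series_id %in% ""] <- NA_character_
  df
}

#' @rdname read_duration_summaries
#' @param x a duration-summary data frame.
#' @export
write_duration_summaries <- function(x, path) {
  cols <- c("temp_C", "series_id", "mean_days", "sd_days", "n")
  df <- as.data.frame(x)
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
  utils::write.csv(df[cols], path, row.names = FALSE)
  invisible(path)
}

#' Write posterior draws with a JSON metadata sidecar
#'
#' The draws go to CSV (one column per parameter, one row per retained
#' draw, plus a `loglik` column); the seed, MCMC settings and model
#' structure go to `<path>.json`.
#'
#' @param fit a `posterior_draws` object.
#' @param path CSV output path.
#' @return Invisibly, the two file paths.
#' @export
write_posterior <- function(fit, path) {
  stopifnot(inherits(fit, "posterior_draws"))
  df <- as.data.frame(fit$draws)
  df$loglik <- fit$loglik
  utils::write.csv(df, path, row.names = FALSE)
  meta <- fit$meta
  meta$settings <- unclass(meta$settings)
  meta$priors <- NULL
  side <- paste0(path, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML configuration for the command-line pipeline and fills in
#' defaults: MCMC settings (`burnin`, `iter`, `thin`, `seed`), random-effect
#' structure `re`, TRT tail `l`, TSP stage fractions, initial and hatchling
#' SCL, and intersex rule. Unknown keys are an error, so typos fail before
#' any computation.
#'
#' @param path YAML file path, or a list with the same fields.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(burnin = 1000L, iter = 10000L, thin = 10L, seed = 1L,
                   re = "1", l = 0.05, stage_fracs = c(1 / 3, 2 / 3),
                   scl0 = 1.7, scl_hatch = 59.3, step_min = 60,
                   intersex = "exclude", sexcounts = NULL, durations = NULL,
                   series_dir = NULL, out_dir = ".")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  stopifnot(cfg$l > 0, cfg$l < 0.5, length(cfg$stage_fracs) == 2L,
            cfg$scl0 > 0, cfg$scl_hatch > cfg$scl0)
  cfg$re <- gsub(" ", "", cfg$re)
  parse_re(cfg$re)
  structure(cfg, class = "run_config")
}

#' Pipeline steps
#'
#' Thin programmatic equivalents of the command-line subcommands; each
#' reads CSV/YAML inputs, calls the corresponding model function and writes
#' CSV/JSON artifacts into `config$out_dir`. A wrapper script suitable for
#' `Rscript` lives in `system.file("scripts", "tsdnorm-cli.R", package =
#' "tsdnorm")`.
#'
#' @param config a [run_config()] (or YAML path / list coercible to one).
#' @return Invisibly, the paths of the written artifacts.
#' @name pipeline
NULL

#' @rdname pipeline
#' @param sim a [sim_config()]; defaults to a no-random-effect design at
#'   the configured seed.
#' @export
pipeline_simulate <- function(config, sim = NULL) {
  cfg <- run_config(config)
  if (is.null(sim))
    sim <- sim_config(clutches_per_id = 20L, eggs_per_clutch = 10L,
                      seed = cfg$seed)
  counts <- gen_sexcounts(sim)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- file.path(cfg$out_dir, "simulated_sexcounts.csv")
  write_sexcounts(counts, out)
  invisible(out)
}

#' @rdname pipeline
#' @export
pipeline_fit_tsd <- function(config) {
  cfg <- run_config(config)
  if (is.null(cfg$sexcounts)) stop("configuration field 'sexcounts' is required")
  counts <- read_sexcounts(cfg$sexcounts, intersex = cfg$intersex)
  fit <- fit_tsd(counts, re = cfg$re,
                 settings = mcmc_settings(cfg$burnin, cfg$iter, cfg$thin),
                 seed = cfg$seed)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  draws_csv <- file.path(cfg$out_dir, "tsd_posterior.csv")
  write_posterior(fit, draws_csv)
  summ <- posterior_summary(fit, c("P", "S", "dS"))
  summ_csv <- file.path(cfg$out_dir, "tsd_summary.csv")
  utils::write.csv(summ, summ_csv, row.names = FALSE)
  invisible(c(draws_csv, summ_csv))
}

#' @rdname pipeline
#' @export
pipeline_fit_growth <- function(config) {
  cfg <- run_config(config)
  if (is.null(cfg$durations)) stop("configuration field 'durations' is required")
  dur <- read_duration_summaries(cfg$durations)
  series <- NULL
  ids <- unique(dur$series_id[!is.na(dur$series_id)])
  if (length(ids)) {
    if (is.null(cfg$series_dir))
      stop("duration rows reference series but 'series_dir' is not set")
    series <- lapply(ids, function(id)
      read_temperature_series(file.path(cfg$series_dir, paste0(id, ".csv"))))
    names(series) <- ids
  }
  fit <- fit_growth(dur, series = series,
                    settings = mcmc_settings(cfg$burnin, cfg$iter, cfg$thin),
                    seed = cfg$seed, scl0 = cfg$scl0,
                    scl_hatch = cfg$scl_hatch, step_min = cfg$step_min)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  draws_csv <- file.path(cfg$out_dir, "growth_posterior.csv")
  write_posterior(fit, draws_csv)
  invisible(draws_csv)
}

#' @rdname pipeline
#' @param growth_draws path of a posterior CSV written by
#'   [pipeline_fit_growth()].
#' @param nests named list as in [cte_table()].
#' @export
pipeline_compute_cte <- function(config, growth_draws, nests) {
  cfg <- run_config(config)
  d <- utils::read.csv(growth_draws)
  tab <- cte_table(nests, as.matrix(d[c("rho25", "dHA", "dHL", "T12L")]),
                   scl0 = cfg$scl0, scl_hatch = cfg$scl_hatch,
                   stage_fracs = cfg$stage_fracs, step_min = cfg$step_min)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- file.path(cfg$out_dir, "cte_table.csv")
  utils::write.csv(tab, out, row.names = FALSE)
  invisible(out)
}

#' @rdname pipeline
#' @param fits named list of `posterior_draws` fits of the same data.
#' @param n shared sample size for AICc.
#' @export
pipeline_compare <- function(config, fits, n) {
  cfg <- run_config(config)
  scores <- posterior_model_weights(fits, n)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- file.path(cfg$out_dir, "model_comparison.csv")
  utils::write.csv(as.data.frame(scores), out, row.names = FALSE)
  invisible(out)
}
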