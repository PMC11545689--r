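#' East Pacific constant-temperature sex counts
#'
#' Published male/female counts of leatherback hatchlings incubated at nine
#' constant temperatures at Playa Grande, Costa Rica (East Pacific RMU).
#' The 33 degrees C condition yielded no sexed individuals and is dropped
#' unless `keep_empty = TRUE`.
#'
#' @param keep_empty keep the empty 33 degrees C row.
#' @return A `"sexcounts"` data frame.
#' @export
east_pacific_counts <- function(keep_empty = FALSE) {
  df <- data.frame(
    temperature_C = c(28, 29, 29.5, 30, 30.5, 31, 31.5, 32, 33),
    males = c(17, 9, 4, 1, 0, 0, 0, 0, 0),
    females = c(0, 1, 6, 15, 10, 12, 8, 19, 0),
    intersex = 0,
    rmu = "EastPacific",
    study_id = "PlayaGrande",
    clutch = "")
  if (!keep_empty) df <- df[df$males + df$females > 0, , drop = FALSE]
  as_sexcounts(df)
}

#' Malaysian nests: CTE within the TSP and sex counts
#'
#' The four historical Malaysian leatherback nests (West Pacific RMU)
#' incubated at fluctuating temperatures, with the published series mean
#' (+/- SE) within the TSP, the posterior median growth-weighted CTE within
#' the TSP and its 95% credible limits, and the sexed hatchling counts.
#'
#' @return A data frame, one row per nest.
#' @export
malaysia_nests <- function() {
  data.frame(
    nest_id = c("1C", "3C", "4C", "Oven"),
    mean_tempC = c(27.04, 29.21, 28.95, 30.42),
    se_tempC = c(0.58, 1.01, 1.34, 0.80),
    median_cte = c(27.31, 28.90, 28.63, 30.43),
    ci95_low = c(27.30, 28.89, 28.62, 30.43),
    ci95_high = c(27.31, 28.91, 28.64, 30.43),
    males = c(11, 9, 9, 0),
    females = c(0, 0, 0, 5))
}

#' Malaysian nests as sex-count records at their median CTE
#'
#' Each fluctuating-temperature nest is represented by a single record
#' placed at its posterior-median growth-weighted CTE within the TSP (the
#' one-temperature-per-record convention used for fitting).
#'
#' @return A `"sexcounts"` data frame.
#' @export
malaysia_counts <- function() {
  nests <- malaysia_nests()
  as_sexcounts(data.frame(
    temperature_C = nests$median_cte,
    males = nests$males,
    females = nests$females,
    intersex = 0,
    rmu = "WestPacific",
    study_id = "Rantau Abang",
    clutch = nests$nest_id))
}

#' All printed sex-count records pooled
#'
#' The East Pacific constant-temperature table pooled with the four
#' Malaysian nests at their median CTEs: 13 records, 136 sexed eggs.
#'
#' @return A `"sexcounts"` data frame.
#' @export
pooled_counts <- function() {
  as_sexcounts(rbind(as.data.frame(east_pacific_counts()),
                     as.data.frame(malaysia_counts())))
}

#' Write the packaged datasets as CSV fixtures
#'
#' Emits the sex-count CSV dialect used by [read_sexcounts()] for the East
#' Pacific table, the Malaysian CTE records and the pooled table.
#'
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_fixture_datasets <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(eastpacific = file.path(dir, "eastpacific_sexcounts.csv"),
             malaysia = file.path(dir, "malaysia_cte_sexcounts.csv"),
             pooled = file.path(dir, "pooled_sexcounts.csv"))
  write_sexcounts(east_pacific_counts(), files[["eastpacific"]])
  write_sexcounts(malaysia_counts(), files[["malaysia"]])
  write_sexcounts(pooled_counts(), files[["pooled"]])
  invisible(files)
}
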