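#' Parameters of the asymmetric flexit* sex-ratio curve
#'
#' The flexit* model describes the proportion of females produced at a
#' constant incubation temperature `T` as a logistic curve with pivotal
#' temperature `P` (where the sex ratio is exactly 1:1) and two limb slopes:
#' `S1 = S` governs the curve below `P` and `S2 = S + dS` above `P`. The two
#' limbs are blended by a quasi-binary threshold ([qbt()]), so the curve is
#' smooth but switches slope essentially instantaneously across `P`. With
#' `dS = 0` the model reduces to the plain symmetric logistic.
#'
#' @param P pivotal temperature, degrees C.
#' @param S lower-limb slope parameter (per degree C, on the 4S logit scale);
#'   must be positive.
#' @param dS slope increment so the upper-limb slope is `S + dS`; `S + dS`
#'   must be positive. Default 0 (symmetric curve).
#' @param l tail sex ratio defining the transitional range of temperatures
#'   (TRT) between sex ratios `l` and `1 - l`; must lie in (0, 0.5).
#'   Default 0.05 (the conventional TRT95).
#'
#' @return An object of class `"flexit_params"`.
#' @seealso [sex_ratio()], [trt_limits()], [loglik_counts()]
#' @examples
#' p <- flexit_params(P = 29.49, S = 2.34, dS = 0.49)
#' sex_ratio(p, c(28, 29.49, 31))
#' @export
flexit_params <- function(P, S, dS = 0, l = 0.05) {
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P))
    stop("'P' must be a single finite number (degrees C)")
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S <= 0)
    stop("'S' must be a single positive number")
  if (!is.numeric(dS) || length(dS) != 1L || !is.finite(dS) || S + dS <= 0)
    stop("'S + dS' must be positive (both limbs of the curve must increase)")
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0 || l >= 0.5)
    stop("'l' must lie strictly in (0, 0.5)")
  structure(list(P = P, S = S, dS = dS, l = l), class = "flexit_params")
}

#' @export
print.flexit_params <- function(x, ...) {
  cat(sprintf(
    "flexit* parameters: P = %.3f degC, S1 = %.3f, S2 = %.3f (l = %g)\n",
    x$P, x$S, x$S + x$dS, x$l))
  invisible(x)
}

#' Quasi-binary threshold function
#'
#' A very steep logistic, `QBT = (1 + exp(100 * (P - T)))^-1`, used to switch
#' the active slope of the flexit* curve across the pivotal temperature:
#' it is exactly 0.5 at `T = P`, and within 1e-4 of 0 (below `P`) or 1
#' (above `P`) once `|T - P| > 0.1` degrees C. Computed overflow-safely for
#' any temperature difference.
#'
#' @param P pivotal temperature, degrees C.
#' @param temp temperature(s), degrees C; vectorised.
#' @return Numeric weight(s) in \[0, 1\].
#' @examples
#' qbt(29.5, c(29.0, 29.5, 30.0))
#' @export
qbt <- function(P, temp) {
  stats::plogis(100 * (temp - P))
}

#' Sex ratio at a given temperature under the flexit* model
#'
#' Returns the expected proportion of females,
#' `sr(T) = (1 + exp(4 * (S + dS * QBT) * (P - T)))^-1`,
#' i.e. females are produced at warm temperatures (TSD pattern Ia, as in
#' sea turtles). At `T = P` the value is exactly 0.5; the curve is strictly
#' increasing in temperature.
#'
#' @param params a [flexit_params()] object.
#' @param temp temperature(s), degrees C (constant incubation temperature or
#'   a constant-temperature equivalent); vectorised.
#' @return Proportion(s) female in \[0, 1\].
#' @export
sex_ratio <- function(params, temp) {
  stopifnot(inherits(params, "flexit_params"))
  slope <- params$S + params$dS * qbt(params$P, temp)
  stats::plogis(4 * slope * (temp - params$P))
}

#' Limits of the transitional range of temperatures (TRT)
#'
#' The TRT is the temperature interval producing sex ratios between `l` and
#' `1 - l`. Under flexit* its limits have closed forms:
#' `lower = P - log((1-l)/l) / (4 S)` and
#' `upper = P + log((1-l)/l) / (4 (S + dS))`.
#' The width is reported as `upper - lower` (positive).
#'
#' @param params a [flexit_params()] object.
#' @param l tail sex ratio in (0, 0.5); defaults to the value stored in
#'   `params`.
#' @return An object of class `"trt_limits"`: list with `lower`, `upper`,
#'   `width` (degrees C) and `l`.
#' @examples
#' trt_limits(flexit_params(29.5, 1))   # symmetric, width log(19)/2
#' @export
trt_limits <- function(params, l = params$l) {
  stopifnot(inherits(params, "flexit_params"))
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0 || l >= 0.5)
    stop("'l' must lie strictly in (0, 0.5)")
  g <- log((1 - l) / l)
  lower <- params$P - g / (4 * params$S)
  upper <- params$P + g / (4 * (params$S + params$dS))
  structure(list(lower = lower, upper = upper, width = upper - lower, l = l),
            class = "trt_limits")
}

#' @export
print.trt_limits <- function(x, ...) {
  cat(sprintf("TRT%g: %.3f to %.3f degC (width %.3f)\n",
              100 * (1 - 2 * x$l), x$lower, x$upper, x$width))
  invisible(x)
}

#' Validate and normalise a table of sex-count records
#'
#' Checks a data frame of incubation-group sex counts (one row per clutch or
#' incubation condition) and resolves intersex individuals according to a
#' fixed rule. Required columns: `temperature_C`, `males`, `females`.
#' Optional: `intersex` (default 0) and the nesting labels `rmu`,
#' `study_id`, `clutch` (default empty strings).
#'
#' @param x a data frame of sex counts.
#' @param intersex how to count intersex individuals: `"exclude"` (drop them,
#'   default), `"female"`, `"male"`, or `"half"` (0.5 to each sex).
#' @return A data frame of class `"sexcounts"` with the intersex rule applied
#'   (the `intersex` column is zeroed once folded) and an
#'   `attr(, "intersex_rule")`.
#' @export
as_sexcounts <- function(x, intersex = c("exclude", "female", "male", "half")) {
  intersex <- match.arg(intersex)
  if (inherits(x, "sexcounts")) return(x)
  if (!is.data.frame(x)) stop("sex counts must be a data frame")
  need <- c("temperature_C", "males", "females")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("sex-count table is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(x)
  if (is.null(df$intersex)) df$intersex <- rep(0, nrow(df))
  for (lab in c("rmu", "study_id", "clutch"))
    if (is.null(df[[lab]])) df[[lab]] <- rep("", nrow(df)) else
      df[[lab]] <- as.character(df[[lab]])
  bad <- which(!is.finite(df$temperature_C))
  if (length(bad))
    stop("non-finite temperature_C in row(s): ", paste(bad, collapse = ", "))
  cnt <- c("males", "females", "intersex")
  for (cc in cnt) {
    bad <- which(!is.finite(df[[cc]]) | df[[cc]] < 0)
    if (length(bad))
      stop(sprintf("invalid '%s' count in row(s): %s", cc,
                   paste(bad, collapse = ", ")))
  }
  ix <- df$intersex
  if (intersex == "female") df$females <- df$females + ix
  if (intersex == "male") df$males <- df$males + ix
  if (intersex == "half") {
    df$females <- df$females + ix / 2
    df$males <- df$males + ix / 2
  }
  df$intersex <- rep(0, nrow(df))
  df <- df[, c("temperature_C", "males", "females", "intersex",
               "rmu", "study_id", "clutch")]
  structure(df, class = c("sexcounts", "data.frame"),
            intersex_rule = intersex)
}

clip_prob <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)

#' Binomial log-likelihood of sex-count data under flexit*
#'
#' Sums, over incubation groups, the binomial log-probability of observing
#' `females` females among `males + females` sexed individuals when the
#' success probability is [sex_ratio()] at the group's temperature. The
#' combinatorial constant is omitted (it does not depend on the parameters,
#' so likelihood ratios, MCMC and AICc comparisons on shared data are
#' unaffected). Probabilities are clipped to `[1e-15, 1 - 1e-15]` so the
#' value is finite for all valid parameters.
#'
#' @param params a [flexit_params()] object.
#' @param data a data frame acceptable to [as_sexcounts()]; every record must
#'   have at least one sexed individual.
#' @return The log-likelihood (a single number).
#' @export
loglik_counts <- function(params, data) {
  stopifnot(inherits(params, "flexit_params"))
  df <- as_sexcounts(data)
  if (nrow(df) == 0L)
    stop(errorCondition("no sex-count records supplied",
                        class = c("tsdnorm_empty_data", "error", "condition")))
  tot <- df$males + df$females
  bad <- which(tot < 1)
  if (length(bad))
    stop(errorCondition(
      paste0("record(s) with zero sexed individuals cannot enter the ",
             "likelihood: row(s) ", paste(bad, collapse = ", ")),
      class = c("tsdnorm_zero_counts", "error", "condition")))
  p <- clip_prob(sex_ratio(params, df$temperature_C))
  sum(df$females * log(p) + df$males * log(1 - p))
}
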