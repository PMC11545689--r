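#' Priors for the flexit* TSD fit
#'
#' Uniform priors on the three global curve parameters and a half-normal
#' prior on every random-effect standard deviation. The support of `dS` is
#' tied to `S` so both limb slopes stay positive.
#'
#' @param P range of the uniform prior on the pivotal temperature, degrees C.
#' @param S range of the uniform prior on the lower-limb slope.
#' @param dS_upper upper bound of the uniform prior on `dS` (lower bound is
#'   `-S + 0.05`, keeping `S + dS >= 0.05`).
#' @param re_sd scale of the half-normal prior on each random-effect SD.
#' @return A list of class `"tsd_priors"`.
#' @export
tsd_priors <- function(P = c(25, 35), S = c(0.05, 20), dS_upper = 20,
                       re_sd = 1) {
  stopifnot(length(P) == 2L, P[1] < P[2], length(S) == 2L, 0 < S[1],
            S[1] < S[2], dS_upper > 0, re_sd > 0)
  structure(list(P = P, S = S, dS_upper = dS_upper, re_sd = re_sd),
            class = "tsd_priors")
}

re_structures <- c("1", "1|RMU", "1|RMU/ID", "1|RMU/ID/Clutch")

parse_re <- function(re) {
  re <- gsub(" ", "", re)
  if (!re %in% re_structures)
    stop("random-effect structure must be one of: ",
         paste(re_structures, collapse = ", "))
  switch(re,
         "1" = character(0),
         "1|RMU" = "RMU",
         "1|RMU/ID" = c("RMU", "ID"),
         "1|RMU/ID/Clutch" = c("RMU", "ID", "Clutch"))
}

## canonical record order so the fit is invariant to input row permutation
canonical_order <- function(df) {
  order(df$rmu, df$study_id, df$clutch, df$temperature_C, df$males,
        df$females, method = "radix")
}

#' Bayesian fit of the flexit* TSD curve, optionally with nested random effects
#'
#' Fits the pivotal temperature `P`, lower-limb slope `S` and slope
#' increment `dS` to clutch-level sex counts with a binomial likelihood
#' ([loglik_counts()]) by adaptive Metropolis-within-Gibbs MCMC. Nested
#' random effects (regional management unit / study / clutch) can be placed
#' on all three parameters: for a record in clutch c of study i of RMU r,
#' `theta_rec = theta + sigma_RMU * z_r + sigma_ID * z_i(r) + sigma_Clutch *
#' z_c(i)` independently for each of `P`, `S`, `dS`, with standard-normal
#' non-centred deviations `z` and half-normal priors on the level SDs.
#'
#' @param data sex counts acceptable to [as_sexcounts()]. Records with zero
#'   sexed individuals are dropped with a message. Record order does not
#'   affect the result (records are sorted canonically before fitting).
#' @param re random-effect structure: `"1"` (none), `"1|RMU"`,
#'   `"1|RMU/ID"` or `"1|RMU/ID/Clutch"`.
#' @param priors a [tsd_priors()] object.
#' @param settings an [mcmc_settings()] object.
#' @param seed integer seed; identical seed and settings give bit-identical
#'   draws.
#' @param intersex intersex rule passed to [as_sexcounts()].
#' @return An object of classes `"tsd_fit"` and `"posterior_draws"`: list
#'   with `draws` (matrix, one row per retained draw), `loglik` (per draw),
#'   `accept` (per-parameter post-burn-in acceptance rates), `meta`
#'   (seed, settings, structure, parameter count `k`, number of sexed eggs
#'   `n`) and the prepared `data`.
#' @examples
#' \donttest{
#' fit <- fit_tsd(east_pacific_counts(), settings = mcmc_settings(200, 1000, 5))
#' posterior_summary(fit, c("P", "S"))
#' }
#' @export
fit_tsd <- function(data, re = "1", priors = tsd_priors(),
                    settings = mcmc_settings(), seed = 1L,
                    intersex = "exclude") {
  stopifnot(inherits(priors, "tsd_priors"))
  df <- as_sexcounts(data, intersex = intersex)
  tot <- df$males + df$females
  if (any(tot < 1)) {
    message(sum(tot < 1), " record(s) with zero sexed individuals dropped")
    df <- df[tot >= 1, , drop = FALSE]
  }
  if (nrow(df) == 0L)
    stop(errorCondition("no usable sex-count records",
                        class = c("tsdnorm_empty_data", "error", "condition")))
  levels_re <- parse_re(re)

  ## label checks in the caller's row order, so error messages name the
  ## offending input records
  if ("Clutch" %in% levels_re && any(df$clutch == "" | is.na(df$clutch)))
    stop("clutch random effect requested but clutch labels are missing in ",
         "record(s): ",
         paste(which(df$clutch == "" | is.na(df$clutch)), collapse = ", "))
  if ("ID" %in% levels_re && any(df$study_id == "" | is.na(df$study_id)))
    stop("study random effect requested but study_id labels are missing in ",
         "record(s): ",
         paste(which(df$study_id == "" | is.na(df$study_id)), collapse = ", "))
  if ("RMU" %in% levels_re && any(df$rmu == "" | is.na(df$rmu)))
    stop("RMU random effect requested but rmu labels are missing in ",
         "record(s): ", paste(which(df$rmu == "" | is.na(df$rmu)), collapse = ", "))
  df <- df[canonical_order(df), , drop = FALSE]
  rownames(df) <- NULL
  keys <- list(
    RMU = df$rmu,
    ID = paste(df$rmu, df$study_id, sep = "/"),
    Clutch = paste(df$rmu, df$study_id, df$clutch, sep = "/"))
  gidx <- lapply(levels_re, function(lv) {
    f <- factor(keys[[lv]], levels = unique(keys[[lv]]))
    as.integer(f)
  })
  names(gidx) <- levels_re
  ngrp <- vapply(gidx, max, integer(1))

  ## parameter vector layout
  pnames <- c("P", "S", "dS")
  for (lv in levels_re)
    pnames <- c(pnames, paste0("sigma_", lv, "_", c("P", "S", "dS")))
  zpos <- list()
  for (lv in levels_re) {
    for (par in c("P", "S", "dS")) {
      nm <- paste0("z_", lv, "_", par, "_", seq_len(ngrp[[lv]]))
      zpos[[paste0(lv, ".", par)]] <- length(pnames) + seq_along(nm)
      pnames <- c(pnames, nm)
    }
  }
  sigpos <- lapply(levels_re, function(lv)
    match(paste0("sigma_", lv, "_", c("P", "S", "dS")), pnames))
  names(sigpos) <- levels_re

  tt <- df$temperature_C
  mm <- df$males
  ff <- df$females
  nrec <- nrow(df)

  loglik <- function(th) {
    Pe <- rep(th[1L], nrec); Se <- rep(th[2L], nrec); De <- rep(th[3L], nrec)
    for (lv in levels_re) {
      sp <- sigpos[[lv]]
      g <- gidx[[lv]]
      Pe <- Pe + th[sp[1L]] * th[zpos[[paste0(lv, ".P")]]][g]
      Se <- Se + th[sp[2L]] * th[zpos[[paste0(lv, ".S")]]][g]
      De <- De + th[sp[3L]] * th[zpos[[paste0(lv, ".dS")]]][g]
    }
    if (any(Se <= 0) || any(Se + De <= 0)) return(-Inf)
    q <- stats::plogis(100 * (tt - Pe))
    p <- clip_prob(stats::plogis(4 * (Se + De * q) * (tt - Pe)))
    sum(ff * log(p) + mm * log(1 - p))
  }

  nz <- length(pnames) - 3L - 3L * length(levels_re)
  zall <- if (nz > 0) (3L + 3L * length(levels_re) + 1L):length(pnames) else integer(0)
  sigall <- unlist(sigpos, use.names = FALSE)
  logprior <- function(th) {
    if (th[1L] < priors$P[1] || th[1L] > priors$P[2]) return(-Inf)
    if (th[2L] < priors$S[1] || th[2L] > priors$S[2]) return(-Inf)
    if (th[3L] < -th[2L] + 0.05 || th[3L] > priors$dS_upper) return(-Inf)
    out <- 0
    if (length(sigall)) {
      sig <- th[sigall]
      if (any(sig < 0)) return(-Inf)
      out <- out + sum(stats::dnorm(sig, 0, priors$re_sd, log = TRUE)) +
        length(sig) * log(2)
    }
    if (length(zall))
      out <- out + sum(stats::dnorm(th[zall], 0, 1, log = TRUE))
    out
  }

  init <- stats::setNames(numeric(length(pnames)), pnames)
  init["P"] <- min(max(stats::median(tt), priors$P[1] + 0.5), priors$P[2] - 0.5)
  init["S"] <- 1
  init["dS"] <- 0
  if (length(sigall)) init[sigall] <- 0.1 * priors$re_sd
  init <- redraw_if_needed(init, loglik, logprior, function() {
    th <- init
    th["P"] <- stats::runif(1, priors$P[1], priors$P[2])
    th["S"] <- stats::runif(1, priors$S[1], min(priors$S[2], 5))
    th["dS"] <- stats::runif(1, -th["S"] + 0.05, 2)
    if (length(sigall)) th[sigall] <- abs(stats::rnorm(length(sigall), 0,
                                                       priors$re_sd / 2))
    if (length(zall)) th[zall] <- stats::rnorm(length(zall), 0, 0.2)
    th
  }, seed)

  scales <- stats::setNames(rep(0.5, length(pnames)), pnames)
  scales[c("P", "S", "dS")] <- c(0.3, 0.5, 0.5)
  if (length(sigall)) scales[sigall] <- 0.2 * priors$re_sd

  run <- run_adaptive_mwg(loglik, logprior, init, settings, seed, scales,
                          joint_block = seq_len(3L + 3L * length(levels_re)))
  structure(list(draws = run$draws, loglik = run$loglik,
                 accept = run$accept, scales = run$scales,
                 meta = list(seed = as.integer(seed), settings = settings,
                             re = re, levels = levels_re,
                             k = 3L + 3L * length(levels_re),
                             n = sum(df$males + df$females),
                             n_records = nrow(df),
                             priors = priors),
                 data = df),
            class = c("tsd_fit", "posterior_draws"))
}

## try the deterministic init; if the posterior is not finite there, re-draw
## starting values from the prior (at most 100 attempts), then fail loudly
redraw_if_needed <- function(init, loglik, logprior, draw_fun, seed,
                             max_tries = 100L) {
  ok <- function(th) {
    lp <- logprior(th)
    is.finite(lp) && is.finite(loglik(th))
  }
  if (ok(init)) return(init)
  set.seed(as.integer(seed) + 777L)
  for (i in seq_len(max_tries)) {
    th <- draw_fun()
    if (ok(th)) return(th)
  }
  stop("could not find a starting point with finite posterior after ",
       max_tries, " prior draws")
}

#' @export
print.tsd_fit <- function(x, ...) {
  cat(sprintf(
    "flexit* TSD fit (%s): %d records, %g sexed eggs, %d retained draws\n",
    x$meta$re, x$meta$n_records, x$meta$n, nrow(x$draws)))
  print(posterior_summary(x, c("P", "S", "dS")))
  invisible(x)
}
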