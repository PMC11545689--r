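test_that("identical seed and settings give bit-identical draws", {
  d <- east_pacific_counts()
  f1 <- fit_tsd(d, settings = fast_settings(), seed = 5)
  f2 <- fit_tsd(d, settings = fast_settings(), seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$loglik, f2$loglik)
  f3 <- fit_tsd(d, settings = fast_settings(), seed = 6)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("permuting record order leaves the posterior unchanged", {
  cfg <- sim_config(n_rmu = 2, ids_per_rmu = 2, clutches_per_id = 3,
                    eggs_per_clutch = 12, temps = c(29.2, 29.5, 29.8),
                    seed = 21)
  d <- as.data.frame(gen_sexcounts(cfg))
  set.seed(99)
  d_perm <- d[sample(nrow(d)), , drop = FALSE]
  f1 <- fit_tsd(d, re = "1|RMU", settings = fast_settings(), seed = 3)
  f2 <- fit_tsd(d_perm, re = "1|RMU", settings = fast_settings(), seed = 3)
  expect_identical(f1$draws, f2$draws)
})

test_that("the no-RE fit recovers the generating pivotal temperature", {
  truth <- default_flexit_params()
  cfg <- sim_config(params = truth, clutches_per_id = 20, eggs_per_clutch = 10,
                    temps = seq(27, 32, by = 0.25), seed = 31)
  d <- gen_sexcounts(cfg)
  fit <- fit_tsd(d, settings = mcmc_settings(500, 4000, 5), seed = 8)
  medP <- median(fit$draws[, "P"])
  expect_lt(abs(medP - truth$P), 0.2)
  expect_true(all(fit$accept >= 0.1 & fit$accept <= 0.6))
})

test_that("single-temperature data pin the local sex ratio but not the slopes", {
  d <- data.frame(temperature_C = 29.5, males = 40, females = 60)
  fit <- fit_tsd(d, settings = fast_settings(), seed = 9)
  prior <- tsd_priors()
  # S wanders over most of its prior range (prior-dominated)
  expect_gt(diff(quantile(fit$draws[, "S"], c(0.025, 0.975))),
            0.3 * diff(prior$S))
  # but the implied sex ratio at the observed temperature is tight around 0.6
  srs <- apply(fit$draws, 1, function(th)
    sex_ratio(flexit_params(th["P"], th["S"], th["dS"]), 29.5))
  expect_lt(abs(median(srs) - 0.6), 0.1)
})

test_that("shrinking the RE SD prior to zero recovers the no-RE posterior", {
  cfg <- sim_config(n_rmu = 1, ids_per_rmu = 1, clutches_per_id = 8,
                    eggs_per_clutch = 15, temps = c(29.3, 29.5, 29.7),
                    seed = 41)
  d <- gen_sexcounts(cfg)
  st <- mcmc_settings(400, 2000, 4)
  f0 <- fit_tsd(d, re = "1", settings = st, seed = 11)
  fz <- fit_tsd(d, re = "1|RMU/ID/Clutch",
                priors = tsd_priors(re_sd = 1e-6), settings = st, seed = 11)
  expect_lt(max(abs(fz$draws[, paste0("sigma_Clutch_", c("P", "S", "dS"))])),
            1e-4)
  expect_lt(abs(median(fz$draws[, "P"]) - median(f0$draws[, "P"])), 0.1)
})

test_that("requesting a clutch effect without clutch labels names the records", {
  d <- data.frame(temperature_C = c(29, 30), males = c(5, 1), females = c(1, 5),
                  rmu = "A", study_id = "s1", clutch = c("c1", ""))
  expect_error(fit_tsd(d, re = "1|RMU/ID/Clutch", settings = fast_settings()),
               "clutch.*2")
  expect_error(fit_tsd(d, re = "nonsense"), "structure")
})

test_that("zero-count records are dropped with a message before fitting", {
  d <- as.data.frame(east_pacific_counts(keep_empty = TRUE))
  expect_message(fit_tsd(d, settings = fast_settings(), seed = 1), "dropped")
})

test_that("growth fit recovers the reaction norm from constant temperatures", {
  gp <- fx_growth()
  dur <- gen_durations(c(27, 28, 29, 30, 31), gp, sd_days = 2, n = 20,
                       seed = 51)
  fit <- fit_growth(dur, settings = mcmc_settings(500, 2500, 5), seed = 52)
  med <- apply(fit$draws, 2, median)
  pm <- schoolfield_params(med["rho25"], med["dHA"], med["dHL"], med["T12L"])
  for (temp in c(27, 29, 31, 33)) {
    expect_lt(abs(schoolfield_rate(pm, temp) / schoolfield_rate(gp, temp) - 1),
              0.1)
  }
  expect_true(all(fit$accept >= 0.1 & fit$accept <= 0.6))
  # identical seed reproduces the chain
  fit2 <- fit_growth(dur, settings = mcmc_settings(500, 2500, 5), seed = 52)
  expect_identical(fit$draws, fit2$draws)
})

test_that("growth fit validates its inputs", {
  gp <- fx_growth()
  dur <- gen_durations(c(28, 30), gp, sd_days = 2, n = 5, seed = 1)
  expect_error(fit_growth(dur), "3 distinct")
  dur2 <- gen_durations(c(28, 29, 30), gp, sd_days = 2, n = 5, seed = 1)
  dur2$sd_days[1] <- 0
  expect_error(fit_growth(dur2), "sd_days")
  dur3 <- data.frame(series_id = "missing", mean_days = 60, sd_days = 2, n = 5)
  expect_error(fit_growth(dur3, series = list()), "matching temperature series")
})

test_that("posterior summaries report SE 0 for constants and normal quantiles", {
  set.seed(7)
  m <- cbind(const = rep(2.5, 4000), z = rnorm(4000))
  s <- posterior_summary(m)
  expect_equal(s$sd[1], 0)
  expect_equal(s$mcse[1], 0)
  expect_equal(s$q2.5[2], -1.96, tolerance = 0.12)
  expect_equal(s$q97.5[2], 1.96, tolerance = 0.12)
  expect_error(posterior_summary(m, "nope"), "unknown parameter")
  # functional interface: per-draw TRT limits
  d <- east_pacific_counts()
  fit <- fit_tsd(d, settings = fast_settings(), seed = 2)
  tr <- posterior_summary(fit, functional = function(th) {
    lim <- trt_limits(flexit_params(th[["P"]], th[["S"]], th[["dS"]]))
    c(lower = lim$lower, upper = lim$upper)
  })
  expect_true(all(tr$median[tr$parameter == "lower"] <
                    tr$median[tr$parameter == "upper"]))
})

test_that("TRT and P uncertainty widen when random effects are included", {
  cfg <- sim_config(n_rmu = 2, ids_per_rmu = 2, clutches_per_id = 3,
                    eggs_per_clutch = 12, temps = c(29.2, 29.4, 29.6, 29.8),
                    re_sd = list(clutch = c(P = 0.25)), seed = 61)
  d <- gen_sexcounts(cfg)
  st <- mcmc_settings(400, 2000, 4)
  f0 <- fit_tsd(d, re = "1", settings = st, seed = 13)
  fre <- fit_tsd(d, re = "1|RMU/ID/Clutch", settings = st, seed = 13)
  sd0 <- sd(f0$draws[, "P"])
  sdre <- sd(fre$draws[, "P"])
  expect_gt(sdre, sd0)
})
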