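test_that("Schoolfield rate has the reference identity and hand-checked value", {
  # with low-temperature inhibition disabled the rate at 25 degC is rho25
  p <- schoolfield_params(1e-4, 5e4, -1e9, 290)
  expect_equal(schoolfield_rate(p, 25), 1e-4, tolerance = 1e-12)
  # hand evaluation of the full formula
  p2 <- schoolfield_params(1e-5, 5e4, -1e5, 293.15)
  TK <- 303.15
  num <- 1e-5 * (TK / 298.15) * exp((5e4 / 8.314) * (1 / 298.15 - 1 / TK))
  den <- 1 + exp((-1e5 / 8.314) * (1 / 293.15 - 1 / TK))
  expect_equal(schoolfield_rate(p2, 30), num / den, tolerance = 1e-12)
  # leatherback-like defaults increase monotonically over 25-35 degC
  r <- schoolfield_rate(fx_growth(), seq(25, 35, by = 0.1))
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0))
})

test_that("integrator matches the constant-temperature closed form", {
  gp <- fx_growth()
  for (temp in c(27, 29.5, 31)) {
    d_closed <- closed_duration_days(gp, temp)
    s <- temperature_series(c(0, 2 * d_closed * 1440), c(temp, temp))
    traj <- integrate_trajectory(gp, s)
    expect_lt(abs(traj$t_hatch_min / 1440 - d_closed) / d_closed, 1e-3)
    expect_equal(traj$scl[1], 1.7)
    expect_true(all(diff(traj$scl) >= 0))
    expect_equal(traj$scl[length(traj$scl)], 59.3, tolerance = 1e-9)
  }
})

test_that("halving the step changes the duration by less than 0.05%", {
  gp <- fx_growth()
  s <- gen_temperature_series(days = 90, mean_C = 28.5, amplitude = 1.5,
                              jitter_sd = 0.3, interval_min = 180, seed = 9)
  d60 <- predict_duration(gp, s, step_min = 60)
  d30 <- predict_duration(gp, s, step_min = 30)
  expect_lt(abs(d60 - d30) / d30, 5e-4)
})

test_that("doubling rho25 halves the constant-temperature duration", {
  gp <- fx_growth()
  g2 <- schoolfield_params(2 * gp$rho25, gp$dHA, gp$dHL, gp$T12L)
  expect_equal(predict_duration(g2, 29.5), predict_duration(gp, 29.5) / 2,
               tolerance = 1e-6)
})

test_that("non-hatching series raises a structured error with attained SCL", {
  gp <- fx_growth()
  s <- temperature_series(c(0, 10 * 1440), c(29.5, 29.5))  # only 10 days
  err <- tryCatch(integrate_trajectory(gp, s), tsdnorm_no_hatch = identity)
  expect_s3_class(err, "tsdnorm_no_hatch")
  expect_true(err$attained_scl > 1.7 && err$attained_scl < 59.3)
  # degenerate near-zero growth: attained size stays at scl0
  g0 <- schoolfield_params(1e-300, 5e4, -1e5, 296)
  err0 <- tryCatch(integrate_trajectory(g0, s), tsdnorm_no_hatch = identity)
  expect_s3_class(err0, "tsdnorm_no_hatch")
  expect_equal(err0$attained_scl, 1.7, tolerance = 1e-9)
})

test_that("accumulated growth over a fixed horizon is order-independent", {
  # the growth law is time-homogeneous: permuting the daily blocks of a
  # piecewise-constant series leaves the growth attained by the end of the
  # series unchanged (durations differ, because hatching truncates the
  # series at different points of the permutation)
  gp <- fx_growth()
  temps <- rep(c(28, 30, 29, 31), each = 7)  # 28 days, too short to hatch
  build <- function(tv) {
    t0 <- (seq_along(tv) - 1) * 1440
    temperature_series(as.vector(rbind(t0, t0 + 1439.9)), rep(tv, each = 2))
  }
  attained <- function(s)
    tryCatch(integrate_trajectory(gp, s, step_min = 15),
             tsdnorm_no_hatch = function(e) e$attained_scl)
  a1 <- attained(build(temps))
  set.seed(77)
  a2 <- attained(build(sample(temps)))
  expect_true(is.numeric(a1) && a1 < 59.3)
  expect_equal(a1, a2, tolerance = 1e-3)
  # determinism: same series twice gives identical durations
  full <- build(rep(c(28, 30, 29, 31), each = 25))
  expect_identical(predict_duration(gp, full), predict_duration(gp, full))
})

test_that("TSP window matches the exponential-growth closed form", {
  gp <- fx_growth()
  temp <- 29.5
  r <- schoolfield_rate(gp, temp)
  d <- closed_duration_days(gp, temp)
  s <- temperature_series(c(0, 2 * d * 1440), c(temp, temp))
  traj <- integrate_trajectory(gp, s)
  tsp <- tsp_window(traj, c(1 / 3, 2 / 3))
  for (k in 1:2) {
    f <- c(1 / 3, 2 / 3)[k]
    expected <- log(f * 59.3 / 1.7) / r
    got <- c(tsp$t_start, tsp$t_end)[k]
    expect_lt(abs(got - expected) / expected, 1e-3)
  }
  expect_lt(tsp$t_start, tsp$t_end)
  expect_error(tsp_window(traj, c(2 / 3, 1 / 3)), "stage_fracs")
})

test_that("the TSP is not the middle third of incubation time and shifts with phase order", {
  gp <- fx_growth()
  # cool first half, warm second half
  s <- temperature_series(c(0, 45 * 1440, 45 * 1440 + 1, 120 * 1440),
                          c(27.5, 27.5, 31, 31))
  traj <- integrate_trajectory(gp, s)
  tsp <- tsp_window(traj)
  dur <- traj$t_hatch_min
  # growth accelerates late, so the SCL-defined TSP sits earlier in *time*
  # than the naive middle third
  expect_gt(tsp$t_start, dur / 3)
  expect_gt(tsp$t_end, 2 * dur / 3)
  s2 <- temperature_series(c(0, 45 * 1440, 45 * 1440 + 1, 120 * 1440),
                           c(31, 31, 27.5, 27.5))
  tsp2 <- tsp_window(integrate_trajectory(gp, s2))
  expect_lt(tsp2$t_start, tsp$t_start)
})

test_that("temperature series validation rejects malformed input", {
  expect_error(temperature_series(c(0, 0), c(29, 29)), "strictly increasing")
  expect_error(temperature_series(0, 29), "two")
  expect_error(temperature_series(c(0, 10), c(10, 29)), "15, 45")
})
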