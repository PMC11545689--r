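test_that("quasi-binary threshold is exact at the pivot and saturates fast", {
  expect_identical(qbt(29.5, 29.5), 0.5)
  expect_equal(qbt(29.5, 35.0), 1.0, tolerance = 1e-12)
  expect_equal(qbt(29.5, 29.49), 1 / (1 + exp(1)), tolerance = 1e-12)
  # overflow-safe over huge temperature offsets
  expect_equal(qbt(29.5, 129.5), 1)
  expect_equal(qbt(29.5, -70.5), 0)
  # saturated beyond 0.1 degC
  expect_lt(abs(qbt(29.5, 29.6) - 1), 1e-4)
  expect_lt(qbt(29.5, 29.39), 1e-4)
})

test_that("sex ratio is 0.5 at P, asymptotes correctly, and is overflow-safe", {
  p <- fx_params()
  expect_identical(sex_ratio(p, p$P), 0.5)
  expect_equal(sex_ratio(p, 1e4), 1)
  expect_equal(sex_ratio(p, -1e4), 0)
  # symmetric-logistic closed form away from P
  ps <- flexit_params(29.5, 1, 0)
  expect_equal(sex_ratio(ps, 25), 1 / (1 + exp(18)), tolerance = 1e-9)
})

test_that("sex ratio uses slope S below P and S + dS above P", {
  p <- flexit_params(29.5, 1, 1)
  # 1 degC below P the QBT weight is ~0: slope 4*S
  expect_equal(sex_ratio(p, 28.5), plogis(-4), tolerance = 1e-9)
  # 1 degC above P the QBT weight is ~1: slope 4*(S+dS)
  expect_equal(sex_ratio(p, 30.5), plogis(8), tolerance = 1e-9)
})

test_that("pivotal identity holds for random parameter sets", {
  set.seed(101)
  for (i in 1:1000) {
    p <- rand_flexit()
    expect_lt(abs(sex_ratio(p, p$P) - 0.5), 1e-12)
  }
})

test_that("sex ratio is monotone in temperature", {
  set.seed(202)
  grid <- seq(20, 40, by = 0.01)
  for (i in 1:25) {
    p <- rand_flexit()
    sr <- sex_ratio(p, grid)
    expect_true(all(diff(sr) >= 0))
    w <- trt_limits(p)$width
    near <- grid[abs(grid - p$P) < 3 * w]
    srn <- sex_ratio(p, near)
    # strict increase wherever the curve is not saturated in double precision
    keep <- srn > 1e-12 & srn < 1 - 1e-12
    expect_true(all(diff(srn[keep]) > 0))
  }
})

test_that("flexit* reduces to the plain logistic when dS = 0", {
  set.seed(303)
  for (i in 1:20) {
    P <- runif(1, 27, 32); S <- runif(1, 0.3, 6)
    p <- flexit_params(P, S, 0)
    temps <- P + c(seq(-5, -0.06, by = 0.2), seq(0.06, 5, by = 0.2))
    expect_equal(sex_ratio(p, temps), plogis(4 * S * (temps - P)),
                 tolerance = 1e-9)
  }
})

test_that("TRT limits match their closed forms and round-trip the curve", {
  p <- flexit_params(29.5, 1, 0, l = 0.05)
  tr <- trt_limits(p)
  expect_equal(tr$lower, 29.5 - log(19) / 4, tolerance = 1e-12)
  expect_equal(tr$upper, 29.5 + log(19) / 4, tolerance = 1e-12)
  expect_equal(tr$width, log(19) / 2, tolerance = 1e-12)
  # symmetry about P when dS = 0
  expect_equal(tr$upper - p$P, p$P - tr$lower)
  # slope ratio 2 halves the upper-side distance
  p2 <- flexit_params(29.5, 1, 1, l = 0.05)
  tr2 <- trt_limits(p2)
  expect_equal(tr2$upper - 29.5, (29.5 - tr2$lower) / 2, tolerance = 1e-12)
  # round trip: sex ratio at the limits equals l and 1 - l; limb slopes are
  # kept <= 6 so the limits sit outside the QBT transition zone (~0.1 degC
  # around P), where the blending is genuinely negligible
  set.seed(404)
  for (i in 1:50) {
    P <- runif(1, 26, 33); S <- runif(1, 0.2, 5)
    dS <- runif(1, -0.6 * S, min(4, 6 - S))
    p <- flexit_params(P, S, dS)
    tr <- trt_limits(p)
    expect_true(tr$lower < p$P && p$P < tr$upper && tr$width > 0)
    expect_lt(abs(sex_ratio(p, tr$lower) - p$l), 1e-6)
    expect_lt(abs(sex_ratio(p, tr$upper) - (1 - p$l)), 1e-6)
  }
  expect_error(trt_limits(p, l = 0.7), "0, 0.5")
  expect_error(flexit_params(29, 1, 0, l = 0), "0, 0.5")
})

test_that("parameter validation rejects non-increasing curves", {
  expect_error(flexit_params(29.5, -1), "'S'")
  expect_error(flexit_params(29.5, 1, -1.5), "S \\+ dS")
  expect_error(flexit_params(NA, 1), "finite")
})

test_that("binomial log-likelihood matches closed forms and per-egg brute force", {
  p <- fx_params()
  # one record at T = P, 1 male 1 female: -2 log 2 without the binomial constant
  d1 <- data.frame(temperature_C = p$P, males = 1, females = 1)
  expect_equal(loglik_counts(p, d1), -2 * log(2), tolerance = 1e-12)
  # an all-male record contributes n * log(1 - q)
  q <- sex_ratio(p, 28)
  d2 <- data.frame(temperature_C = 28, males = 17, females = 0)
  expect_equal(loglik_counts(p, d2), 17 * log(1 - q), tolerance = 1e-12)
  # additivity: duplicated record doubles the value
  d3 <- rbind(d2, d2)
  expect_equal(loglik_counts(p, d3), 2 * loglik_counts(p, d2))
  # brute-force per-egg oracle on small random datasets
  set.seed(505)
  for (i in 1:20) {
    pp <- rand_flexit()
    nd <- data.frame(temperature_C = runif(4, 27, 32),
                     males = sample(0:3, 4, replace = TRUE),
                     females = sample(0:3, 4, replace = TRUE))
    nd <- nd[nd$males + nd$females >= 1, , drop = FALSE]
    if (nrow(nd) == 0) next
    expect_equal(loglik_counts(pp, nd), brute_loglik(pp, nd),
                 tolerance = 1e-10)
  }
})

test_that("likelihood errors distinguish empty data from zero-count records", {
  p <- fx_params()
  empty <- data.frame(temperature_C = numeric(0), males = numeric(0),
                      females = numeric(0))
  expect_error(loglik_counts(p, empty), class = "tsdnorm_empty_data")
  zero <- data.frame(temperature_C = 33, males = 0, females = 0)
  expect_error(loglik_counts(p, zero), class = "tsdnorm_zero_counts")
})

test_that("intersex rules fold counts as configured", {
  d <- data.frame(temperature_C = 29.5, males = 2, females = 3, intersex = 2)
  expect_equal(as_sexcounts(d, "exclude")$females, 3)
  expect_equal(as_sexcounts(d, "female")$females, 5)
  expect_equal(as_sexcounts(d, "male")$males, 4)
  half <- as_sexcounts(d, "half")
  expect_equal(half$males, 3)
  expect_equal(half$females, 4)
})
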