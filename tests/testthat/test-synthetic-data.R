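test_that("simulation is deterministic under a fixed seed", {
  spec <- simulation_spec("weibull", c(shape = 1.3, scale = 30), n = 500,
                          accrual_window = 12, admin_censor = 40, seed = 7)
  expect_identical(simulate_ipd(spec), simulate_ipd(spec))
  spec2 <- simulation_spec("weibull", c(shape = 1.3, scale = 30), n = 500,
                           accrual_window = 12, admin_censor = 40, seed = 8)
  expect_false(identical(simulate_ipd(spec), simulate_ipd(spec2)))
})

test_that("no censoring mechanism yields all events", {
  spec <- simulation_spec("lognormal", c(meanlog = 2, sdlog = 1), n = 400,
                          accrual_window = 0, admin_censor = Inf, seed = 1)
  ipd <- simulate_ipd(spec)
  expect_true(all(ipd$event == 1))
  expect_true(all(ipd$time > 0))
})

test_that("empirical survival converges to the family closed form", {
  spec <- simulation_spec("exponential", c(rate = 0.05), n = 200000,
                          admin_censor = Inf, seed = 42)
  ipd <- simulate_ipd(spec)
  expect_lt(abs(mean(ipd$time > 12) - exp(-0.6)), 0.005)
})

test_that("large-sample moments match closed forms within Monte-Carlo error", {
  n <- 50000
  cases <- list(
    list(fam = "weibull", par = c(shape = 1.5, scale = 24),
         mean = 24 * gamma(1 + 1 / 1.5), median = 24 * log(2)^(1 / 1.5)),
    list(fam = "lognormal", par = c(meanlog = 2.5, sdlog = 0.9),
         mean = exp(2.5 + 0.9^2 / 2), median = exp(2.5)),
    list(fam = "loglogistic", par = c(shape = 2.5, scale = 18),
         mean = 18 * (pi / 2.5) / sin(pi / 2.5), median = 18))
  for (cs in cases) {
    ipd <- simulate_ipd(simulation_spec(cs$fam, cs$par, n = n,
                                        admin_censor = Inf, seed = 42))
    expect_lt(abs(mean(ipd$time) - cs$mean) / cs$mean, 0.02)
    expect_lt(abs(median(ipd$time) - cs$median) / cs$median, 0.02)
  }
})

test_that("censoring fraction rises as administrative follow-up shortens", {
  props <- vapply(c(60, 36, 24, 12), function(ac) {
    ipd <- simulate_ipd(simulation_spec("lognormal",
                                        c(meanlog = 2.7, sdlog = 1.4),
                                        n = 4000, accrual_window = 6,
                                        admin_censor = ac, seed = 42))
    mean(ipd$event == 0)
  }, numeric(1))
  expect_true(all(diff(props) > 0))
})

test_that("KM estimator reproduces the hand product-limit computation", {
  ipd <- data.frame(time = 1:4, event = 1)
  km <- km_estimate(ipd)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$n_risk, 4:1)

  all_cens <- data.frame(time = c(2, 4, 7), event = 0)
  expect_true(all(km_estimate(all_cens)$surv == 1))

  expect_error(km_estimate(data.frame(time = numeric(0), event = numeric(0))),
               "at least one record")
})

test_that("KM of a large simulated sample tracks the true survival", {
  spec <- simulation_spec("lognormal", c(meanlog = 2.7, sdlog = 1.4),
                          n = 100000, accrual_window = 12, admin_censor = 48,
                          seed = 42)
  ipd <- simulate_ipd(spec)
  grid <- seq(0.5, 35, by = 0.5)
  km <- km_estimate(ipd, grid = grid)
  truth <- surv_prob(parametric_model("lognormal",
                                      c(meanlog = 2.7, sdlog = 1.4)), grid)
  expect_lt(max(abs(km$surv - truth)), 0.01)
})

test_that("digitized fixtures reproduce the KM exactly when jitter is zero", {
  ipd <- simulate_ipd(simulation_spec("lognormal", c(meanlog = 2, sdlog = 1),
                                      n = 200, accrual_window = 4,
                                      admin_censor = 30, seed = 5))
  fx <- make_digitized_fixture(ipd, coord_step = 1, risk_interval = 6)
  km <- km_estimate(ipd, grid = fx$coords$time)
  expect_equal(fx$coords$surv, km$surv, tolerance = 1e-12)
  expect_equal(fx$risk_table$n_risk[1], 200)
  expect_equal(fx$total_events, sum(ipd$event))
  expect_equal(attr(fx, "n_clamped"), 0L)
})

test_that("jitter that breaks monotonicity is clamped with a warning", {
  ipd <- simulate_ipd(simulation_spec("weibull", c(shape = 1.2, scale = 10),
                                      n = 80, admin_censor = 25, seed = 9))
  expect_warning(
    fx <- make_digitized_fixture(ipd, coord_step = 0.5, risk_interval = 5,
                                 jitter = 0.05, seed = 3),
    "clamped")
  expect_true(attr(fx, "n_clamped") > 0)
  expect_true(all(diff(fx$coords$surv) <= 0))
})

test_that("IPD and curve CSV round trips preserve the data", {
  ipd <- simulate_ipd(simulation_spec("weibull", c(shape = 1.5, scale = 18),
                                      n = 50, accrual_window = 6,
                                      admin_censor = 30, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ipd_csv(ipd, f)
  back <- read_ipd_csv(f)
  expect_equal(back$time, ipd$time, tolerance = 1e-12)
  expect_equal(back$event, ipd$event)

  fx <- make_digitized_fixture(ipd, coord_step = 2, risk_interval = 6)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(fx, f1, f2)
  back2 <- read_curve_csv(f1, f2, total_events = fx$total_events)
  expect_equal(back2$coords$surv, fx$coords$surv, tolerance = 1e-12)
  expect_equal(back2$risk_table$n_risk, fx$risk_table$n_risk)
})

test_that("invalid simulation specs are rejected", {
  expect_error(simulation_spec("weibull", c(shape = 1, scale = -2), n = 10),
               "strictly positive")
  expect_error(simulation_spec("nope", c(rate = 1), n = 10))
  expect_error(simulation_spec("exponential", c(rate = 1), n = 0), "n must be")
  expect_error(simulation_spec("exponential", c(rate = 1), n = 10,
                               accrual_window = 12, admin_censor = 6),
               "exceed accrual_window")
})
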