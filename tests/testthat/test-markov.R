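test_that("trace starts whole and conserves membership to 1e-12", {
  for (tr in list(TRACES_US$evp, TRACES_US$ngc)) {
    expect_equal(unlist(tr[1, c("pfs", "pd", "dead")]),
                 c(pfs = 1, pd = 0, dead = 0), tolerance = 1e-12)
    expect_lt(max(abs(tr$pfs + tr$pd + tr$dead - 1)), 1e-12)
    expect_true(all(diff(tr$dead) >= -1e-15))
    expect_true(all(tr$pd >= 0))
    expect_equal(tr$incident_deaths[-1], diff(tr$dead), tolerance = 1e-15)
  }
  expect_equal(nrow(TRACES_US$evp), 871)  # ceil(600 months / 21-day cycle) + origin
})

test_that("final-cycle death fractions reproduce the printed tail values", {
  expect_equal(round(100 * TRACES_US$evp$dead[871], 1), 97.9)
  expect_equal(round(100 * TRACES_US$ngc$dead[871], 1), 99.6)
})

test_that("the far-tail PFS/OS crossing in the N+GC arm is clamped with a warning", {
  expect_warning(
    build_trace(MODEL_NGC_PFS, MODEL_NGC_OS, model_settings()),
    "clamped")
  expect_gt(attr(TRACES_US$ngc, "n_clamped"), 0)
  expect_equal(attr(TRACES_US$evp, "n_clamped"), 0)
})

test_that("discount factors follow annual compounding identities", {
  expect_equal(discount_factor(12, 0.03), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(0, 0.08), 1)
  expect_true(all(discount_factor(c(1, 7, 600), 0) == 1))
  expect_equal(discount_factor(24, 0.05), discount_factor(12, 0.05)^2,
               tolerance = 1e-12)
  expect_error(discount_factor(12, -0.01), "annual_rate")
  expect_error(discount_factor(-1, 0.03), "t must be")
})

test_that("undiscounted unit-utility QALYs match an adaptive-quadrature restricted mean", {
  settings <- model_settings(discount_annual = 0)
  tr <- build_trace(MODEL_EVP_PFS, MODEL_EVP_OS, settings)
  u1 <- utility_set(1, 1)
  q <- discounted_qalys(tr, u1, settings)
  horizon <- settings$n_cycles * settings$cycle_months
  oracle <- stats::integrate(function(x) surv_prob(MODEL_EVP_OS, x),
                             0, horizon, rel.tol = 1e-10,
                             subdivisions = 1000L)$value / 12
  expect_lt(abs(q$total - oracle) / oracle, 0.005)
})

test_that("an all-dead trace accrues no QALYs", {
  settings <- model_settings()
  tr <- build_trace(MODEL_EVP_PFS, MODEL_EVP_OS, settings)
  tr$pfs <- tr$pd <- rep(0, nrow(tr)); tr$dead <- rep(1, nrow(tr))
  q <- discounted_qalys(tr, utility_set(0.772, 0.698), settings)
  expect_equal(q$total, 0)
})

test_that("halving the cycle length moves discounted QALYs by < 0.5%", {
  u <- utility_set(0.772, 0.698)
  s21 <- model_settings(cycle_days = 21, discount_annual = 0.03)
  s10 <- model_settings(cycle_days = 10.5, discount_annual = 0.03)
  q21 <- discounted_qalys(build_trace(MODEL_EVP_PFS, MODEL_EVP_OS, s21), u, s21)
  q10 <- discounted_qalys(build_trace(MODEL_EVP_PFS, MODEL_EVP_OS, s10), u, s10)
  expect_lt(abs(q21$total - q10$total) / q10$total, 0.005)
})

test_that("half-cycle correction lies between endpoint accrual sums", {
  settings <- model_settings(discount_annual = 0.03)
  tr <- build_trace(MODEL_EVP_PFS, MODEL_EVP_OS, settings)
  u <- utility_set(0.772, 0.698)
  q_mid <- discounted_qalys(tr, u, settings)$total
  # endpoint sums computed directly from the boundary memberships
  N <- settings$n_cycles
  dy <- settings$cycle_months / 12
  disc <- discount_factor((tr$t_months[-1] + tr$t_months[-(N + 1)]) / 2, 0.03)
  val <- function(idx) {
    sum(dy * (0.772 * tr$pfs[idx] + 0.698 * tr$pd[idx]) * disc)
  }
  left <- val(1:N); right <- val(2:(N + 1))
  expect_gte(q_mid, min(left, right))
  expect_lte(q_mid, max(left, right))
})

test_that("adverse-event disutility subtracts a one-cycle decrement", {
  settings <- model_settings()
  tr <- build_trace(MODEL_EVP_PFS, MODEL_EVP_OS, settings)
  ae <- data.frame(prob = c(0.041, 0.077), disutility = c(0.33, 0.032))
  q0 <- discounted_qalys(tr, utility_set(0.772, 0.698), settings)
  q1 <- discounted_qalys(tr, utility_set(0.772, 0.698, ae), settings)
  expected <- sum(ae$prob * ae$disutility) * settings$cycle_months / 12
  expect_equal(q0$total - q1$total, expected, tolerance = 1e-12)
})

test_that("landmark validation returns curve values and handles the origin", {
  val <- internal_validation(TRACES_US$evp, c(0, 12),
                             reference = data.frame(pfs = c(100, 51.4),
                                                    os = c(100, 77.7)))
  expect_equal(val$model_pfs_pct[1], 100)
  expect_equal(val$model_os_pct[1], 100)
  expect_equal(val$model_pfs_pct[2], 100 * surv_prob(MODEL_EVP_PFS, 12),
               tolerance = 1e-12)
  expect_equal(val$model_os_pct[2], 100 * surv_prob(MODEL_EVP_OS, 12),
               tolerance = 1e-12)
  expect_equal(val$ref_os_pct, c(100, 77.7))
  expect_error(internal_validation(TRACES_US$evp, 9999), "horizon")
})

test_that("settings validate their domains", {
  expect_error(model_settings(cycle_days = 0), "cycle_days")
  expect_error(model_settings(discount_annual = 1.2), "discount_annual")
  expect_error(model_settings(horizon_years = -1), "horizon_years")
  expect_error(utility_set(1.2, 0.5), "utilities")
  expect_error(utility_set(0.7, 0.5, data.frame(prob = 2, disutility = 0.1)),
               "probabilities")
})
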