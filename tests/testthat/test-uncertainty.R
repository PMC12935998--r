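test_that("parameter draws match their moment conventions", {
  specs <- rbind(
    param_spec("cost_x", "costs/bsc_cycle", 1000, 800, 1200, "gamma"),
    param_spec("util_x", "utilities/pfs", 0.772, 0.618, 0.926, "beta"),
    param_spec("weight", "population/weight_kg", 70, 56, 84, "uniform"),
    param_spec("fixed_x", "costs/terminal", 500, 500, 500, "fixed"))
  d <- draw_params(specs, n = 100000, seed = 42)
  expect_lt(abs(mean(d[, "cost_x"]) - 1000) / 1000, 0.01)   # gamma mean
  sd_target <- (1200 - 800) / 3.92
  expect_lt(abs(sd(d[, "cost_x"]) - sd_target) / sd_target, 0.02)
  expect_true(all(d[, "util_x"] >= 0 & d[, "util_x"] <= 1))  # beta support
  expect_lt(abs(mean(d[, "util_x"]) - 0.772), 0.002)
  expect_true(all(d[, "weight"] >= 56 & d[, "weight"] <= 84))
  expect_true(all(d[, "fixed_x"] == 500))
  # seed determinism
  expect_identical(draw_params(specs, n = 10, seed = 7),
                   draw_params(specs, n = 10, seed = 7))
})

test_that("infeasible beta moments fall back to uniform with a warning", {
  wide <- param_spec("p", "utilities/pd", 0.5, 0, 1, "beta")
  wide$high <- 3  # sd = 3/3.92 > sqrt(0.25)
  expect_warning(d <- draw_params(wide, n = 500, seed = 1), "uniform fallback")
  expect_true(all(d >= 0 & d <= 3))
})

test_that("config paths address scalar and adverse-event entries", {
  expect_equal(get_config_value(CFG_US, "drug_prices/ev_20mg"), 2751.73)
  expect_equal(get_config_value(CFG_US, "ae/evp/prob/2"), 0.077)
  cfg <- set_config_value(CFG_US, "ae/evp/prob/2", 0.1)
  expect_equal(cfg$ae$evp$prob[2], 0.1)
  expect_equal(CFG_US$ae$evp$prob[2], 0.077)  # original untouched
  expect_error(get_config_value(CFG_US, "no/such/key"), "no config value")
})

test_that("a degenerate range produces zero tornado span at the base ICER", {
  spec1 <- param_spec("fixed_price", "drug_prices/ev_20mg",
                      2751.73, 2751.73, 2751.73, "fixed")
  tor <- suppressWarnings(owsa(CFG_US, spec1))
  expect_equal(tor$span, 0, tolerance = 1e-9)
  expect_equal(tor$icer_low, attr(tor, "base_icer"), tolerance = 1e-9)
})

test_that("PFS utility ranks among the top five tornado parameters in both countries", {
  for (cfg in list(CFG_US, CFG_CN)) {
    tor <- suppressWarnings(owsa(cfg))
    expect_lte(match("utility_pfs", tor$name), 5)
    expect_false(any(tor$error))
  }
})

test_that("the ICER increases monotonically with the EV unit price", {
  base_price <- CFG_US$drug_prices$ev_20mg
  icers <- vapply(c(0.5, 1, 1.5), function(m) {
    cfg <- set_config_value(CFG_US, "drug_prices/ev_20mg", base_price * m)
    run_cea_quiet(cfg, TRACES_US)$icer
  }, numeric(1))
  expect_true(all(diff(icers) > 0))
})

test_that("the PSA is seed-deterministic and its CEAC behaves", {
  ps1 <- suppressWarnings(psa(CFG_US, n_draws = 300, seed = 42))
  ps2 <- suppressWarnings(psa(CFG_US, n_draws = 300, seed = 42))
  expect_identical(ps1$draws, ps2$draws)
  expect_identical(ps1$ceac, ps2$ceac)
  # CEAC at WTP 0 equals the fraction of draws where EV+P is cheaper
  expect_equal(ps1$ceac$prob_ce[ps1$ceac$wtp == 0],
               mean(ps1$draws$delta_cost < 0))
  # with all delta QALYs positive the CEAC is nondecreasing
  if (all(ps1$draws$delta_qaly > 0)) {
    expect_true(all(diff(ps1$ceac$prob_ce) >= 0))
  }
  expect_gte(min(ps1$draws$qaly_evp), 0)
})

test_that("one-way price threshold search brackets the WTP crossing", {
  # ICER is monotone in the multiplier over the scan
  scan <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(m) {
    cfg <- set_config_value(CFG_US, "drug_prices/ev_20mg",
                            CFG_US$drug_prices$ev_20mg * m)
    run_cea_quiet(cfg, TRACES_US)$icer
  }, numeric(1))
  expect_true(all(diff(scan) > 0))

  th <- suppressWarnings(price_threshold_oneway(CFG_US, "ev", wtp = 150000))
  expect_equal(th$status, "threshold")
  expect_true(th$multiplier > 0 && th$multiplier < 1)
  # the ICER at the found multiplier sits at the threshold
  cfg_star <- set_config_value(CFG_US, "drug_prices/ev_20mg",
                               CFG_US$drug_prices$ev_20mg * th$multiplier)
  expect_equal(run_cea_quiet(cfg_star, TRACES_US)$icer, 150000,
               tolerance = 1e-2)

  # a WTP above the base ICER needs no reduction
  base_icer <- run_cea_quiet(CFG_US, TRACES_US)$icer
  easy <- suppressWarnings(price_threshold_oneway(CFG_US, "ev",
                                                  wtp = base_icer * 2))
  expect_equal(easy$status, "already_cost_effective")
  expect_equal(easy$multiplier, 1)
})

test_that("two-way surface is monotone and its diagonal matches the joint scan", {
  grid <- c(0, 0.5, 1)
  tw <- suppressWarnings(price_threshold_twoway(CFG_CN, wtp = 40451.64,
                                                grid = grid))
  # multiplier (1,1) reproduces the base-case ICER
  base_icer <- run_cea_quiet(CFG_CN, TRACES_CN)$icer
  expect_equal(tw$surface$icer[tw$surface$m_ev == 1 & tw$surface$m_pembro == 1],
               base_icer, tolerance = 1e-9)
  # diagonal of the surface equals the one-way joint scan
  diag_from_surface <- vapply(grid, function(m) {
    tw$surface$icer[tw$surface$m_ev == m & tw$surface$m_pembro == m]
  }, numeric(1))
  expect_equal(diag_from_surface, tw$diagonal$icer, tolerance = 1e-9)
  # monotone nonincreasing in each price reduction (dominant draws map to
  # -Inf; clamp to a finite floor so equal infinities difference to zero)
  fin <- function(x) pmax(x, -1e300)
  for (m in grid) {
    row <- fin(tw$surface$icer[tw$surface$m_pembro == m])
    expect_true(all(diff(row) >= 0))  # increasing multiplier, increasing ICER
    col <- fin(tw$surface$icer[tw$surface$m_ev == m])
    expect_true(all(diff(col) >= 0))
  }
  expect_error(price_threshold_twoway(CFG_CN, grid = 1), "at least 2")
})
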