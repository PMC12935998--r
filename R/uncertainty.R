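#' Sensitivity-parameter specification table
#'
#' One row per uncertain input: its location in the configuration (a
#' `/`-separated path; numeric segments index adverse-event rows), the
#' base value, deterministic low/high range, and the probabilistic
#' distribution family.
#'
#' @param name Human-readable label.
#' @param path `/`-separated path into the configuration list.
#' @param base,low,high Base value and deterministic range
#'   (`low <= base <= high`).
#' @param dist One of `"gamma"`, `"beta"`, `"uniform"`, `"fixed"`.
#' @return One-row data frame; rows can be `rbind`-ed into a spec table.
#' @export
param_spec <- function(name, path, base, low, high,
                       dist = c("gamma", "beta", "uniform", "fixed")) {
  dist <- match.arg(dist)
  if (!(low <= base && base <= high)) {
    stop(sprintf("%s: need low <= base <= high", name), call. = FALSE)
  }
  if (dist == "beta" && (low < 0 || high > 1)) {
    stop(sprintf("%s: beta support must lie in [0, 1]", name), call. = FALSE)
  }
  data.frame(name = name, path = path, base = base, low = low, high = high,
             dist = dist, stringsAsFactors = FALSE)
}

#' Default sensitivity-parameter table for a configuration
#'
#' Enumerates every uncertain input with the conventions of the analysis:
#' gamma distributions and +/-20% ranges for unit costs and drug prices,
#' beta for utilities, adverse-event risks and disutilities (+/-20%
#' ranges, as printed in the input table), uniform for weight, body
#' surface area and the discount rate (guideline range 0-5% US, 0-8%
#' China). Survival-curve parameters are deliberately absent: no ranges
#' or distributions are published for them, so they are held fixed.
#'
#' @param config A validated configuration.
#' @return Data frame of [param_spec()] rows.
#' @export
default_param_specs <- function(config) {
  rel <- config$ranges$rel %||% 0.2
  rows <- list()
  add <- function(name, path, base, dist,
                  low = base * (1 - rel), high = base * (1 + rel)) {
    rows[[length(rows) + 1]] <<- param_spec(name, path, base, low, high, dist)
  }
  for (nm in names(config$drug_prices)) {
    add(paste0("price_", nm), paste0("drug_prices/", nm),
        config$drug_prices[[nm]], "gamma")
  }
  for (nm in names(config$costs)) {
    add(paste0("cost_", nm), paste0("costs/", nm),
        config$costs[[nm]], "gamma")
  }
  add("utility_pfs", "utilities/pfs", config$utilities$pfs, "beta")
  add("utility_pd", "utilities/pd", config$utilities$pd, "beta")
  for (arm in c("evp", "ngc")) {
    ae <- config$ae[[arm]]
    for (i in seq_len(nrow(ae))) {
      add(sprintf("ae_prob_%s_%s", arm, ae$name[i]),
          sprintf("ae/%s/prob/%d", arm, i), ae$prob[i], "beta")
      add(sprintf("ae_disutility_%s_%s", arm, ae$name[i]),
          sprintf("ae/%s/disutility/%d", arm, i), ae$disutility[i], "beta")
      add(sprintf("ae_cost_%s_%s", arm, ae$name[i]),
          sprintf("ae/%s/cost/%d", arm, i), ae$cost[i], "gamma")
    }
  }
  add("weight_kg", "population/weight_kg", config$population$weight_kg,
      "uniform")
  add("bsa_m2", "population/bsa_m2", config$population$bsa_m2, "uniform")
  dr <- config$ranges$discount_annual %||%
    c(0, config$settings$discount_annual * (1 + rel))
  add("discount_rate", "settings/discount_annual",
      config$settings$discount_annual, "uniform",
      low = dr[1], high = dr[2])
  do.call(rbind, rows)
}

## path helpers ------------------------------------------------------------

split_path <- function(path) strsplit(path, "/", fixed = TRUE)[[1]]

#' Get or set a configuration value by path
#'
#' @param config Configuration list.
#' @param path `/`-separated key path; an all-digit segment indexes a row
#'   of an adverse-event table (whose preceding segment is the column).
#' @param value Replacement value (for `set_config_value`).
#' @return The value at `path`, or the modified configuration.
#' @export
get_config_value <- function(config, path) {
  segs <- split_path(path)
  x <- config
  for (s in segs) {
    x <- if (grepl("^[0-9]+$", s)) x[[as.integer(s)]] else x[[s]]
    if (is.null(x)) stop("no config value at: ", path, call. = FALSE)
  }
  x
}

#' @rdname get_config_value
#' @export
set_config_value <- function(config, path, value) {
  segs <- split_path(path)
  rec <- function(x, segs) {
    s <- segs[1]
    key <- if (grepl("^[0-9]+$", s)) as.integer(s) else s
    if (length(segs) == 1) {
      x[[key]] <- value
    } else {
      x[[key]] <- rec(x[[key]], segs[-1])
    }
    x
  }
  rec(config, segs)
}

## numeric ICER for ordering/bisection: dominance maps to the signed
## extremes so "more favourable to EV+P" is always smaller
icer_ordinal <- function(res) {
  switch(res$icer_label,
    icer = res$icer,
    dominant = -Inf,
    dominated = Inf,
    equivalent = 0,
    zero_qaly = if (res$delta_cost > 0) Inf else -Inf)
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Re-runs the full two-arm model with each parameter at its low and high
#' bound, holding everything else at base, and records the resulting
#' ICERs. Rows are sorted by ICER span (descending); the base-case ICER
#' is attached as attribute `base_icer`.
#'
#' @param config A validated configuration.
#' @param specs Parameter table (default [default_param_specs()]).
#' @return Data frame `name, path, low, high, icer_low, icer_high, span`
#'   (failed rows keep `NA` ICERs and an `error` note).
#' @export
owsa <- function(config, specs = default_param_specs(config)) {
  traces <- config_traces(config)
  base <- run_cea(config, traces = traces)
  run_at <- function(path, value) {
    tryCatch({
      cfg <- set_config_value(config, path, value)
      icer_ordinal(run_cea(cfg, traces = traces))
    }, error = function(e) NA_real_)
  }
  n <- nrow(specs)
  icer_low <- icer_high <- numeric(n)
  for (i in seq_len(n)) {
    icer_low[i] <- run_at(specs$path[i], specs$low[i])
    icer_high[i] <- run_at(specs$path[i], specs$high[i])
  }
  out <- data.frame(
    name = specs$name, path = specs$path,
    low = specs$low, high = specs$high,
    icer_low = icer_low, icer_high = icer_high,
    span = abs(icer_high - icer_low),
    error = is.na(icer_low) | is.na(icer_high))
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- icer_ordinal(base)
  out
}

#' Draw parameter vectors for probabilistic sensitivity analysis
#'
#' Gamma and beta distributions are moment-matched to mean = base and
#' sd = (high - low)/3.92 (the range read as a 95% interval); uniform
#' draws on \[low, high\]; `"fixed"` always returns the base. A beta spec
#' whose moments are infeasible (sd too large for the \[0, 1\] support)
#' falls back to uniform with a warning.
#'
#' @param specs Parameter table (see [default_param_specs()]).
#' @param n Number of draws.
#' @param seed Optional RNG seed.
#' @return `n` x `nrow(specs)` matrix, columns named by `specs$name`.
#' @export
draw_params <- function(specs, n = 1, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  draws <- matrix(NA_real_, nrow = n, ncol = nrow(specs),
                  dimnames = list(NULL, specs$name))
  for (i in seq_len(nrow(specs))) {
    base <- specs$base[i]
    s <- (specs$high[i] - specs$low[i]) / 3.92
    draws[, i] <- switch(specs$dist[i],
      fixed = rep(base, n),
      uniform = stats::runif(n, specs$low[i], specs$high[i]),
      gamma = {
        if (s <= 0 || base <= 0) rep(base, n)
        else stats::rgamma(n, shape = (base / s)^2, rate = base / s^2)
      },
      beta = {
        if (s <= 0) rep(base, n)
        else if (s^2 >= base * (1 - base)) {
          warning(sprintf(
            "%s: beta moments infeasible (sd %.4g too large); uniform fallback",
            specs$name[i], s), call. = FALSE)
          stats::runif(n, specs$low[i], specs$high[i])
        } else {
          nu <- base * (1 - base) / s^2 - 1
          stats::rbeta(n, base * nu, (1 - base) * nu)
        }
      })
  }
  draws
}

#' Probabilistic sensitivity analysis with acceptability curve
#'
#' Redraws every uncertain input `n_draws` times (survival distributions
#' held fixed; see [default_param_specs()]), rebuilds both arms per draw,
#' and summarizes the incremental cost/QALY cloud as a cost-effectiveness
#' acceptability curve: the fraction of draws in which EV+P has the higher
#' net monetary benefit at each willingness-to-pay value.
#'
#' @param config A validated configuration.
#' @param specs Parameter table (default [default_param_specs()]).
#' @param n_draws Number of Monte-Carlo draws (default 10000).
#' @param seed RNG seed.
#' @param wtp_grid Willingness-to-pay grid for the CEAC; defaults to 41
#'   points from 0 to four times the configured threshold.
#' @return List: `draws` (per-draw arm costs/QALYs and increments),
#'   `ceac` (`wtp`, `prob_ce`), `prob_ce` (probability EV+P is
#'   cost-effective at the configured threshold), `n_draws`, `seed`.
#' @export
psa <- function(config, specs = default_param_specs(config),
                n_draws = 10000, seed = 1L, wtp_grid = NULL) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (is.null(wtp_grid)) {
    wtp_grid <- seq(0, 4 * config$wtp, length.out = 41)
  }
  traces <- config_traces(config)
  mat <- draw_params(specs, n = n_draws, seed = seed)
  cost_evp <- qaly_evp <- cost_ngc <- qaly_ngc <- numeric(n_draws)
  paths <- specs$path
  for (d in seq_len(n_draws)) {
    cfg <- config
    for (j in seq_along(paths)) {
      cfg <- set_config_value(cfg, paths[j], mat[d, j])
    }
    res <- run_cea(cfg, traces = traces)
    cost_evp[d] <- res$evp$cost; qaly_evp[d] <- res$evp$qalys
    cost_ngc[d] <- res$ngc$cost; qaly_ngc[d] <- res$ngc$qalys
  }
  draws <- data.frame(
    draw = seq_len(n_draws),
    cost_evp = cost_evp, qaly_evp = qaly_evp,
    cost_ngc = cost_ngc, qaly_ngc = qaly_ngc,
    delta_cost = cost_evp - cost_ngc, delta_qaly = qaly_evp - qaly_ngc)
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_ce = vapply(wtp_grid, function(w) {
      mean(w * draws$delta_qaly - draws$delta_cost > 0)
    }, numeric(1)))
  list(draws = draws, ceac = ceac,
       prob_ce = mean(config$wtp * draws$delta_qaly - draws$delta_cost > 0),
       n_draws = n_draws, seed = seed)
}

price_key <- function(component) {
  switch(match.arg(component, c("ev", "pembro", "nivo", "gem", "cis")),
    ev = "drug_prices/ev_20mg",
    pembro = "drug_prices/pembro_100mg",
    nivo = "drug_prices/nivo_40mg",
    gem = "drug_prices/gem_1000mg",
    cis = "drug_prices/cis_50mg")
}

## deterministic ICER as a function of price multipliers on one or more
## components, with traces cached
icer_at_multiplier <- function(config, components, m, traces) {
  cfg <- config
  m <- rep_len(m, length(components))
  for (i in seq_along(components)) {
    key <- price_key(components[i])
    cfg <- set_config_value(cfg, key, get_config_value(config, key) * m[i])
  }
  icer_ordinal(run_cea(cfg, traces = traces))
}

#' One-way drug-price threshold search
#'
#' Finds the price multiplier `m*` in \[0, 1\] at which the deterministic
#' ICER of EV+P versus N+GC equals the willingness-to-pay threshold
#' (bisection, tolerance 1e-4 on the multiplier). The ICER is monotone
#' nonincreasing in the price reduction, so the root is unique when it
#' exists.
#'
#' @param config A validated configuration.
#' @param component Drug whose unit price is scaled (default `"ev"`).
#' @param wtp Willingness-to-pay threshold (default the configured one).
#' @return List with `status` (`"threshold"`, `"already_cost_effective"`
#'   or `"unreachable"`), `multiplier` (`m*`, or `NA` if unreachable),
#'   `reduction_pct`, `icer_at_base`, `icer_at_zero`.
#' @export
price_threshold_oneway <- function(config, component = "ev",
                                   wtp = config$wtp) {
  traces <- config_traces(config)
  f <- function(m) icer_at_multiplier(config, component, m, traces)
  i1 <- f(1); i0 <- f(0)
  if (i1 <= wtp) {
    return(list(status = "already_cost_effective", multiplier = 1,
                reduction_pct = 0, icer_at_base = i1, icer_at_zero = i0))
  }
  if (i0 > wtp) {
    return(list(status = "unreachable", multiplier = NA_real_,
                reduction_pct = NA_real_, icer_at_base = i1,
                icer_at_zero = i0))
  }
  lo <- 0; hi <- 1
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (f(mid) > wtp) hi <- mid else lo <- mid
  }
  m_star <- (lo + hi) / 2
  list(status = "threshold", multiplier = m_star,
       reduction_pct = 100 * (1 - m_star),
       icer_at_base = i1, icer_at_zero = i0)
}

#' Two-way (joint) drug-price threshold analysis
#'
#' Scans a grid of independent price multipliers for enfortumab vedotin
#' and pembrolizumab and, on the diagonal (the same multiplier applied to
#' both drugs, i.e. a joint price reduction), bisects for the multiplier
#' at which the ICER crosses the willingness-to-pay threshold.
#'
#' @param config A validated configuration.
#' @param components The two drugs varied jointly (default EV and
#'   pembrolizumab).
#' @param wtp Willingness-to-pay threshold (default the configured one).
#' @param grid Multiplier grid per axis (default 0, 0.1, ..., 1; at least
#'   two points).
#' @return List: `status`/`multiplier`/`reduction_pct` for the joint
#'   diagonal threshold, `diagonal` (data frame `multiplier`, `icer`),
#'   and `surface` (data frame `m_ev`, `m_pembro`, `icer`).
#' @export
price_threshold_twoway <- function(config, components = c("ev", "pembro"),
                                   wtp = config$wtp,
                                   grid = seq(0, 1, by = 0.1)) {
  if (length(grid) < 2) stop("grid needs at least 2 points", call. = FALSE)
  if (length(components) != 2) stop("need exactly 2 components", call. = FALSE)
  traces <- config_traces(config)
  f2 <- function(m1, m2) {
    icer_at_multiplier(config, components, c(m1, m2), traces)
  }
  diag_tab <- data.frame(
    multiplier = grid,
    icer = vapply(grid, function(m) f2(m, m), numeric(1)))
  surf <- expand.grid(m_ev = grid, m_pembro = grid)
  surf$icer <- mapply(f2, surf$m_ev, surf$m_pembro)
  i1 <- f2(1, 1); i0 <- f2(0, 0)
  if (i1 <= wtp) {
    status <- "already_cost_effective"; m_star <- 1
  } else if (i0 > wtp) {
    status <- "unreachable"; m_star <- NA_real_
  } else {
    lo <- 0; hi <- 1
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      if (f2(mid, mid) > wtp) hi <- mid else lo <- mid
    }
    status <- "threshold"; m_star <- (lo + hi) / 2
  }
  list(status = status, multiplier = m_star,
       reduction_pct = if (is.na(m_star)) NA_real_ else 100 * (1 - m_star),
       diagonal = diag_tab, surface = surf)
}
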