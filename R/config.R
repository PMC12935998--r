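#' Built-in base-case analysis configuration
#'
#' Returns the complete model configuration for one country: settings,
#' representative patient (weight, body surface area), the four fitted
#' survival distributions, health-state utilities, per-vial drug prices,
#' all other unit costs (2025 USD), the five most frequent grade >= 3
#' adverse events per arm with risks, one-cycle disutilities and
#' per-event management costs, the willingness-to-pay threshold
#' ($150,000/QALY US; $40,451.64/QALY China = 3x 2024 GDP per capita),
#' and sensitivity ranges. Bundled YAML copies of these configurations
#' live in `inst/extdata/` and load identically via [load_config()].
#'
#' @param country `"us"` or `"china"`.
#' @return A validated configuration list.
#' @export
default_config <- function(country = c("us", "china")) {
  country <- match.arg(country)
  us <- country == "us"
  ae_evp <- data.frame(
    name = c("peripheral_sensory_neuropathy", "maculopapular_rash",
             "diarrhea", "anemia", "neutropenia"),
    prob = c(0.041, 0.077, 0.039, 0.036, 0.052),
    disutility = c(0.33, 0.032, 0.05, 0.07, 0.09),
    cost = if (us) c(24918.40, 16337.36, 7968.48, 4823.52, 17868.24)
           else c(16089.48, 85.81, 15016.71, 140.55, 116.51))
  ae_ngc <- data.frame(
    name = c("decreased_platelet_count", "neutropenia",
             "decreased_neutrophil_count", "anemia",
             "decreased_white_cell_count"),
    prob = c(0.076, 0.188, 0.145, 0.22, 0.099),
    disutility = c(0.05, 0.09, 0.20, 0.07, 0.20),
    cost = if (us) c(8608.13, 17868.24, 37550.24, 4823.52, 13506.01)
           else c(1525.50, 116.51, 116.51, 140.55, 114.81))
  cfg <- list(
    country = country,
    wtp = if (us) 150000 else 40451.64,
    settings = list(
      cycle_days = 21, horizon_years = 50,
      discount_annual = if (us) 0.03 else 0.05,
      half_cycle = TRUE),
    population = list(
      weight_kg = if (us) 70 else 65,
      bsa_m2 = if (us) 1.86 else 1.72),
    survival = list(
      evp = list(
        pfs = list(family = "lognormal",
                   params = list(meanlog = 2.6709, sdlog = 1.4649)),
        os = list(family = "loglogistic",
                  params = list(shape = 1.3124, scale = 32.1285))),
      ngc = list(
        pfs = list(family = "gengamma",
                   params = list(mu = 1.9794, sigma = 1.1635, Q = -0.6043)),
        os = list(family = "lognormal",
                  params = list(meanlog = 3.1474, sdlog = 1.2350)))),
    utilities = list(pfs = 0.772, pd = 0.698),
    drug_prices = list(
      ev_20mg = if (us) 2751.73 else 740.14,
      pembro_100mg = if (us) 5884.02 else 2541.56,
      nivo_40mg = if (us) 1301.04 else 650.60,
      gem_1000mg = if (us) 20.93 else 5.74,
      cis_50mg = if (us) 10.55 else 8.19),
    costs = list(
      second_line_cycle = if (us) 1358.58 else 157.38,
      bsc_cycle = if (us) 1374.00 else 711.00,
      imaging_cycle = if (us) 942.00 else 143.00,
      administration = if (us) 894.00 else 404.79,
      labs_radiology = if (us) 2458.04 else 672.02,
      hospitalization = if (us) 1522.56 else 47.32,
      followup = if (us) 318.16 else 27.37,
      terminal = if (us) 6246.00 else 1761.00),
    ae = list(evp = ae_evp, ngc = ae_ngc),
    options = list(second_line_cycles = 6, vial_sharing = FALSE),
    ranges = list(
      # deterministic range conventions: +/-20% on costs, prices,
      # utilities, disutilities and AE risks (the printed table ranges);
      # guideline ranges on the discount rate
      discount_annual = if (us) c(0, 0.05) else c(0, 0.08),
      rel = 0.2))
  validate_config(cfg)
}

#' Validate an analysis configuration
#'
#' Checks the schema (exact top-level key set, no unknown keys), types,
#' positivity/interval constraints, and survival-family validity. Errors
#' name the offending key path.
#'
#' @param config Configuration list.
#' @return The (normalized) configuration, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  want <- c("country", "wtp", "settings", "population", "survival",
            "utilities", "drug_prices", "costs", "ae", "options", "ranges")
  missing_keys <- setdiff(want, names(config))
  if (length(missing_keys)) {
    stop("config is missing keys: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(config), want)
  if (length(unknown)) {
    stop("config has unknown keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!config$country %in% c("us", "china")) {
    stop("country: must be 'us' or 'china'", call. = FALSE)
  }
  if (!is.numeric(config$wtp) || config$wtp <= 0) {
    stop("wtp: must be a positive number", call. = FALSE)
  }
  bad <- character(0)
  for (nm in names(config$drug_prices)) {
    v <- config$drug_prices[[nm]]
    if (!is.numeric(v) || v < 0) bad <- c(bad, paste0("drug_prices/", nm))
  }
  for (nm in names(config$costs)) {
    v <- config$costs[[nm]]
    if (!is.numeric(v) || v < 0) bad <- c(bad, paste0("costs/", nm))
  }
  if (length(bad)) {
    stop("negative or non-numeric cost at: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("pfs", "pd")) {
    u <- config$utilities[[nm]]
    if (!is.numeric(u) || u < 0 || u > 1) {
      stop("utilities/", nm, ": must lie in [0, 1]", call. = FALSE)
    }
  }
  if (config$population$weight_kg <= 0 || config$population$bsa_m2 <= 0) {
    stop("population: weight_kg and bsa_m2 must be > 0", call. = FALSE)
  }
  # normalize AE tables (YAML gives lists of records) and validate
  for (arm in c("evp", "ngc")) {
    ae <- config$ae[[arm]]
    if (!is.data.frame(ae)) {
      ae <- do.call(rbind, lapply(ae, as.data.frame))
    }
    need <- c("name", "prob", "disutility", "cost")
    if (!all(need %in% names(ae))) {
      stop("ae/", arm, ": needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (any(ae$prob < 0 | ae$prob > 1)) {
      stop("ae/", arm, "/prob: must lie in [0, 1]", call. = FALSE)
    }
    if (any(ae$disutility < 0) || any(ae$cost < 0)) {
      stop("ae/", arm, ": disutility and cost must be >= 0", call. = FALSE)
    }
    config$ae[[arm]] <- ae
  }
  # survival blocks must construct valid models
  for (arm in c("evp", "ngc")) {
    for (curve in c("pfs", "os")) {
      blk <- config$survival[[arm]][[curve]]
      if (is.null(blk)) {
        stop("survival/", arm, "/", curve, ": missing", call. = FALSE)
      }
      parametric_model(blk$family, blk$params)
    }
  }
  s <- config$settings
  if (s$discount_annual < 0 || s$discount_annual > 1) {
    stop("settings/discount_annual: must lie in [0, 1]", call. = FALSE)
  }
  model_settings(s$cycle_days, s$horizon_years, s$discount_annual,
                 s$half_cycle)
  config
}

#' Load and validate a configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON) configuration document with the
#'   same structure as [default_config()].
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

#' Write a configuration to YAML
#'
#' Inverse of [load_config()]; a load -> write -> load round trip is
#' idempotent.
#'
#' @param config Configuration list.
#' @param path Output file path.
#' @export
write_config <- function(config, path) {
  cfg <- config
  # serialize AE tables as lists of records for readable YAML
  for (arm in c("evp", "ngc")) {
    ae <- cfg$ae[[arm]]
    if (is.data.frame(ae)) {
      cfg$ae[[arm]] <- lapply(seq_len(nrow(ae)), function(i) {
        list(name = ae$name[i], prob = ae$prob[i],
             disutility = ae$disutility[i], cost = ae$cost[i])
      })
    }
  }
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' Country-level cost and dosing inputs from a configuration
#'
#' Bundles the monetary, dosing and adverse-event inputs consumed by the
#' costing functions.
#'
#' @param config A validated configuration (see [default_config()]).
#' @return Object of class `country_inputs`.
#' @export
country_inputs <- function(config) {
  structure(list(
    country = config$country,
    weight_kg = config$population$weight_kg,
    bsa_m2 = config$population$bsa_m2,
    drug_prices = config$drug_prices,
    costs = config$costs,
    ae = config$ae,
    second_line_cycles = config$options$second_line_cycles %||% 6,
    sharing = isTRUE(config$options$vial_sharing)),
    class = "country_inputs")
}

config_settings <- function(config) {
  s <- config$settings
  model_settings(s$cycle_days, s$horizon_years, s$discount_annual,
                 s$half_cycle)
}

config_model <- function(config, arm, curve) {
  blk <- config$survival[[arm]][[curve]]
  parametric_model(blk$family, blk$params)
}

#' Build the two cohort traces of a configuration
#'
#' @param config A validated configuration.
#' @return Named list of [build_trace()] results (`evp`, `ngc`). Traces
#'   depend only on the survival distributions and the cycle grid, so
#'   they can be reused across cost/utility sensitivity runs.
#' @export
config_traces <- function(config) {
  settings <- config_settings(config)
  list(
    evp = build_trace(config_model(config, "evp", "pfs"),
                      config_model(config, "evp", "os"), settings),
    ngc = build_trace(config_model(config, "ngc", "pfs"),
                      config_model(config, "ngc", "os"), settings))
}

#' Run the deterministic base-case analysis
#'
#' Builds (or reuses) the cohort traces, accrues discounted QALYs and
#' costs per arm, and compares the arms at the configured
#' willingness-to-pay threshold.
#'
#' @param config A validated configuration.
#' @param traces Optional precomputed [config_traces()] (used by the
#'   sensitivity analyses, whose parameter draws never alter the survival
#'   distributions).
#' @return A `cea_result` (see [compare_arms()]); the traces used are
#'   attached as attribute `traces`.
#' @export
run_cea <- function(config, traces = NULL) {
  settings <- config_settings(config)
  if (is.null(traces)) traces <- config_traces(config)
  inputs <- country_inputs(config)
  results <- lapply(c(evp = "evp", ngc = "ngc"), function(arm) {
    us <- utility_set(config$utilities$pfs, config$utilities$pd,
                      ae = inputs$ae[[arm]])
    q <- discounted_qalys(traces[[arm]], us, settings)
    cost <- arm_total_cost(traces[[arm]], arm, inputs, settings,
                           second_line_cycles = inputs$second_line_cycles,
                           sharing = inputs$sharing)
    arm_result(arm, cost, q$total, country = config$country)
  })
  res <- compare_arms(results$evp, results$ngc, wtps = config$wtp)
  attr(res, "traces") <- traces
  res
}

## tiny deterministic FNV-1a style hash of the serialized config, so
## pipeline outputs can be tied back to the exact inputs that made them
config_hash <- function(config) {
  txt <- yaml::as.yaml(config, precision = 12)
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline and write results to disk
#'
#' Stages: `"base"` (deterministic CEA + cohort traces + landmark
#' validation), `"owsa"` (tornado table), `"psa"` (probabilistic draws and
#' acceptability curve), `"threshold"` (one-way and joint price
#' thresholds). Every output directory gets the configuration copy, its
#' hash, and a run log recording seeds and warning counters.
#'
#' @param config A validated configuration.
#' @param stages Subset of `c("base", "owsa", "psa", "threshold")`.
#' @param out_dir Output directory (created if needed).
#' @param n_draws PSA draw count (default 10000).
#' @param seed RNG seed for the PSA.
#' @return Invisible list of the in-memory results per stage.
#' @export
run_pipeline <- function(config, stages = c("base", "owsa", "psa", "threshold"),
                         out_dir, n_draws = 10000, seed = 1L) {
  ok <- c("base", "owsa", "psa", "threshold")
  bad <- setdiff(stages, ok)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; must be among ", paste(ok, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  write_config(config, file.path(out_dir, "config.yaml"))
  log_lines <- c(
    sprintf("uccea run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("config_hash %s", hash),
    sprintf("country %s", config$country),
    sprintf("seed %d", as.integer(seed)),
    sprintf("stages %s", paste(stages, collapse = ",")))
  results <- list()
  traces <- config_traces(config)

  if ("base" %in% stages) {
    base <- run_cea(config, traces = traces)
    results$base <- base
    for (arm in c("evp", "ngc")) {
      tr <- traces[[arm]]
      utils::write.csv(
        cbind(as.data.frame(tr), config_hash = hash),
        file.path(out_dir, sprintf("trace_%s.csv", arm)), row.names = FALSE)
    }
    jsonlite::write_json(
      list(config_hash = hash, country = config$country,
           evp = list(cost = base$evp$cost, qalys = base$evp$qalys,
                      breakdown = unclass(base$evp$breakdown)),
           ngc = list(cost = base$ngc$cost, qalys = base$ngc$qalys,
                      breakdown = unclass(base$ngc$breakdown)),
           delta_cost = base$delta_cost, delta_qaly = base$delta_qaly,
           icer = base$icer, icer_label = base$icer_label,
           wtp = base$wtp_table),
      file.path(out_dir, "cea_result.json"), auto_unbox = TRUE, digits = NA)
    val <- internal_validation(traces$evp, c(12))
    utils::write.csv(val, file.path(out_dir, "validation_evp.csv"),
                     row.names = FALSE)
    log_lines <- c(log_lines,
      sprintf("base icer %s", format(base$icer)),
      sprintf("trace_clamps evp=%d ngc=%d",
              attr(traces$evp, "n_clamped"), attr(traces$ngc, "n_clamped")))
  }
  if ("owsa" %in% stages) {
    tor <- owsa(config)
    results$owsa <- tor
    utils::write.csv(cbind(tor, config_hash = hash),
                     file.path(out_dir, "tornado.csv"), row.names = FALSE)
  }
  if ("psa" %in% stages) {
    ps <- psa(config, n_draws = n_draws, seed = seed)
    results$psa <- ps
    utils::write.csv(cbind(ps$draws, config_hash = hash),
                     file.path(out_dir, "psa_draws.csv"), row.names = FALSE)
    utils::write.csv(cbind(ps$ceac, config_hash = hash),
                     file.path(out_dir, "ceac.csv"), row.names = FALSE)
    log_lines <- c(log_lines,
      sprintf("psa n_draws %d prob_ce %.4f", n_draws, ps$prob_ce))
  }
  if ("threshold" %in% stages) {
    th1 <- price_threshold_oneway(config, "ev", config$wtp)
    th2 <- price_threshold_twoway(config, wtp = config$wtp)
    results$threshold <- list(oneway = th1, twoway = th2)
    utils::write.csv(cbind(th2$diagonal, config_hash = hash),
                     file.path(out_dir, "price_diagonal.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, oneway_ev = th1[c("status", "multiplier")],
           joint = th2[c("status", "multiplier")]),
      file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}
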