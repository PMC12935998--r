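#' Vials needed for one administration
#'
#' Base case rounds partial vials up (wastage); with `sharing = TRUE` the
#' exact fractional ratio is costed (vial sharing policy scenario).
#'
#' @param dose_mg Administered dose in mg (> 0).
#' @param vial_mg Vial size in mg (> 0).
#' @param sharing Logical; share vials across patients.
#' @return Vial count (integer unless `sharing`).
#' @export
vials_needed <- function(dose_mg, vial_mg, sharing = FALSE) {
  if (any(dose_mg <= 0) || any(vial_mg <= 0)) {
    stop("dose_mg and vial_mg must be > 0", call. = FALSE)
  }
  if (sharing) dose_mg / vial_mg else ceiling(dose_mg / vial_mg)
}

#' One drug component of a regimen
#'
#' @param name Component label.
#' @param dosing One of `"per_kg"`, `"per_m2"`, `"flat"`.
#' @param dose_value Dose in mg (per kg / per m2 / absolute).
#' @param vial_mg Vial size in mg.
#' @param unit_cost Cost per vial (2025 USD).
#' @param admins_per_cycle Administrations per 21-day cycle.
#' @param first_cycle,last_cycle Active cycle window (1-based, inclusive).
#' @param rate_scale Multiplier converting an off-grid schedule to a
#'   per-cycle cost rate (e.g. 21/28 for an every-4-week drug costed on a
#'   21-day grid); default 1.
#' @return Object of class `drug_component`.
#' @export
drug_component <- function(name, dosing, dose_value, vial_mg, unit_cost,
                           admins_per_cycle = 1, first_cycle = 1,
                           last_cycle = Inf, rate_scale = 1) {
  dosing <- match.arg(dosing, c("per_kg", "per_m2", "flat"))
  if (dose_value <= 0 || vial_mg <= 0) {
    stop("dose_value and vial_mg must be > 0", call. = FALSE)
  }
  if (unit_cost < 0) stop("unit_cost must be >= 0", call. = FALSE)
  if (last_cycle < first_cycle) stop("empty active window", call. = FALSE)
  structure(list(name = name, dosing = dosing, dose_value = dose_value,
                 vial_mg = vial_mg, unit_cost = unit_cost,
                 admins_per_cycle = admins_per_cycle,
                 first_cycle = first_cycle, last_cycle = last_cycle,
                 rate_scale = rate_scale), class = "drug_component")
}

component_dose <- function(comp, inputs) {
  switch(comp$dosing,
    per_kg = comp$dose_value * inputs$weight_kg,
    per_m2 = comp$dose_value * inputs$bsa_m2,
    flat   = comp$dose_value)
}

#' Regimen definition for one arm
#'
#' Builds the drug-component list for an arm from country inputs:
#' \describe{
#'   \item{evp}{enfortumab vedotin 1.25 mg/kg on days 1 and 8 (no cap) plus
#'     pembrolizumab 200 mg on day 1 for at most 35 cycles.}
#'   \item{ngc}{nivolumab 360 mg, gemcitabine 1000 mg/m2 (days 1 and 8) and
#'     cisplatin 70 mg/m2, each for six cycles; then maintenance nivolumab
#'     480 mg every 4 weeks (costed at 21/28 per cycle) for up to 24 months
#'     of maintenance.}
#' }
#'
#' @param arm `"evp"` or `"ngc"`.
#' @param inputs A [country_inputs()].
#' @param settings A [model_settings()] (for the maintenance window).
#' @return List of [drug_component()]s.
#' @export
arm_regimen <- function(arm, inputs, settings = model_settings()) {
  arm <- match.arg(arm, c("evp", "ngc"))
  pr <- inputs$drug_prices
  if (arm == "evp") {
    list(
      drug_component("enfortumab_vedotin", "per_kg", 1.25, 20,
                     pr$ev_20mg, admins_per_cycle = 2),
      drug_component("pembrolizumab", "flat", 200, 100,
                     pr$pembro_100mg, admins_per_cycle = 1, last_cycle = 35))
  } else {
    maint_last <- 6 + ceiling(24 / settings$cycle_months)
    list(
      drug_component("nivolumab", "flat", 360, 40, pr$nivo_40mg,
                     admins_per_cycle = 1, last_cycle = 6),
      drug_component("gemcitabine", "per_m2", 1000, 1000, pr$gem_1000mg,
                     admins_per_cycle = 2, last_cycle = 6),
      drug_component("cisplatin", "per_m2", 70, 50, pr$cis_50mg,
                     admins_per_cycle = 1, last_cycle = 6),
      drug_component("nivolumab_maintenance", "flat", 480, 40, pr$nivo_40mg,
                     admins_per_cycle = 1, first_cycle = 7,
                     last_cycle = maint_last, rate_scale = 21 / 28))
  }
}

#' First-line drug acquisition cost for one cycle
#'
#' Sums vial-rounded component costs whose active window contains the
#' cycle (per-cycle rate scaling applied for off-grid schedules).
#'
#' @param arm `"evp"` or `"ngc"`.
#' @param cycle_index Cycle number (1-based); vectorized.
#' @param inputs A [country_inputs()].
#' @param sharing Vial sharing flag (see [vials_needed()]).
#' @param settings A [model_settings()].
#' @return Cost in USD per cycle while on treatment.
#' @export
cycle_drug_cost <- function(arm, cycle_index, inputs, sharing = FALSE,
                            settings = model_settings()) {
  if (any(cycle_index < 1)) stop("cycle_index must be >= 1", call. = FALSE)
  comps <- arm_regimen(arm, inputs, settings)
  out <- numeric(length(cycle_index))
  for (comp in comps) {
    per_admin <- vials_needed(component_dose(comp, inputs), comp$vial_mg,
                              sharing) * comp$unit_cost
    active <- cycle_index >= comp$first_cycle & cycle_index <= comp$last_cycle
    out <- out + active * per_admin * comp$admins_per_cycle * comp$rate_scale
  }
  out
}

#' Expected adverse-event burden for one arm
#'
#' Dot products of the grade >= 3 event risks with per-event management
#' costs and with one-cycle utility decrements; both applied once at model
#' entry.
#'
#' @param arm `"evp"` or `"ngc"`.
#' @param inputs A [country_inputs()].
#' @return List with `cost` (USD) and `disutility` (utility units; the
#'   QALY decrement is `disutility * cycle_months / 12`).
#' @export
ae_burden <- function(arm, inputs) {
  arm <- match.arg(arm, c("evp", "ngc"))
  ae <- inputs$ae[[arm]]
  if (is.null(ae) || nrow(ae) == 0) return(list(cost = 0, disutility = 0))
  if (any(ae$prob < 0 | ae$prob > 1)) {
    stop("ae probabilities must lie in [0, 1]", call. = FALSE)
  }
  list(cost = sum(ae$prob * ae$cost),
       disutility = sum(ae$prob * ae$disutility))
}

#' Total discounted cost of one arm
#'
#' Drives per-cycle accrual with half-cycle-corrected state memberships:
#' progression-free members accrue first-line drugs (subject to component
#' caps), administration, and monitoring (imaging, laboratory/radiology,
#' hospitalization and daily care); progressed members accrue second-line
#' therapy plus imaging and routine follow-up for the first
#' `second_line_cycles` cycles after progression (per-entrant schedule),
#' then best supportive care plus routine follow-up; terminal care is a
#' one-off per incident death, discounted at the cycle boundary; expected
#' adverse-event management cost is applied once at entry.
#'
#' @param trace A [build_trace()] result.
#' @param arm `"evp"` or `"ngc"`.
#' @param inputs A [country_inputs()].
#' @param settings The [model_settings()] used for the trace.
#' @param second_line_cycles Expected second-line duration K in cycles
#'   (default from `inputs$second_line_cycles`, itself defaulting to 6 —
#'   one full gemcitabine-cisplatin course).
#' @param sharing Vial sharing flag.
#' @return List of class `cost_breakdown`: discounted USD by category
#'   (`drugs`, `administration`, `monitoring`, `ae`, `second_line`, `bsc`,
#'   `terminal`) and `total`.
#' @export
arm_total_cost <- function(trace, arm, inputs, settings,
                           second_line_cycles = NULL, sharing = FALSE) {
  arm <- match.arg(arm, c("evp", "ngc"))
  tr_set <- attr(trace, "settings")
  if (!is.null(tr_set) && tr_set$n_cycles != settings$n_cycles) {
    stop("trace was built with different settings", call. = FALSE)
  }
  K <- second_line_cycles %||% inputs$second_line_cycles %||% 6
  acc <- trace_accrual(trace, settings)
  N <- settings$n_cycles
  cyc <- seq_len(N)
  co <- inputs$costs

  drug_per_cycle <- cycle_drug_cost(arm, cyc, inputs, sharing, settings)
  on_tx <- drug_per_cycle > 0
  drugs <- sum(drug_per_cycle * acc$pfs * acc$disc_mid)
  administration <- sum(co$administration * on_tx * acc$pfs * acc$disc_mid)
  monitoring <- sum((co$imaging_cycle + co$labs_radiology +
                       co$hospitalization) * acc$pfs * acc$disc_mid)

  # progression inflow per cycle (PFS-curve decline) feeds a K-cycle
  # second-line window; occupancy is capped by actual PD membership
  inflow <- pmax(0, -diff(trace$pfs))
  sl_window <- stats::filter(inflow, rep(1, K), sides = 1)
  sl_window[is.na(sl_window)] <- cumsum(inflow)[is.na(sl_window)]
  sl_occ <- pmin(acc$pd, as.numeric(sl_window))
  post_sl <- acc$pd - sl_occ
  second_line <- sum(sl_occ * (co$second_line_cycle + co$imaging_cycle +
                                 co$followup) * acc$disc_mid)
  bsc <- sum(post_sl * (co$bsc_cycle + co$followup) * acc$disc_mid)

  terminal <- co$terminal * sum(trace$incident_deaths[-1] * acc$disc_bound)
  ae <- ae_burden(arm, inputs)$cost

  out <- list(drugs = drugs, administration = administration,
              monitoring = monitoring, ae = ae, second_line = second_line,
              bsc = bsc, terminal = terminal)
  out$total <- sum(unlist(out))
  class(out) <- "cost_breakdown"
  out
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown> (discounted USD)\n")
  for (nm in setdiff(names(x), "total")) {
    cat(sprintf("  %-15s %14.2f\n", nm, x[[nm]]))
  }
  cat(sprintf("  %-15s %14.2f\n", "total", x$total))
  invisible(x)
}
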