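#' Cohort model settings
#'
#' The simulation runs in 21-day cycles over a 50-year horizon with
#' country-specific annual discounting (3% US, 5% China) and half-cycle
#' correction. Time is in months (one month = 365.25/12 days), so one
#' cycle is 21/(365.25/12) = 0.6899 months and the horizon spans
#' ceil(600 / cycle) = 870 cycles.
#'
#' @param cycle_days Cycle length in days (default 21).
#' @param horizon_years Model horizon in years (default 50).
#' @param discount_annual Annual discount rate in \[0, 1\].
#' @param half_cycle Apply half-cycle correction (default `TRUE`).
#' @return Object of class `model_settings` with derived fields
#'   `cycle_months` and `n_cycles`.
#' @export
model_settings <- function(cycle_days = 21, horizon_years = 50,
                           discount_annual = 0.03, half_cycle = TRUE) {
  if (cycle_days <= 0) stop("cycle_days must be > 0", call. = FALSE)
  if (horizon_years <= 0) stop("horizon_years must be > 0", call. = FALSE)
  if (discount_annual < 0 || discount_annual > 1) {
    stop("discount_annual must be in [0, 1]", call. = FALSE)
  }
  month_days <- 365.25 / 12
  cycle_months <- cycle_days / month_days
  horizon_months <- horizon_years * 12
  structure(list(
    cycle_days = cycle_days, horizon_years = horizon_years,
    discount_annual = discount_annual, half_cycle = isTRUE(half_cycle),
    month_days = month_days, cycle_months = cycle_months,
    n_cycles = as.integer(ceiling(horizon_months / cycle_months))),
    class = "model_settings")
}

#' Discount factor at a time point
#'
#' Annual compounding with fractional exponents:
#' `(1 + rate)^(-t / 12)` for `t` in months.
#'
#' @param t Time in months (>= 0).
#' @param annual_rate Annual discount rate (>= 0).
#' @return Discount factor(s) in (0, 1\].
#' @export
discount_factor <- function(t, annual_rate) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (annual_rate < 0) stop("annual_rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-t / 12)
}

#' Build the three-state cohort trace from PFS and OS curves
#'
#' Partitioned-survival accounting: at each cycle boundary t,
#' progression-free membership is S_PFS(t), death is 1 - S_OS(t), and
#' progressed disease is the difference S_OS(t) - S_PFS(t), clamped at
#' zero where independently extrapolated curves cross in the tail (the
#' clamp count is recorded and a warning is raised when more than 5% of
#' cycles are clamped).
#'
#' @param pfs_model,os_model [parametric_model()] objects for
#'   progression-free and overall survival (months).
#' @param settings A [model_settings()].
#' @return Data frame of class `cohort_trace` with one row per cycle
#'   boundary (cycle 0 .. n_cycles): `cycle`, `t_months`, `pfs`, `pd`,
#'   `dead`, `incident_deaths` (deaths during the cycle ending at this
#'   boundary). The two curves and the settings are attached as
#'   attributes.
#' @export
build_trace <- function(pfs_model, os_model, settings) {
  stopifnot_model(pfs_model); stopifnot_model(os_model)
  if (!inherits(settings, "model_settings")) {
    stop("expected 'model_settings'", call. = FALSE)
  }
  N <- settings$n_cycles
  tk <- (0:N) * settings$cycle_months
  s_pfs <- surv_prob(pfs_model, tk)
  s_os <- surv_prob(os_model, tk)
  pd_raw <- s_os - s_pfs
  clamped <- pd_raw < 0
  pd <- pmax(pd_raw, 0)
  pfs <- s_pfs - pmax(-pd_raw, 0)  # keep memberships summing to one
  pfs <- pmin(pfs, s_os)
  dead <- 1 - s_os
  if (mean(clamped) > 0.05) {
    warning(sprintf("PFS exceeds OS at %.1f%% of cycle boundaries; PD clamped",
                    100 * mean(clamped)), call. = FALSE)
  }
  out <- data.frame(
    cycle = 0:N, t_months = tk, pfs = pfs, pd = pd, dead = dead,
    incident_deaths = c(0, diff(dead)))
  class(out) <- c("cohort_trace", "data.frame")
  attr(out, "settings") <- settings
  attr(out, "pfs_model") <- pfs_model
  attr(out, "os_model") <- os_model
  attr(out, "n_clamped") <- sum(clamped)
  out
}

## cycle-level helper: half-cycle-corrected memberships, midpoint times
## and discount factors shared by QALY and cost accrual
trace_accrual <- function(trace, settings) {
  N <- settings$n_cycles
  stopifnot(nrow(trace) == N + 1)
  b <- function(x) if (settings$half_cycle) (x[-1] + x[-(N + 1)]) / 2 else x[-1]
  t_mid <- if (settings$half_cycle) {
    (trace$t_months[-1] + trace$t_months[-(N + 1)]) / 2
  } else trace$t_months[-1]
  list(pfs = b(trace$pfs), pd = b(trace$pd), dead = b(trace$dead),
       t_mid = t_mid,
       disc_mid = discount_factor(t_mid, settings$discount_annual),
       disc_bound = discount_factor(trace$t_months[-1],
                                    settings$discount_annual))
}

#' Health-state utilities and adverse-event disutilities for one arm
#'
#' @param u_pfs,u_pd Utilities of the progression-free and progressed
#'   states, in \[0, 1\].
#' @param ae Optional data frame with columns `prob` (grade >= 3 event
#'   risk) and `disutility` (one-cycle utility decrement), one row per
#'   adverse event.
#' @return Object of class `utility_set`.
#' @export
utility_set <- function(u_pfs, u_pd, ae = NULL) {
  if (u_pfs < 0 || u_pfs > 1 || u_pd < 0 || u_pd > 1) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(ae)) {
    ae <- as.data.frame(ae)
    if (!all(c("prob", "disutility") %in% names(ae))) {
      stop("ae needs columns 'prob' and 'disutility'", call. = FALSE)
    }
    if (any(ae$prob < 0 | ae$prob > 1)) {
      stop("ae probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (any(ae$disutility < 0)) {
      stop("ae disutilities must be >= 0", call. = FALSE)
    }
  }
  structure(list(u_pfs = u_pfs, u_pd = u_pd, ae = ae),
            class = "utility_set")
}

#' Discounted quality-adjusted life-years of a cohort trace
#'
#' Per-cycle accrual is `(cycle months / 12) * (u_pfs * PFS + u_pd * PD)`
#' on half-cycle-corrected memberships, discounted at the cycle midpoint.
#' The adverse-event burden `sum(p_i * d_i) * (cycle months / 12)` is
#' subtracted once in the first cycle (undiscounted).
#'
#' @param trace A [build_trace()] result.
#' @param utilities A [utility_set()].
#' @param settings The [model_settings()] the trace was built with.
#' @return List with `total`, `pfs_qalys`, `pd_qalys`, `ae_decrement`.
#' @export
discounted_qalys <- function(trace, utilities, settings) {
  if (!inherits(utilities, "utility_set")) {
    stop("expected 'utility_set'", call. = FALSE)
  }
  acc <- trace_accrual(trace, settings)
  dy <- settings$cycle_months / 12
  q_pfs <- sum(dy * utilities$u_pfs * acc$pfs * acc$disc_mid)
  q_pd <- sum(dy * utilities$u_pd * acc$pd * acc$disc_mid)
  ae_dec <- if (!is.null(utilities$ae)) {
    sum(utilities$ae$prob * utilities$ae$disutility) * dy
  } else 0
  list(total = q_pfs + q_pd - ae_dec,
       pfs_qalys = q_pfs, pd_qalys = q_pd, ae_decrement = ae_dec)
}

#' Landmark survival from the model for internal validation
#'
#' Report-only comparison of model PFS/OS at landmark times against
#' optional reference values (e.g. trial readouts); nothing is asserted.
#'
#' @param trace A [build_trace()] result (carries its curves).
#' @param landmarks Times in months, within the horizon.
#' @param reference Optional data frame with columns `pfs` and/or `os`
#'   (percent), one row per landmark.
#' @return Data frame with `t_months`, `model_pfs_pct`, `model_os_pct`
#'   and any reference columns (`ref_pfs_pct`, `ref_os_pct`).
#' @export
internal_validation <- function(trace, landmarks, reference = NULL) {
  settings <- attr(trace, "settings")
  if (any(landmarks < 0) ||
      any(landmarks > settings$n_cycles * settings$cycle_months)) {
    stop("landmarks must lie within the horizon", call. = FALSE)
  }
  pfs_model <- attr(trace, "pfs_model")
  os_model <- attr(trace, "os_model")
  out <- data.frame(
    t_months = landmarks,
    model_pfs_pct = 100 * surv_prob(pfs_model, landmarks),
    model_os_pct = 100 * surv_prob(os_model, landmarks))
  if (!is.null(reference)) {
    reference <- as.data.frame(reference)
    if (!is.null(reference$pfs)) out$ref_pfs_pct <- reference$pfs
    if (!is.null(reference$os)) out$ref_os_pct <- reference$os
  }
  out
}
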