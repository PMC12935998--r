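#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental QALYs.
#' @return List with `value` (the ratio, or `NA` when not defined) and
#'   `label`: `"icer"` for a meaningful ratio, `"dominant"` (cheaper and
#'   at least as effective), `"dominated"` (costlier and less effective),
#'   `"equivalent"` (both increments zero), `"zero_qaly"` (cost differs
#'   but effects identical).
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) {
    return(list(value = NA_real_, label = "equivalent"))
  }
  if (delta_qaly == 0) {
    return(list(value = NA_real_, label = "zero_qaly"))
  }
  if (delta_cost <= 0 && delta_qaly > 0) {
    return(list(value = NA_real_, label = "dominant"))
  }
  if (delta_cost >= 0 && delta_qaly < 0) {
    return(list(value = NA_real_, label = "dominated"))
  }
  list(value = delta_cost / delta_qaly, label = "icer")
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`.
#'
#' @param cost Cost (USD).
#' @param qaly QALYs.
#' @param wtp Willingness-to-pay per QALY (>= 0).
#' @return Net monetary benefit in USD.
#' @export
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * qaly - cost
}

#' Per-arm result container
#'
#' @param arm Arm label.
#' @param cost Total discounted cost (USD) or a `cost_breakdown`.
#' @param qalys Total discounted QALYs.
#' @param country Country tag used for consistency checks.
#' @return Object of class `arm_result`.
#' @export
arm_result <- function(arm, cost, qalys, country = NA_character_) {
  breakdown <- NULL
  if (inherits(cost, "cost_breakdown")) {
    breakdown <- cost
    cost <- cost$total
  }
  structure(list(arm = arm, cost = cost, qalys = qalys, country = country,
                 breakdown = breakdown), class = "arm_result")
}

#' Incremental comparison of the two arms
#'
#' @param result_evp,result_ngc [arm_result()]s computed under identical
#'   settings (EV+P is the intervention, N+GC the comparator).
#' @param wtps Named or unnamed vector of willingness-to-pay thresholds.
#' @return Object of class `cea_result`: per-arm totals, `delta_cost`,
#'   `delta_qaly`, `icer` (value + label), and per-WTP `nmb_evp`,
#'   `nmb_ngc`, `cost_effective` (EV+P preferred by net monetary
#'   benefit).
#' @export
compare_arms <- function(result_evp, result_ngc, wtps) {
  stopifnot(inherits(result_evp, "arm_result"),
            inherits(result_ngc, "arm_result"))
  if (!identical(result_evp$country, result_ngc$country)) {
    stop("arm results come from different countries", call. = FALSE)
  }
  dc <- result_evp$cost - result_ngc$cost
  dq <- result_evp$qalys - result_ngc$qalys
  ic <- icer(dc, dq)
  wtab <- data.frame(
    wtp = as.numeric(wtps),
    nmb_evp = nmb(result_evp$cost, result_evp$qalys, as.numeric(wtps)),
    nmb_ngc = nmb(result_ngc$cost, result_ngc$qalys, as.numeric(wtps)))
  wtab$cost_effective <- wtab$nmb_evp > wtab$nmb_ngc
  structure(list(
    evp = result_evp, ngc = result_ngc,
    delta_cost = dc, delta_qaly = dq,
    icer = ic$value, icer_label = ic$label, wtp_table = wtab),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  tab <- data.frame(
    arm = c("N+GC", "EV+P"),
    cost = c(x$ngc$cost, x$evp$cost),
    qalys = c(x$ngc$qalys, x$evp$qalys))
  print(format(tab, big.mark = ",", digits = 6), row.names = FALSE)
  cat(sprintf("  delta cost %14.2f   delta QALYs %6.3f\n",
              x$delta_cost, x$delta_qaly))
  if (x$icer_label == "icer") {
    cat(sprintf("  ICER %14.2f USD/QALY\n", x$icer))
  } else {
    cat("  ICER:", x$icer_label, "\n")
  }
  for (i in seq_len(nrow(x$wtp_table))) {
    cat(sprintf("  at WTP %10.2f: EV+P %s\n", x$wtp_table$wtp[i],
                if (x$wtp_table$cost_effective[i]) "cost-effective"
                else "not cost-effective"))
  }
  invisible(x)
}
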