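#' Specification for a simulated right-censored survival sample
#'
#' Describes a trial-like sampling scheme: event times drawn from one of the
#' six parametric families, uniform staggered accrual over
#' `accrual_window` months, and administrative censoring `admin_censor`
#' months after study start.
#'
#' @param family,params Passed to [parametric_model()].
#' @param n Sample size (>= 1).
#' @param accrual_window Months of uniform staggered entry (>= 0).
#' @param admin_censor Months of administrative follow-up after study start
#'   (> `accrual_window` so every subject has positive follow-up; may be
#'   `Inf` for no censoring).
#' @param seed Integer RNG seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(family, params, n, accrual_window = 0,
                            admin_censor = Inf, seed = 1L) {
  model <- parametric_model(family, params)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (accrual_window < 0) stop("accrual_window must be >= 0", call. = FALSE)
  if (admin_censor <= 0) stop("admin_censor must be > 0", call. = FALSE)
  if (admin_censor <= accrual_window) {
    stop("admin_censor must exceed accrual_window", call. = FALSE)
  }
  structure(list(model = model, n = as.integer(n),
                 accrual_window = accrual_window,
                 admin_censor = admin_censor, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate pseudo individual-patient data
#'
#' Draws event times by inverse-CDF sampling from the spec's family and
#' applies staggered-entry administrative censoring: a subject entering at
#' offset `e` (uniform on \[0, accrual_window\]) is censored at
#' `admin_censor - e` months of follow-up if still event-free.
#'
#' @param spec A [simulation_spec()].
#' @return Data frame with columns `time` (months, > 0) and `event` (0/1),
#'   one row per subject. Reproducible for a fixed seed.
#' @export
simulate_ipd <- function(spec) {
  if (!inherits(spec, "simulation_spec")) {
    stop("expected a 'simulation_spec'", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  u <- stats::runif(spec$n)
  tt <- quantile_time(spec$model, u)
  entry <- if (spec$accrual_window > 0) {
    stats::runif(spec$n, 0, spec$accrual_window)
  } else {
    rep(0, spec$n)
  }
  fup <- spec$admin_censor - entry
  event <- as.integer(tt <= fup)
  time <- pmin(tt, fup)
  # guard against zero times from quantile underflow
  time <- pmax(time, .Machine$double.xmin)
  data.frame(time = time, event = event)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Kaplan-Meier estimate of a survival sample
#'
#' Product-limit estimator (via [survival::survfit()]) returned as a step
#' function table. With a `grid`, the step function is evaluated at the
#' grid times (carried forward between event times).
#'
#' @param ipd Data frame with `time`, `event`.
#' @param grid Optional increasing vector of times (months) at which to
#'   evaluate the estimate.
#' @return Data frame with columns `time`, `surv`, `n_risk`.
#' @export
km_estimate <- function(ipd, grid = NULL) {
  ipd <- validate_ipd(ipd)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd,
                           conf.type = "none")
  if (is.null(grid)) {
    data.frame(time = fit$time, surv = fit$surv, n_risk = fit$n.risk)
  } else {
    if (is.unsorted(grid, strictly = TRUE)) {
      stop("grid times must be strictly increasing", call. = FALSE)
    }
    s <- summary(fit, times = grid, extend = TRUE)
    data.frame(time = s$time, surv = s$surv, n_risk = s$n.risk)
  }
}

#' Build a digitized Kaplan-Meier fixture with known ground truth
#'
#' Emulates manual curve digitization: samples the KM step curve of `ipd`
#' on a regular grid of spacing `coord_step`, reads numbers-at-risk at
#' `risk_interval` spacing, and optionally perturbs the survival
#' coordinates by uniform jitter of the given magnitude (clamped to keep
#' the curve a valid nonincreasing survival function; the number of clamps
#' is recorded).
#'
#' @param ipd Data frame with `time`, `event`.
#' @param coord_step Coordinate grid spacing, months (> 0).
#' @param risk_interval Numbers-at-risk spacing, months (> 0).
#' @param jitter Uniform jitter half-width applied to survival coordinates
#'   (default 0 = exact digitization).
#' @param seed Optional seed for the jitter noise.
#' @return A [digitized_curve()] whose `total_events` is the true event
#'   count; attribute `n_clamped` counts monotonicity clamps.
#' @export
make_digitized_fixture <- function(ipd, coord_step, risk_interval,
                                   jitter = 0, seed = NULL) {
  ipd <- validate_ipd(ipd)
  if (coord_step <= 0 || risk_interval <= 0) {
    stop("coord_step and risk_interval must be > 0", call. = FALSE)
  }
  tmax <- max(ipd$time)
  grid <- seq(0, tmax, by = coord_step)
  if (grid[length(grid)] < tmax) grid <- c(grid, tmax)
  km <- km_estimate(ipd, grid = grid)
  surv <- km$surv
  n_clamped <- 0L
  if (jitter > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    if (!is.null(seed)) set.seed(seed)
    noisy <- surv + stats::runif(length(surv), -jitter, jitter)
    noisy <- pmin(pmax(noisy, 0), 1)
    noisy[1] <- surv[1]  # the origin S(0) = 1 is always read off exactly
    mono <- cummin(noisy)
    n_clamped <- sum(mono != noisy)
    if (n_clamped > 0) {
      warning(sprintf("jitter broke monotonicity at %d coordinates; clamped",
                      n_clamped), call. = FALSE)
    }
    surv <- mono
  }
  risk_times <- seq(0, tmax, by = risk_interval)
  risk_times <- risk_times[risk_times < tmax]
  at_risk <- km_estimate(ipd, grid = risk_times)$n_risk
  keep <- at_risk > 0
  curve <- digitized_curve(
    coords = data.frame(time = grid, surv = surv),
    risk_table = data.frame(time = risk_times[keep], n_risk = at_risk[keep]),
    total_events = sum(ipd$event))
  attr(curve, "n_clamped") <- n_clamped
  curve
}

#' Read or write pseudo-IPD as CSV
#'
#' Two-column CSV (`time_months`, `event`) with a one-line header.
#'
#' @param ipd Data frame with `time`, `event`.
#' @param path File path.
#' @return `read_ipd_csv` returns a data frame with `time`, `event`.
#' @export
write_ipd_csv <- function(ipd, path) {
  ipd <- validate_ipd(ipd)
  utils::write.csv(
    data.frame(time_months = ipd$time, event = ipd$event),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ipd_csv
#' @export
read_ipd_csv <- function(path) {
  x <- utils::read.csv(path)
  validate_ipd(data.frame(time = x$time_months, event = x$event))
}

#' Read or write a digitized curve as a CSV pair
#'
#' Coordinates as (`time_months`, `survival`); risk table as
#' (`time_months`, `n_risk`).
#'
#' @param curve A [digitized_curve()].
#' @param coords_path,risk_path File paths for the two tables.
#' @return `read_curve_csv` returns a [digitized_curve()].
#' @export
write_curve_csv <- function(curve, coords_path, risk_path) {
  stopifnot(inherits(curve, "digitized_curve"))
  utils::write.csv(
    data.frame(time_months = curve$coords$time,
               survival = curve$coords$surv),
    coords_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(time_months = curve$risk_table$time,
               n_risk = curve$risk_table$n_risk),
    risk_path, row.names = FALSE, quote = FALSE)
  invisible(coords_path)
}

#' @rdname write_curve_csv
#' @param total_events Optional event-count constraint attached on read.
#' @export
read_curve_csv <- function(coords_path, risk_path, total_events = NULL) {
  co <- utils::read.csv(coords_path)
  ri <- utils::read.csv(risk_path)
  digitized_curve(
    coords = data.frame(time = co$time_months, surv = co$survival),
    risk_table = data.frame(time = ri$time_months, n_risk = ri$n_risk),
    total_events = total_events)
}
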