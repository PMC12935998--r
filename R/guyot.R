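#' A digitized Kaplan-Meier curve
#'
#' Container for the two artifacts read off a published KM plot: the step
#' curve coordinates and the numbers-at-risk table, plus an optional total
#' event count (when a trial reports it).
#'
#' @param coords Data frame with `time` (months, nondecreasing, first >= 0)
#'   and `surv` (in \[0, 1\], nonincreasing).
#' @param risk_table Data frame with `time` (strictly increasing) and
#'   `n_risk` (positive, nonincreasing).
#' @param total_events Optional integer: reported number of events.
#' @return An object of class `digitized_curve`.
#' @export
digitized_curve <- function(coords, risk_table, total_events = NULL) {
  coords <- as.data.frame(coords)
  risk_table <- as.data.frame(risk_table)
  if (NROW(coords) == 0) stop("coords must be nonempty", call. = FALSE)
  if (!all(c("time", "surv") %in% names(coords))) {
    stop("coords needs columns 'time' and 'surv'", call. = FALSE)
  }
  if (!all(c("time", "n_risk") %in% names(risk_table))) {
    stop("risk_table needs columns 'time' and 'n_risk'", call. = FALSE)
  }
  if (coords$time[1] < 0) stop("first coordinate time must be >= 0", call. = FALSE)
  if (is.unsorted(coords$time)) stop("coordinate times must be nondecreasing", call. = FALSE)
  if (any(coords$surv < 0 | coords$surv > 1)) {
    stop("survival coordinates must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(coords$surv) > 1e-12)) {
    stop("survival coordinates must be nonincreasing", call. = FALSE)
  }
  if (NROW(risk_table) > 0) {
    if (is.unsorted(risk_table$time, strictly = TRUE)) {
      stop("risk-table times must be strictly increasing", call. = FALSE)
    }
    if (any(risk_table$n_risk <= 0)) {
      stop("risk-table counts must be positive", call. = FALSE)
    }
    if (any(diff(risk_table$n_risk) > 0)) {
      stop("risk-table counts must be nonincreasing", call. = FALSE)
    }
  }
  if (NROW(risk_table) < 1) {
    stop("risk table needs at least the initial number at risk", call. = FALSE)
  }
  structure(list(coords = coords, risk_table = risk_table,
                 total_events = if (is.null(total_events)) NULL
                                else as.integer(total_events)),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat("<digitized_curve>", NROW(x$coords), "coordinates,",
      NROW(x$risk_table), "risk-table rows")
  if (!is.null(x$total_events)) cat(",", x$total_events, "events reported")
  cat("\n")
  invisible(x)
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Implements the iterative inversion of the product-limit estimator from
#' curve coordinates and numbers-at-risk. Within each risk-table
#' interval the number censored is first guessed from the survival ratio,
#' censoring times are spread uniformly over the interval, event counts at
#' each coordinate are recovered by inverting the KM ratios, and the
#' censoring guess is adjusted until the implied number at risk at the next
#' risk-table time matches the published count. After the last risk-table
#' time, censoring is assumed absent unless a reported `total_events`
#' constrains it, in which case the residual censoring level is searched so
#' the reconstructed event count matches.
#'
#' Negative intermediate counts (a risk table inconsistent with the
#' coordinates) are clamped at zero and counted; the clamp count is
#' returned as attribute `n_clamped`.
#'
#' @param curve A [digitized_curve()].
#' @return Data frame with columns `time`, `event`; one row per subject
#'   initially at risk. Attributes: `n_clamped`, `per_interval` (events and
#'   censorings per risk interval).
#' @references Guyot P, Ades AE, Ouwens MJ, Welton NJ. Enhanced secondary
#'   analysis of survival data: reconstructing the data from published
#'   Kaplan-Meier survival curves. BMC Med Res Methodol. 2012;12:9.
#' @export
guyot_reconstruct <- function(curve) {
  if (!inherits(curve, "digitized_curve")) {
    stop("expected a 'digitized_curve'", call. = FALSE)
  }
  tS <- curve$coords$time
  S <- curve$coords$surv
  # ensure an origin coordinate
  if (tS[1] > 0 || S[1] < 1) {
    tS <- c(0, tS)
    S <- c(1, S)
  }
  K <- length(tS)
  rt <- curve$risk_table
  if (NROW(rt) == 0 || rt$time[1] > 0) {
    stop("risk table must include the time origin", call. = FALSE)
  }
  trisk <- rt$time
  nrisk <- rt$n_risk
  J <- length(trisk)
  # coordinate index ranges per risk interval: lower[j] = first coordinate
  # at or after trisk[j]
  lower <- vapply(trisk, function(a) which(tS >= a - 1e-9)[1], integer(1))
  if (anyNA(lower)) stop("risk-table times beyond coordinate range", call. = FALSE)

  n_clamped <- 0L
  d <- integer(K)        # events at each coordinate
  cens_times <- numeric(0)
  n_hat <- nrisk[1]      # running number at risk
  km_run <- 1            # running KM value at last event
  iv_events <- integer(J)
  iv_cens <- integer(J)

  # process interval j spanning coordinates lower[j] .. (lower[j+1]-1),
  # matching n at risk at lower[j+1]
  process <- function(idx_from, idx_to, n_start, km_start, n_cens) {
    # spread censorings uniformly over (tS[idx_from], tS[idx_to]]
    t0 <- tS[idx_from]; t1 <- tS[min(idx_to + 1, K)]
    ct <- if (n_cens > 0) {
      t0 + (seq_len(n_cens)) * (t1 - t0) / (n_cens + 1)
    } else numeric(0)
    dloc <- integer(K)
    n_k <- n_start; km <- km_start
    for (k in idx_from:idx_to) {
      if (n_k > 0 && S[k] < km - 1e-12) {
        dk <- round(n_k * (1 - S[k] / km))
        dk <- max(0L, min(dk, n_k))
        if (dk > 0) {
          km <- km * (1 - dk / n_k)
          dloc[k] <- dk
          n_k <- n_k - dk
        }
      }
      # censorings in (tS[k], tS[k+1]]
      if (k < K) {
        nc <- sum(ct > tS[k] & ct <= tS[k + 1] + 1e-12)
        n_k <- n_k - nc
      }
      if (n_k < 0) { n_k <- 0 }
    }
    list(d = dloc, n_end = n_k, km = km, cens = ct)
  }

  # recompute the running KM value after an event-count adjustment
  replay_km <- function(idx_from, idx_to, n_start, km_start, dloc, ct) {
    n_k <- n_start; km <- km_start
    for (k in idx_from:idx_to) {
      if (dloc[k] > 0 && n_k > 0) {
        km <- km * (1 - dloc[k] / n_k)
        n_k <- n_k - dloc[k]
      }
      if (k < K) n_k <- n_k - sum(ct > tS[k] & ct <= tS[k + 1] + 1e-12)
    }
    km
  }

  for (j in seq_len(J)) {
    idx_from <- lower[j]
    last_interval <- j == J
    idx_to <- if (last_interval) K else lower[j + 1] - 1L
    if (!last_interval) {
      target <- nrisk[j + 1]
      t_next <- tS[lower[j + 1]]
      if (idx_to < idx_from) {
        # no coordinates fall inside this risk interval: the at-risk drop
        # is pure censoring
        n_cens <- n_hat - target
        if (n_cens < 0) { n_clamped <- n_clamped + 1L; n_cens <- 0L }
        cens_times <- c(cens_times, rep(t_next - 1e-9, n_cens))
        iv_cens[j] <- n_cens
        n_hat <- min(n_hat, target)
        next
      }
      # n_end is nonincreasing in the interval censor count, so binary
      # search the smallest count whose implied at-risk is at or below
      # the published one
      f <- function(nc) process(idx_from, idx_to, n_hat, km_run, nc)
      res <- f(0L)
      if (res$n_end > target) {
        lo <- 0L; hi <- n_hat
        while (lo < hi) {
          mid <- (lo + hi) %/% 2L
          if (f(mid)$n_end > target) lo <- mid + 1L else hi <- mid
        }
        res <- f(lo)
        if (res$n_end < target && lo > 0L) {
          # rounding made the count jump past the target: censor the
          # surplus explicitly at the end of the interval instead
          res <- f(lo - 1L)
          surplus <- res$n_end - target
          res$cens <- c(res$cens, rep(t_next - 1e-9, surplus))
          res$n_end <- target
        }
      }
      if (res$n_end < target) {
        # zero censoring still undershoots: event rounding overshot;
        # remove the deficit from the latest event coordinates
        deficit <- as.integer(target - res$n_end)
        n_clamped <- n_clamped + 1L
        for (k in rev(seq(idx_from, idx_to))) {
          take <- min(deficit, res$d[k])
          res$d[k] <- res$d[k] - take
          deficit <- deficit - take
          if (deficit == 0L) break
        }
        res$n_end <- target - deficit
        res$km <- replay_km(idx_from, idx_to, n_hat, km_run, res$d, res$cens)
      }
      if (res$n_end > target) {
        # even censoring everyone cannot reach the published count
        n_clamped <- n_clamped + 1L
        surplus <- res$n_end - target
        res$cens <- c(res$cens, rep(t_next - 1e-9, surplus))
        res$n_end <- target
      }
      d <- d + res$d
      cens_times <- c(cens_times, res$cens)
      iv_events[j] <- sum(res$d)
      iv_cens[j] <- length(res$cens)
      km_run <- res$km
      n_hat <- res$n_end
    } else {
      # final interval: choose censoring to satisfy total_events if given
      tot_prev <- sum(d)
      fit_last <- function(n_cens) process(idx_from, idx_to, n_hat, km_run, n_cens)
      if (!is.null(curve$total_events)) {
        need <- curve$total_events - tot_prev
        best <- NULL; best_gap <- Inf
        for (n_cens in 0:n_hat) {
          res <- fit_last(n_cens)
          gap <- abs(sum(res$d) - need)
          if (gap < best_gap) { best <- res; best_gap <- gap; best_nc <- n_cens }
          if (gap == 0) break
        }
        res <- best
        if (best_gap > 0) n_clamped <- n_clamped + 1L
      } else {
        res <- fit_last(0L)
      }
      d <- d + res$d
      cens_times <- c(cens_times, res$cens)
      iv_events[j] <- sum(res$d)
      # everyone still at risk after the last coordinate is censored there
      n_left <- res$n_end
      if (n_left > 0) {
        cens_times <- c(cens_times, rep(tS[K], n_left))
      }
      iv_cens[j] <- length(res$cens) + n_left
    }
  }

  ev_times <- rep(tS, times = d)
  out <- data.frame(
    time = c(ev_times, cens_times),
    event = c(rep(1L, length(ev_times)), rep(0L, length(cens_times))))
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  out$time <- pmax(out$time, .Machine$double.xmin)
  attr(out, "n_clamped") <- n_clamped
  attr(out, "per_interval") <- data.frame(
    interval = seq_len(J), start = trisk,
    events = iv_events, censored = iv_cens)
  out
}

#' Fidelity report for a reconstruction
#'
#' Re-estimates the KM curve from reconstructed records and compares it
#' with the digitized coordinates.
#'
#' @param curve The [digitized_curve()] the records were built from.
#' @param ipd Output of [guyot_reconstruct()].
#' @return List with `max_abs_dS`, `mean_abs_dS`, `n_clamped`,
#'   `per_interval`, and the comparison table `by_coord`.
#' @export
reconstruction_report <- function(curve, ipd) {
  if (!inherits(curve, "digitized_curve")) {
    stop("expected a 'digitized_curve'", call. = FALSE)
  }
  ipd <- validate_ipd(ipd)
  km <- km_estimate(ipd, grid = unique(pmax(curve$coords$time, 0)))
  s_hat <- km$surv[match(pmax(curve$coords$time, 0), km$time)]
  dS <- abs(s_hat - curve$coords$surv)
  list(
    max_abs_dS = max(dS),
    mean_abs_dS = mean(dS),
    n_clamped = attr(ipd, "n_clamped") %||% 0L,
    per_interval = attr(ipd, "per_interval"),
    by_coord = data.frame(time = curve$coords$time,
                          surv_digitized = curve$coords$surv,
                          surv_reconstructed = s_hat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
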