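#' Maximum-likelihood fit of one survival family
#'
#' Fits `family` to right-censored records by maximum likelihood
#' (numerical optimization on an unconstrained transformed scale, via
#' [flexsurv::flexsurvreg()]). If the first attempt fails or does not
#' converge, two restarts from perturbed initial values are tried.
#'
#' @param family One of [ucc_families()].
#' @param ipd Data frame with `time` (months) and `event` (0/1).
#' @param init Optional named initial parameter vector on the natural scale.
#' @return An object of class `fit_result`: list with `model`
#'   ([parametric_model()] at the MLE), `loglik`, `aic`, `bic`,
#'   `converged`, `n`, `n_events`.
#' @export
fit_mle <- function(family, ipd, init = NULL) {
  family <- match.arg(family, ucc_families())
  ipd <- validate_ipd(ipd)
  n <- nrow(ipd)
  n_events <- sum(ipd$event)
  need <- if (family == "gengamma") 3L else 2L
  if (n_events < need) {
    stop(sprintf("fitting '%s' needs at least %d events, got %d",
                 family, need, n_events), call. = FALSE)
  }
  dist <- switch(family,
    exponential = "exp", weibull = "weibull", gompertz = "gompertz",
    lognormal = "lnorm", loglogistic = "llogis", gengamma = "gengamma")

  try_fit <- function(inits) {
    tryCatch({
      args <- list(formula = survival::Surv(time, event) ~ 1, data = ipd,
                   dist = dist)
      if (!is.null(inits)) args$inits <- inits
      fit <- do.call(flexsurv::flexsurvreg, args)
      if (!is.null(fit$opt$convergence) && fit$opt$convergence != 0) {
        attr(fit, "ucc_converged") <- FALSE
      } else {
        attr(fit, "ucc_converged") <- TRUE
      }
      fit
    }, error = function(e) NULL)
  }

  inits0 <- if (!is.null(init)) unname(unlist(init)[flexsurv_param_order(family)])
            else NULL
  fit <- try_fit(inits0)
  if (is.null(fit) || !attr(fit, "ucc_converged")) {
    base_init <- if (!is.null(fit)) fit$res[, "est"] else moment_init(family, ipd)
    for (k in 1:2) {
      jit <- base_init * stats::runif(length(base_init), 0.7, 1.3)
      cand <- try_fit(unname(jit))
      if (!is.null(cand) && attr(cand, "ucc_converged")) { fit <- cand; break }
      if (is.null(fit) && !is.null(cand)) fit <- cand
    }
  }
  if (is.null(fit)) {
    stop(sprintf("all fit attempts failed for family '%s'", family),
         call. = FALSE)
  }
  est <- fit$res[, "est"]
  params <- flexsurv_to_ucc(family, est)
  k <- n_params(family)
  ll <- fit$loglik
  structure(list(
    model = parametric_model(family, params),
    loglik = ll,
    aic = 2 * k - 2 * ll,
    bic = k * log(n) - 2 * ll,
    converged = isTRUE(attr(fit, "ucc_converged")),
    n = n, n_events = n_events), class = "fit_result")
}

## flexsurv's natural-scale parameter order per dist
flexsurv_param_order <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gompertz    = c("shape", "rate"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"),
    gengamma    = c("mu", "sigma", "Q"))
}

flexsurv_to_ucc <- function(family, est) {
  nm <- flexsurv_param_order(family)
  stats::setNames(as.numeric(est[seq_along(nm)]), nm)
}

## crude method-of-moments style starting values for restarts
moment_init <- function(family, ipd) {
  tt <- ipd$time
  m <- mean(tt); lm <- mean(log(tt)); ls <- stats::sd(log(tt))
  if (!is.finite(ls) || ls <= 0) ls <- 1
  switch(family,
    exponential = c(rate = 1 / m),
    weibull     = c(shape = 1, scale = m),
    gompertz    = c(shape = 0.001, rate = 1 / m),
    lognormal   = c(meanlog = lm, sdlog = ls),
    loglogistic = c(shape = 1.5, scale = stats::median(tt)),
    gengamma    = c(mu = lm, sigma = ls, Q = 0))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s  loglik %.3f  AIC %.2f  BIC %.2f  %s\n",
              x$model$family, x$loglik, x$aic, x$bic,
              if (x$converged) "converged" else "NOT converged"))
  print(x$model$params)
  invisible(x)
}

#' Fit and rank candidate survival families
#'
#' Fits each requested family by [fit_mle()] and returns the results
#' ranked by AIC (ties broken by fewer parameters, then family name).
#' Families whose fits fail are dropped with a warning.
#'
#' @param ipd Data frame with `time`, `event`.
#' @param families Character vector of families (default all six).
#' @return Data frame with columns `family`, `loglik`, `aic`, `bic`,
#'   `converged`, `n_params`, sorted by AIC; attribute `fits` holds the
#'   `fit_result` objects keyed by family.
#' @export
model_select <- function(ipd, families = ucc_families()) {
  families <- match.arg(families, ucc_families(), several.ok = TRUE)
  fits <- list()
  for (f in families) {
    res <- tryCatch(fit_mle(f, ipd), error = function(e) {
      warning(sprintf("fit failed for '%s': %s", f, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) fits[[f]] <- res
  }
  if (length(fits) == 0) stop("all fits failed", call. = FALSE)
  tab <- data.frame(
    family = names(fits),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    n_params = vapply(names(fits), n_params, integer(1)))
  ord <- order(tab$aic, tab$n_params, tab$family)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Overlay table of fitted survival against the KM estimate
#'
#' Exports the data needed for the visual-congruence check of a fit: the
#' KM step estimate of the sample and the fitted parametric survival on a
#' common time grid.
#'
#' @param model A [parametric_model()] (e.g. from a `fit_result`).
#' @param ipd The sample the model was fitted to.
#' @param times Optional evaluation grid; defaults to 100 points spanning
#'   the observed range.
#' @return Data frame with `time`, `km`, `fitted`.
#' @export
km_overlay <- function(model, ipd, times = NULL) {
  ipd <- validate_ipd(ipd)
  if (is.null(times)) times <- seq(0, max(ipd$time), length.out = 100)
  km <- km_estimate(ipd, grid = times)
  data.frame(time = times, km = km$surv, fitted = surv_prob(model, times))
}
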