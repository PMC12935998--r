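#' Six parametric survival families
#'
#' The candidate distributions used for extrapolating progression-free and
#' overall survival: exponential, Weibull, Gompertz, log-normal, log-logistic
#' and generalized gamma (Prentice parameterization). Time is in months
#' throughout the package (one month = 365.25/12 days).
#'
#' Parameter vectors are named:
#' \describe{
#'   \item{exponential}{\code{rate} (> 0); S(t) = exp(-rate t)}
#'   \item{weibull}{\code{shape}, \code{scale} (> 0); S(t) = exp(-(t/scale)^shape)}
#'   \item{gompertz}{\code{shape} (any real), \code{rate} (> 0);
#'     S(t) = exp(-(rate/shape)(e^{shape t} - 1)), exponential in the
#'     shape -> 0 limit}
#'   \item{lognormal}{\code{meanlog} (any real), \code{sdlog} (> 0)}
#'   \item{loglogistic}{\code{shape}, \code{scale} (> 0);
#'     S(t) = 1 / (1 + (t/scale)^shape)}
#'   \item{gengamma}{\code{mu} (any real), \code{sigma} (> 0), \code{Q}
#'     (any real); Q = 0 reduces to lognormal(mu, sigma)}
#' }
#'
#' @param family One of `ucc_families()`.
#' @param params Named numeric vector or list of parameters for `family`.
#' @return An object of class `parametric_model`.
#' @examples
#' m <- parametric_model("loglogistic", c(shape = 1.3124, scale = 32.1285))
#' surv_prob(m, c(0, 12, 600))
#' @export
parametric_model <- function(family, params) {
  family <- match.arg(family, ucc_families())
  params <- unlist(params)
  want <- family_param_names(family)
  if (!setequal(names(params), want)) {
    stop(sprintf("family '%s' needs parameters {%s}, got {%s}",
                 family, paste(want, collapse = ", "),
                 paste(names(params), collapse = ", ")), call. = FALSE)
  }
  params <- params[want]
  if (any(!is.finite(params))) {
    stop("non-finite parameter value", call. = FALSE)
  }
  pos <- switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gompertz    = "rate",
    lognormal   = "sdlog",
    loglogistic = c("shape", "scale"),
    gengamma    = "sigma")
  if (any(params[pos] <= 0)) {
    stop(sprintf("parameter(s) %s must be strictly positive",
                 paste(pos[params[pos] <= 0], collapse = ", ")), call. = FALSE)
  }
  structure(list(family = family, params = params), class = "parametric_model")
}

#' @export
print.parametric_model <- function(x, ...) {
  cat("<parametric_model>", x$family, "\n")
  print(x$params)
  invisible(x)
}

#' Names of the supported survival families
#' @return Character vector of the six family names.
#' @export
ucc_families <- function() {
  c("exponential", "weibull", "gompertz", "lognormal", "loglogistic",
    "gengamma")
}

family_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gompertz    = c("shape", "rate"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"),
    gengamma    = c("mu", "sigma", "Q"))
}

n_params <- function(family) length(family_param_names(family))

stopifnot_model <- function(model) {
  if (!inherits(model, "parametric_model")) {
    stop("expected a 'parametric_model' object", call. = FALSE)
  }
}

## dispatch onto the d/p/q/h family functions (flexsurv for the three
## families base R lacks); `what` is one of "d", "p", "q", "h"
family_fun <- function(model, what, x, lower.tail = TRUE) {
  p <- as.list(model$params)
  switch(model$family,
    exponential = switch(what,
      d = stats::dexp(x, p$rate),
      p = stats::pexp(x, p$rate, lower.tail = lower.tail),
      q = stats::qexp(x, p$rate),
      h = rep_len(p$rate, length(x))),
    weibull = switch(what,
      d = stats::dweibull(x, p$shape, p$scale),
      p = stats::pweibull(x, p$shape, p$scale, lower.tail = lower.tail),
      q = stats::qweibull(x, p$shape, p$scale),
      h = flexsurv::hweibull(x, p$shape, p$scale)),
    gompertz = switch(what,
      d = flexsurv::dgompertz(x, p$shape, p$rate),
      p = flexsurv::pgompertz(x, p$shape, p$rate, lower.tail = lower.tail),
      q = flexsurv::qgompertz(x, p$shape, p$rate),
      # closed form h = rate * e^(shape t); the density/survival ratio
      # underflows where S vanishes
      h = p$rate * exp(p$shape * x)),
    lognormal = switch(what,
      d = stats::dlnorm(x, p$meanlog, p$sdlog),
      p = stats::plnorm(x, p$meanlog, p$sdlog, lower.tail = lower.tail),
      q = stats::qlnorm(x, p$meanlog, p$sdlog),
      h = flexsurv::hlnorm(x, p$meanlog, p$sdlog)),
    loglogistic = switch(what,
      d = flexsurv::dllogis(x, p$shape, p$scale),
      p = flexsurv::pllogis(x, p$shape, p$scale, lower.tail = lower.tail),
      q = flexsurv::qllogis(x, p$shape, p$scale),
      h = flexsurv::hllogis(x, p$shape, p$scale)),
    gengamma = switch(what,
      d = flexsurv::dgengamma(x, p$mu, p$sigma, p$Q),
      p = flexsurv::pgengamma(x, p$mu, p$sigma, p$Q, lower.tail = lower.tail),
      q = flexsurv::qgengamma(x, p$mu, p$sigma, p$Q),
      h = flexsurv::hgengamma(x, p$mu, p$sigma, p$Q)))
}

#' Survival, hazard and density of a parametric model
#'
#' `surv_prob()` evaluates S(t); `haz_rate()` the hazard h(t) (per month);
#' `dens_fun()` the density f(t) = h(t) S(t).
#'
#' @param model A [parametric_model()].
#' @param t Time in months; `t >= 0` for `surv_prob`, `t > 0` for hazard
#'   and density.
#' @return Numeric vector the length of `t`.
#' @export
surv_prob <- function(model, t) {
  stopifnot_model(model)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  s <- family_fun(model, "p", t, lower.tail = FALSE)
  pmin(pmax(s, 0), 1)
}

#' @rdname surv_prob
#' @export
haz_rate <- function(model, t) {
  stopifnot_model(model)
  if (any(t <= 0)) stop("t must be > 0", call. = FALSE)
  family_fun(model, "h", t)
}

#' @rdname surv_prob
#' @export
dens_fun <- function(model, t) {
  stopifnot_model(model)
  if (any(t <= 0)) stop("t must be > 0", call. = FALSE)
  family_fun(model, "d", t)
}

#' Quantile (inverse survival) of a parametric model
#'
#' @param model A [parametric_model()].
#' @param p Cumulative probability in \[0, 1\].
#' @return Time t such that F(t) = p, in months.
#' @export
quantile_time <- function(model, p) {
  stopifnot_model(model)
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  family_fun(model, "q", p)
}

#' Right-censored log-likelihood of a parametric model
#'
#' Sum over records of `event * log f(t) + (1 - event) * log S(t)`.
#'
#' @param model A [parametric_model()].
#' @param ipd Data frame with columns `time` (> 0, months) and `event`
#'   (0/1).
#' @return Scalar log-likelihood.
#' @export
model_loglik <- function(model, ipd) {
  stopifnot_model(model)
  ipd <- validate_ipd(ipd)
  ev <- ipd$event == 1
  sum(log(dens_fun(model, ipd$time[ev]))) +
    sum(log(surv_prob(model, ipd$time[!ev])))
}

## shared validation for (time, event) records
validate_ipd <- function(ipd) {
  if (is.null(ipd) || NROW(ipd) == 0) {
    stop("ipd must contain at least one record", call. = FALSE)
  }
  ipd <- as.data.frame(ipd)
  if (!all(c("time", "event") %in% names(ipd))) {
    stop("ipd needs columns 'time' and 'event'", call. = FALSE)
  }
  if (any(!is.finite(ipd$time)) || any(ipd$time <= 0)) {
    stop("all times must be strictly positive and finite", call. = FALSE)
  }
  if (!all(ipd$event %in% c(0, 1))) {
    stop("event must be 0 or 1", call. = FALSE)
  }
  ipd
}
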