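#' Parametric survival distributions
#'
#' Construct a parametric survival model from one of the seven families used
#' for extrapolating trial Kaplan-Meier curves: exponential, Weibull, gamma,
#' log-normal, log-logistic, Gompertz and generalized gamma. Time is measured
#' in months throughout.
#'
#' Parameterizations follow the usual survival-analysis conventions:
#' \describe{
#'   \item{exponential}{\code{rate > 0}; S(t) = exp(-rate t).}
#'   \item{weibull}{\code{shape, scale > 0} (as [stats::pweibull]).}
#'   \item{gamma}{\code{shape, rate > 0}.}
#'   \item{lognormal}{\code{meanlog}, \code{sdlog > 0}; S(t) =
#'     1 - Phi((log t - meanlog)/sdlog); the median is exp(meanlog).}
#'   \item{loglogistic}{\code{shape, scale > 0};
#'     S(t) = 1 / (1 + (t/scale)^shape); the median equals \code{scale}.}
#'   \item{gompertz}{\code{shape} (any sign), \code{rate > 0}. A negative
#'     shape gives an improper distribution (a fraction never dies); the
#'     object is flagged via its \code{improper} field.}
#'   \item{gengamma}{log-location form \code{(mu, sigma > 0, Q)} as in
#'     [flexsurv::dgengamma].}
#' }
#'
#' @param family Character; one of \code{"exponential"}, \code{"weibull"},
#'   \code{"gamma"}, \code{"lognormal"}, \code{"loglogistic"},
#'   \code{"gompertz"}, \code{"gengamma"} (alias
#'   \code{"generalized_gamma"}).
#' @param params Numeric vector of parameters, in the order listed above.
#' @return An object of class \code{"parsurv"}: a list with elements
#'   \code{family}, \code{params} (named) and \code{improper}.
#' @examples
#' m <- parsurv("loglogistic", c(shape = 2.004, scale = 13.331))
#' surv_prob(m, c(0, 13.331))   # 1 and 0.5: the scale is the median
#' @export
parsurv <- function(family, params) {
  family <- match.arg(gsub("generalized_gamma", "gengamma", family[1]),
                      surv_families())
  params <- as.numeric(params)
  info <- family_info(family)
  if (length(params) != info$npars)
    stop(sprintf("family '%s' needs %d parameter(s), got %d",
                 family, info$npars, length(params)), call. = FALSE)
  if (any(!is.finite(params)))
    stop("non-finite parameter values", call. = FALSE)
  pos <- params[info$positive]
  if (any(pos <= 0))
    stop(sprintf("family '%s': parameter(s) %s must be strictly positive",
                 family,
                 paste(info$par_names[info$positive][pos <= 0], collapse = ", ")),
         call. = FALSE)
  names(params) <- info$par_names
  improper <- family == "gompertz" && params[["shape"]] < 0
  structure(list(family = family, params = params, improper = improper),
            class = "parsurv")
}

#' @rdname parsurv
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gamma", "lognormal", "loglogistic",
    "gompertz", "gengamma")
}

family_info <- function(family) {
  switch(family,
    exponential = list(npars = 1L, par_names = "rate", positive = 1L),
    weibull     = list(npars = 2L, par_names = c("shape", "scale"), positive = 1:2),
    gamma       = list(npars = 2L, par_names = c("shape", "rate"), positive = 1:2),
    lognormal   = list(npars = 2L, par_names = c("meanlog", "sdlog"), positive = 2L),
    loglogistic = list(npars = 2L, par_names = c("shape", "scale"), positive = 1:2),
    gompertz    = list(npars = 2L, par_names = c("shape", "rate"), positive = 2L),
    gengamma    = list(npars = 3L, par_names = c("mu", "sigma", "Q"), positive = 2L),
    stop("unknown family: ", family, call. = FALSE))
}

stopifnot_parsurv <- function(model) {
  if (!inherits(model, "parsurv"))
    stop("'model' must be a parsurv object", call. = FALSE)
}

#' Survival, density, hazard and quantile functions
#'
#' Evaluate a [parsurv] model. `surv_prob` returns S(t), `surv_density` the
#' density f(t), and `surv_quantile` the inverse of the cumulative incidence
#' F = 1 - S (so `surv_quantile(m, 0.5)` is the median survival time).
#'
#' @param model A [parsurv] object.
#' @param t Non-negative times in months.
#' @param p Probabilities in `[0, 1]`.
#' @return Numeric vector.
#' @export
surv_prob <- function(model, t) {
  stopifnot_parsurv(model)
  t <- as.numeric(t)
  if (any(t < 0)) stop("negative times are outside the domain", call. = FALSE)
  pr <- model$params
  s <- switch(model$family,
    exponential = stats::pexp(t, rate = pr[1], lower.tail = FALSE),
    weibull     = stats::pweibull(t, pr[1], pr[2], lower.tail = FALSE),
    gamma       = stats::pgamma(t, shape = pr[1], rate = pr[2], lower.tail = FALSE),
    lognormal   = stats::plnorm(t, pr[1], pr[2], lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = pr[1], scale = pr[2], lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = pr[1], rate = pr[2], lower.tail = FALSE),
    gengamma    = flexsurv::pgengamma(t, mu = pr[1], sigma = pr[2], Q = pr[3],
                                      lower.tail = FALSE))
  pmin(pmax(s, 0), 1)
}

#' @rdname surv_prob
#' @export
surv_density <- function(model, t) {
  stopifnot_parsurv(model)
  t <- as.numeric(t)
  if (any(t < 0)) stop("negative times are outside the domain", call. = FALSE)
  pr <- model$params
  switch(model$family,
    exponential = stats::dexp(t, rate = pr[1]),
    weibull     = stats::dweibull(t, pr[1], pr[2]),
    gamma       = stats::dgamma(t, shape = pr[1], rate = pr[2]),
    lognormal   = stats::dlnorm(t, pr[1], pr[2]),
    loglogistic = flexsurv::dllogis(t, shape = pr[1], scale = pr[2]),
    gompertz    = flexsurv::dgompertz(t, shape = pr[1], rate = pr[2]),
    gengamma    = flexsurv::dgengamma(t, mu = pr[1], sigma = pr[2], Q = pr[3]))
}

#' @rdname surv_prob
#' @export
surv_quantile <- function(model, p) {
  stopifnot_parsurv(model)
  p <- as.numeric(p)
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  pr <- model$params
  switch(model$family,
    exponential = stats::qexp(p, rate = pr[1]),
    weibull     = stats::qweibull(p, pr[1], pr[2]),
    gamma       = stats::qgamma(p, shape = pr[1], rate = pr[2]),
    lognormal   = stats::qlnorm(p, pr[1], pr[2]),
    loglogistic = flexsurv::qllogis(p, shape = pr[1], scale = pr[2]),
    gompertz    = flexsurv::qgompertz(p, shape = pr[1], rate = pr[2]),
    gengamma    = flexsurv::qgengamma(p, mu = pr[1], sigma = pr[2], Q = pr[3]))
}

#' @export
print.parsurv <- function(x, ...) {
  cat(sprintf("Parametric survival model: %s\n", x$family))
  print(round(x$params, 4))
  if (x$improper)
    cat("Note: improper distribution (negative Gompertz shape); S(t) does not reach 0.\n")
  invisible(x)
}

#' @export
predict.parsurv <- function(object, times,
                            type = c("survival", "density", "quantile"), ...) {
  type <- match.arg(type)
  switch(type,
    survival = surv_prob(object, times),
    density  = surv_density(object, times),
    quantile = surv_quantile(object, times))
}

#' Simulate event times from a parametric survival model
#'
#' Inverse-CDF sampling: each event time is `surv_quantile(model, u)` for a
#' uniform draw `u`.
#'
#' @param object A [parsurv] object.
#' @param nsim Number of event times.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Numeric vector of `nsim` event times (months). May contain `Inf`
#'   for improper distributions.
#' @export
simulate.parsurv <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  surv_quantile(object, stats::runif(nsim))
}

#' @export
plot.parsurv <- function(x, t_max = NULL, ...) {
  if (is.null(t_max)) {
    t_max <- if (x$improper) 120 else min(surv_quantile(x, 0.99) * 1.2, 480)
  }
  tt <- seq(0, t_max, length.out = 400)
  plot(tt, surv_prob(x, tt), type = "l", xlab = "Time (months)",
       ylab = "Survival probability", ylim = c(0, 1),
       main = paste0("S(t), ", x$family), ...)
  invisible(x)
}
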