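# Maximum-likelihood fitting of parametric survival distributions to
# right-censored pseudo individual patient data, and AIC/BIC model selection.
# Fitting is done directly on the censored log-likelihood
#   sum_events log f(t_i) + sum_censored log S(t_i)
# via optim() on an unconstrained transformed parameter scale.  survreg()
# could cover four of the six families but not Gompertz or gamma; a single
# in-house likelihood keeps the family set uniform (survreg is used as an
# independent cross-check in the test suite).

# parameters are optimised on an unconstrained scale: log() for positive
# parameters, identity for real-valued ones
.par_transform <- function(family) {
  u <- function(x) unname(x)
  switch(family,
    exponential = list(to = function(p) log(u(p)),
                       from = function(x) c(rate = exp(u(x)))),
    weibull     = list(to = function(p) log(u(p)),
                       from = function(x) c(shape = exp(u(x)[1]), scale = exp(u(x)[2]))),
    lognormal   = list(to = function(p) c(u(p)[1], log(u(p)[2])),
                       from = function(x) c(meanlog = u(x)[1], sdlog = exp(u(x)[2]))),
    loglogistic = list(to = function(p) c(u(p)[1], log(u(p)[2])),
                       from = function(x) c(theta = u(x)[1], kappa = exp(u(x)[2]))),
    gompertz    = list(to = function(p) c(u(p)[1], log(u(p)[2])),
                       from = function(x) c(shape = u(x)[1], rate = exp(u(x)[2]))),
    gamma       = list(to = function(p) log(u(p)),
                       from = function(x) c(shape = exp(u(x)[1]), rate = exp(u(x)[2]))))
}

.censored_loglik <- function(family, params, time, event) {
  te <- time[event == 1]; tc <- time[event == 0]
  ll <- switch(family,
    exponential = {
      r <- params[["rate"]]
      sum(stats::dexp(te, r, log = TRUE)) - r * sum(tc)
    },
    weibull = sum(stats::dweibull(te, params[["shape"]], params[["scale"]], log = TRUE)) +
      sum(stats::pweibull(tc, params[["shape"]], params[["scale"]],
                          lower.tail = FALSE, log.p = TRUE)),
    lognormal = sum(stats::dlnorm(te, params[["meanlog"]], params[["sdlog"]], log = TRUE)) +
      sum(stats::plnorm(tc, params[["meanlog"]], params[["sdlog"]],
                        lower.tail = FALSE, log.p = TRUE)),
    loglogistic = sum(.loglogistic_logdens(te, params[["theta"]], params[["kappa"]])) +
      sum(log(.loglogistic_surv(tc, params[["theta"]], params[["kappa"]]))),
    gompertz = sum(.gompertz_logdens(te, params[["shape"]], params[["rate"]])) +
      sum(log(.gompertz_surv(tc, params[["shape"]], params[["rate"]]))),
    gamma = sum(stats::dgamma(te, params[["shape"]], params[["rate"]], log = TRUE)) +
      sum(stats::pgamma(tc, params[["shape"]], params[["rate"]],
                        lower.tail = FALSE, log.p = TRUE)))
  if (!is.finite(ll)) -1e10 else ll
}

# moment-style starting values from the empirical survival of the data
.start_values <- function(family, time, event) {
  km <- km_estimate(pseudo_ipd(time, event, validate = FALSE))
  med <- .km_quantile(km, 0.5)
  q25 <- .km_quantile(km, 0.75)  # time at S = .75 (25th percentile of T)
  q75 <- .km_quantile(km, 0.25)
  if (!is.finite(med) || med <= 0) med <- stats::median(time)
  if (!is.finite(q25) || q25 <= 0) q25 <- med / 2
  if (!is.finite(q75) || q75 <= med) q75 <- med * 2
  mean_t <- mean(time)
  switch(family,
    exponential = c(rate = log(2) / med),
    weibull = {
      shape <- log(log(4) / log(4 / 3)) / log(q75 / q25)
      shape <- min(max(shape, 0.2), 10)
      c(shape = shape, scale = med / log(2)^(1 / shape))
    },
    lognormal = c(meanlog = log(med), sdlog = max(0.2, log(q75 / q25) / 2.7)),
    loglogistic = {
      # S(med)=.5 => exp(theta) med^kappa = 1; spread sets kappa via
      # S(q75)=.25 => exp(theta) q75^kappa = 3
      kappa <- log(9) / log(q75 / q25)
      kappa <- min(max(kappa, 0.2), 10)
      c(theta = -kappa * log(med), kappa = kappa)
    },
    gompertz = c(shape = 0.01, rate = log(2) / med),
    gamma = {
      shape <- max(0.3, (mean_t / stats::sd(time))^2)
      c(shape = shape, rate = shape / mean_t)
    })
}

#' Fit a parametric survival distribution to pseudo-IPD
#'
#' Maximum-likelihood fit under right censoring.  On non-convergence the
#' optimiser is restarted from up to two perturbed starting points before
#' giving up.
#'
#' @param ipd a [pseudo_ipd()] object (or data.frame with `time`, `event`)
#' @param family distribution family, see [parametric_survival()]
#' @param time_unit recorded on the fitted model
#' @return an object of class `fit_result`: fields `model`
#'   ([parametric_survival()]), `loglik`, `aic`, `bic`, `n`, `n_events`,
#'   `convergence`
#' @export
fit_parametric <- function(ipd, family, time_unit = c("months", "days")) {
  family <- match.arg(family, .SURV_FAMILIES)
  time_unit <- match.arg(time_unit)
  time <- ipd$time; event <- ipd$event
  if (length(time) == 0) stop("no records to fit")
  if (sum(event) < 2) stop("at least 2 events are required to fit a distribution")
  if (any(time <= 0)) stop("all times must be positive")

  tr <- .par_transform(family)
  negll <- function(x) -.censored_loglik(family, tr$from(x), time, event)
  start <- tr$to(.start_values(family, time, event))

  fit <- NULL
  for (attempt in 0:2) {
    x0 <- start + if (attempt == 0) 0 else stats::rnorm(length(start), 0, 0.3 * attempt)
    method <- if (length(start) == 1L) "Brent" else "Nelder-Mead"
    res <- tryCatch(
      if (method == "Brent") {
        stats::optim(x0, negll, method = "Brent", lower = x0 - 15, upper = x0 + 15)
      } else {
        stats::optim(x0, negll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
      },
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) && res$value < 1e9 &&
        (method == "Brent" || res$convergence == 0)) {
      fit <- res
      break
    }
  }
  if (is.null(fit)) {
    stop(sprintf("fit_parametric: %s fit failed to converge after 3 starts", family))
  }

  params <- tr$from(fit$par)
  k <- .family_npar(family)
  loglik <- -fit$value
  structure(list(
    model = parametric_survival(family, params, time_unit),
    loglik = loglik,
    aic = -2 * loglik + 2 * k,
    bic = -2 * loglik + log(length(time)) * k,
    n = length(time),
    n_events = sum(event),
    convergence = TRUE
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: loglik %.3f, AIC %.2f, BIC %.2f (n = %d, events = %d)\n",
              x$model$family, x$loglik, x$aic, x$bic, x$n, x$n_events))
  print(round(x$model$params, 5))
  invisible(x)
}

#' Fit all candidate families
#'
#' Convenience wrapper fitting the six candidate distributions; families
#' whose fit fails are dropped with a warning.
#'
#' @inheritParams fit_parametric
#' @param families subset of candidate families
#' @return list of `fit_result`
#' @export
fit_all_families <- function(ipd, families = .SURV_FAMILIES,
                             time_unit = c("months", "days")) {
  time_unit <- match.arg(time_unit)
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_parametric(ipd, fam, time_unit), error = function(e) {
      warning(sprintf("%s fit failed: %s", fam, conditionMessage(e)))
      NULL
    })
    if (!is.null(f)) fits[[fam]] <- f
  }
  fits
}

#' Select the best-fitting distribution
#'
#' Returns the fit with the minimal AIC or BIC.  Ties are broken by fewer
#' parameters, then by alphabetical family name.
#'
#' @param fits list of `fit_result` objects
#' @param criterion `"aic"` or `"bic"`
#' @return the selected `fit_result`
#' @export
select_best <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (length(fits) == 0) stop("empty fit list")
  crit <- vapply(fits, function(f) f[[criterion]], numeric(1))
  npar <- vapply(fits, function(f) .family_npar(f$model$family), integer(1))
  fam <- vapply(fits, function(f) f$model$family, character(1))
  fits[[order(crit, npar, fam)[1L]]]
}

#' Tabulate goodness of fit across families
#'
#' @param fits list of `fit_result`
#' @return data.frame with one row per family: family, parameter summary,
#'   loglik, aic, bic
#' @export
fit_summary <- function(fits) {
  do.call(rbind, lapply(unname(fits), function(f) data.frame(
    family = f$model$family,
    params = paste(sprintf("%s=%.5g", names(f$model$params), f$model$params),
                   collapse = "; "),
    loglik = f$loglik, aic = f$aic, bic = f$bic,
    n = f$n, n_events = f$n_events,
    stringsAsFactors = FALSE)))
}

#' Export a fitted survival curve for graphical overlay
#'
#' @param model a `parametric_survival`
#' @param times evaluation times
#' @return data.frame (time, survival)
#' @export
survival_curve <- function(model, times) {
  data.frame(time = times, survival = eval_survival(model, times))
}
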