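# Parametric survival curves, hazard-ratio adjustment, fitting and
# AIC/BIC model selection.

test_that("log-logistic survival matches the closed form", {
  m <- parametric_survival("loglogistic", c(theta = 0, kappa = 1))
  expect_identical(eval_survival(m, 0), 1)
  expect_equal(eval_survival(m, 1), 0.5)

  m2 <- parametric_survival("loglogistic", c(theta = -2, kappa = 1.5))
  expect_equal(eval_survival(m2, 4), 1 / (1 + exp(-2) * 4^1.5), tolerance = 1e-12)
  expect_equal(eval_survival(m2, 4), 0.48014, tolerance = 1e-4)

  expect_error(eval_survival(m2, -1), "non-negative")
  expect_error(parametric_survival("loglogistic", c(theta = 0, kappa = -1)))
})

test_that("hazard-ratio adjustment is the stated power law", {
  m <- parametric_survival("loglogistic", c(theta = -2, kappa = 1.5))
  t <- c(0, 1, 4, 10)
  expect_equal(apply_hr(m, 1, t), eval_survival(m, t))
  expect_equal(apply_hr(m, 2, 4), eval_survival(m, 4)^2)
  expect_equal(apply_hr(m, 0.63, 4), 0.48014^0.63, tolerance = 1e-4)
  expect_error(apply_hr(m, 0, 4), "positive")
  expect_error(apply_hr(m, -1, 4), "positive")

  hr <- hazard_ratio(0.63, 0.49, 0.82, endpoint = "OS")
  expect_equal(apply_hr(m, hr, 4), eval_survival(m, 4)^0.63)
  expect_error(hazard_ratio(0.5, 0.6, 0.8), "ci_low")
})

test_that("survival is monotone non-increasing for every family", {
  set.seed(42)
  t <- seq(0, 60, by = 0.5)
  for (rep in 1:20) {
    models <- list(
      parametric_survival("exponential", c(rate = runif(1, 0.01, 1))),
      parametric_survival("weibull", c(shape = runif(1, 0.3, 4),
                                       scale = runif(1, 1, 30))),
      parametric_survival("lognormal", c(meanlog = runif(1, 0, 3),
                                         sdlog = runif(1, 0.2, 2))),
      parametric_survival("loglogistic", c(theta = runif(1, -6, 1),
                                           kappa = runif(1, 0.3, 4))),
      parametric_survival("gompertz", c(shape = runif(1, -0.1, 0.3),
                                        rate = runif(1, 0.01, 0.5))),
      parametric_survival("gamma", c(shape = runif(1, 0.3, 4),
                                     rate = runif(1, 0.05, 1))))
    for (m in models) {
      s <- eval_survival(m, t)
      expect_true(all(diff(s) <= 1e-12), label = m$family)
      expect_identical(s[1], 1)
      expect_true(all(s >= 0 & s <= 1))
    }
  }
})

test_that("HR direction orders the adjusted curve around the base curve", {
  m <- parametric_survival("loglogistic", c(theta = -4, kappa = 1.6))
  t <- seq(0.5, 40, by = 0.5)
  expect_true(all(apply_hr(m, 0.6, t) >= eval_survival(m, t)))
  expect_true(all(apply_hr(m, 1.7, t) <= eval_survival(m, t)))
})

test_that("exponential MLE and AIC/BIC match the closed form", {
  ipd <- pseudo_ipd(c(1, 2, 3), c(1, 1, 1))
  fit <- fit_parametric(ipd, "exponential")
  # events / exposure = 3/6
  expect_equal(unname(fit$model$params[["rate"]]), 0.5, tolerance = 1e-6)
  ll <- 3 * log(0.5) - 0.5 * 6
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  expect_equal(fit$aic, -2 * ll + 2, tolerance = 1e-5)
  expect_equal(fit$bic, -2 * ll + log(3), tolerance = 1e-5)
  expect_equal(fit$n_events, 3L)
})

test_that("log-logistic fit recovers generating parameters", {
  ipd <- gen_ipd(-4.0, 1.6, n = 10000,
                 censoring = list(type = "uniform", max = 30), seed = 7)
  fit <- fit_parametric(ipd, "loglogistic")
  expect_lt(abs(fit$model$params[["theta"]] - (-4.0)), 0.1)
  expect_lt(abs(fit$model$params[["kappa"]] - 1.6), 0.05)
})

test_that("fitted parameters agree with survreg for shared families", {
  ipd <- gen_ipd(-3.5, 1.4, n = 4000,
                 censoring = list(type = "uniform", max = 40), seed = 11)
  # log-logistic: survreg's (mu, sigma) map to kappa = 1/sigma,
  # theta = -mu/sigma
  sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = ipd,
                          dist = "loglogistic")
  fit <- fit_parametric(ipd, "loglogistic")
  expect_equal(unname(fit$model$params[["kappa"]]), 1 / sr$scale,
               tolerance = 1e-3)
  expect_equal(unname(fit$model$params[["theta"]]),
               -unname(coef(sr)) / sr$scale, tolerance = 1e-2)

  srw <- survival::survreg(survival::Surv(time, event) ~ 1, data = ipd,
                           dist = "weibull")
  fw <- fit_parametric(ipd, "weibull")
  expect_equal(unname(fw$model$params[["shape"]]), 1 / srw$scale,
               tolerance = 1e-3)
  expect_equal(unname(fw$model$params[["scale"]]), exp(unname(coef(srw))),
               tolerance = 1e-3)
})

test_that("parameter bias shrinks with sample size", {
  err <- sapply(c(1000, 10000), function(n) {
    ipd <- gen_ipd(-4.0, 1.6, n = n,
                   censoring = list(type = "uniform", max = 30), seed = 3)
    fit <- fit_parametric(ipd, "loglogistic")
    abs(fit$model$params[["theta"]] + 4.0) + abs(fit$model$params[["kappa"]] - 1.6)
  })
  expect_lt(err[2], err[1])
})

test_that("select_best applies the criterion and its tie-breaks", {
  mk <- function(fam, aic) {
    structure(list(model = parametric_survival(fam,
      switch(fam, exponential = c(rate = 1), c(1, 1))),
      loglik = 0, aic = aic, bic = aic, n = 10, n_events = 10),
      class = "fit_result")
  }
  fits <- list(mk("weibull", 100), mk("lognormal", 98), mk("gamma", 103))
  expect_identical(select_best(fits, "aic")$model$family, "lognormal")
  expect_identical(select_best(fits[2], "aic")$model$family, "lognormal")
  # tie: 1-parameter exponential beats 2-parameter weibull
  tie <- list(mk("weibull", 98), mk("exponential", 98))
  expect_identical(select_best(tie, "aic")$model$family, "exponential")
  expect_error(select_best(list()), "empty")
})

test_that("model selection recovers the log-logistic family", {
  # smaller replicate count than the full experiment, same design
  wins <- 0L
  for (s in 1:10) {
    ipd <- gen_ipd(-4.0, 1.6, n = 2000,
                   censoring = list(type = "uniform", max = 30), seed = 100 + s)
    fits <- suppressWarnings(fit_all_families(ipd))
    if (select_best(fits, "aic")$model$family == "loglogistic") wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("fitting rejects degenerate input", {
  expect_error(fit_parametric(pseudo_ipd(c(1, 2), c(0, 0)), "exponential"),
               "2 events")
  expect_error(fit_parametric(pseudo_ipd(numeric(0), integer(0),
                                         validate = FALSE), "weibull"),
               "no records")
})
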