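# Deterministic (one-way tornado, threshold search) and probabilistic
# (Monte Carlo, acceptability-curve) sensitivity analyses, plus
# subgroup-level runs.  Distribution parameterisation follows ISPOR-style
# practice: gamma for costs, beta for utilities and frequencies, lognormal
# for hazard ratios, each moment-matched so the mean equals the base value
# and (high - low) / (2 * 1.96) acts as the standard deviation; hazard
# ratios match their 95% CI on the log scale.

#' Sensitivity-analysis parameter specification
#'
#' @param name parameter name understood by [wb_set()]
#' @param base base-case value
#' @param low,high deterministic range with `low <= base <= high`
#' @param distribution `"gamma"`, `"beta"`, `"lognormal"`, `"uniform"` or
#'   `"fixed"` (degenerate at base)
#' @return a `param_spec` with derived distribution parameters
#' @export
param_spec <- function(name, base, low, high,
                       distribution = c("gamma", "beta", "lognormal",
                                        "uniform", "fixed")) {
  distribution <- match.arg(distribution)
  if (!(low <= base && base <= high)) stop(name, ": need low <= base <= high")
  sd <- (high - low) / (2 * 1.96)
  dp <- switch(distribution,
    fixed = list(),
    uniform = list(min = low, max = high),
    gamma = {
      if (base <= 0 || sd == 0) { distribution <- "fixed"; list() }
      else list(shape = (base / sd)^2, rate = base / sd^2)
    },
    beta = {
      if (base <= 0 || base >= 1) stop(name, ": beta needs base in (0, 1)")
      v <- base * (1 - base) / sd^2 - 1
      if (sd == 0 || v <= 0) { distribution <- "fixed"; list() }
      else list(shape1 = base * v, shape2 = (1 - base) * v)
    },
    lognormal = {
      if (base <= 0 || low <= 0) stop(name, ": lognormal needs positive range")
      sdlog <- if (high > low) (log(high) - log(low)) / (2 * 1.96) else 0
      if (sdlog == 0) { distribution <- "fixed"; list() }
      else list(meanlog = log(base), sdlog = sdlog)
    })
  structure(list(name = name, base = base, low = low, high = high,
                 distribution = distribution, dist_params = dp),
            class = "param_spec")
}

#' Draw random values from a parameter specification
#'
#' @param spec a [param_spec()]
#' @param n number of draws
#' @return numeric vector of length `n`
#' @export
draw_param <- function(spec, n) {
  dp <- spec$dist_params
  switch(spec$distribution,
    fixed = rep(spec$base, n),
    uniform = stats::runif(n, dp$min, dp$max),
    gamma = stats::rgamma(n, shape = dp$shape, rate = dp$rate),
    beta = stats::rbeta(n, dp$shape1, dp$shape2),
    lognormal = stats::rlnorm(n, dp$meanlog, dp$sdlog))
}

#' Default sensitivity specifications for a workbook
#'
#' Hazard ratios vary over their 95% CIs (lognormal), the discount rate
#' over 0-8% (uniform), utilities over +/-25% clipped to 1 (beta), and
#' costs, prices and weight over +/-25% (gamma).
#'
#' @param wb a `cea_workbook`
#' @param strategy the intervention whose HRs are varied
#' @return named list of [param_spec()]
#' @export
default_dsa_specs <- function(wb, strategy) {
  stopifnot(strategy %in% names(wb$hrs))
  pm25 <- function(x) c(0.75 * x, 1.25 * x)
  specs <- list()
  add <- function(s) specs[[s$name]] <<- s
  for (ep in c("os", "pfs", "ae")) {
    h <- wb$hrs[[strategy]][[ep]]
    add(param_spec(sprintf("hr_%s.%s", ep, strategy), h[1], h[2], h[3],
                   "lognormal"))
  }
  add(param_spec("discount_rate", wb$settings$discount_rate_annual, 0, 0.08,
                 "uniform"))
  w <- mean_weight(wb$population)
  add(param_spec("weight_mean", w, pm25(w)[1], pm25(w)[2], "gamma"))
  for (u in c("u_pfd", "u_pd")) {
    b <- wb$utilities[[u]]
    add(param_spec(u, b, 0.75 * b, min(1, 1.25 * b), "beta"))
  }
  for (cc in c("cost_bsc", "cost_subsequent", "cost_palliative",
               "cost_followup")) {
    b <- wb$settings[[cc]]
    add(param_spec(cc, b, 0.75 * b, 1.25 * b, "gamma"))
  }
  add(param_spec("ae_cost_mult", 1, 0.75, 1.25, "gamma"))
  # strategy-specific drug prices (non-backbone drugs of this strategy)
  backbone <- vapply(wb$dosing[["chemotherapy"]], `[[`, character(1), "drug")
  for (r in wb$dosing[[strategy]]) {
    if (r$drug %in% backbone) next
    p <- if (!is.na(r$price_per_admin)) r$price_per_admin else r$price_per_mg
    add(param_spec(paste0("price.", r$drug), p, 0.75 * p, 1.25 * p, "gamma"))
  }
  specs
}

#' One-way deterministic sensitivity analysis
#'
#' Reruns the model with each parameter at its low and high bound (all
#' others at base) and ranks parameters by the ICER spread (tornado
#' ordering).  A runner failure at an endpoint is recorded in the `error`
#' column, not dropped.
#'
#' @param specs list of [param_spec()]
#' @param runner deterministic function(overrides) -> ICER, e.g. from
#'   [make_icer_runner()]
#' @return data.frame (param, low, high, icer_low, icer_high, spread,
#'   error) sorted by descending spread, of class `tornado`
#' @export
dsa_oneway <- function(specs, runner) {
  rows <- lapply(specs, function(sp) {
    f <- function(v) tryCatch(runner(stats::setNames(list(v), sp$name)),
                              error = function(e) NA_real_)
    lo <- f(sp$low); hi <- f(sp$high)
    data.frame(param = sp$name, low = sp$low, high = sp$high,
               icer_low = lo, icer_high = hi,
               spread = abs(hi - lo),
               error = is.na(lo) || is.na(hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Threshold search: parameter value where the ICER crosses a WTP
#'
#' Bisection on a parameter over `[low, high]`, assuming the ICER is
#' monotone there (verified at the endpoints).  Returns `NA` when the ICER
#' does not cross the threshold inside the interval.
#'
#' @param spec a [param_spec()] giving the search interval
#' @param wtp willingness-to-pay threshold in USD/QALY
#' @param runner function(overrides) -> ICER
#' @param tol relative tolerance on the parameter value
#' @param check_monotone verify monotonicity with a midpoint probe and fail
#'   with advice to grid-search when violated
#' @return the crossing value, or `NA_real_` if none
#' @export
threshold_search <- function(spec, wtp, runner, tol = 1e-6,
                             check_monotone = TRUE) {
  f <- function(v) runner(stats::setNames(list(v), spec$name)) - wtp
  lo <- spec$low; hi <- spec$high
  flo <- f(lo); fhi <- f(hi)
  if (check_monotone) {
    fm <- f((lo + hi) / 2)
    if ((fm - flo) * (fhi - fm) < 0) {
      stop("ICER is not monotone over the interval; use a grid search")
    }
  }
  if (flo * fhi > 0) return(NA_real_)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / max(abs(mid), 1e-12) < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` independent joint samples of the parameters and evaluates the
#' model per draw.  Reproducible for a given seed.
#'
#' @param specs list of [param_spec()]
#' @param runner function(overrides) -> data.frame (strategy, cost, qalys),
#'   e.g. from [make_ce_runner()]
#' @param n number of Monte Carlo draws (default 10,000)
#' @param seed RNG seed, recorded in the result
#' @return a `psa_result`: list with `draws` (n x p parameter matrix) and
#'   `samples` (long data.frame: draw, strategy, cost, qalys)
#' @export
psa <- function(specs, runner, n = 10000, seed = 1L) {
  for (sp in specs) {
    if (!inherits(sp, "param_spec")) stop("specs must be param_spec objects")
  }
  set.seed(seed)
  draws <- vapply(specs, draw_param, numeric(n), n = n)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n)
  colnames(draws) <- vapply(specs, `[[`, character(1), "name")
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    res <- runner(as.list(draws[i, ]))
    samples[[i]] <- cbind(draw = i, res[, c("strategy", "cost", "qalys")])
  }
  structure(list(draws = draws,
                 samples = do.call(rbind, samples),
                 seed = seed, n = n),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that each strategy
#' has the maximal net monetary benefit across draws; ties split equally.
#'
#' @param samples a `psa_result` or its long `samples` data.frame
#' @param wtp_grid WTP values in USD/QALY (default 0 to 60,000 by 500,
#'   spanning the 15,217-38,042.49 decision range)
#' @return data.frame (wtp, strategy, probability) of class `ceac`;
#'   probabilities sum to 1 at each WTP
#' @export
ceac <- function(samples, wtp_grid = seq(0, 60000, by = 500)) {
  if (inherits(samples, "psa_result")) samples <- samples$samples
  if (length(wtp_grid) == 0) stop("empty WTP grid")
  if (nrow(samples) == 0) stop("no PSA samples")
  strategies <- unique(samples$strategy)
  cost <- matrix(samples$cost, ncol = length(strategies), byrow = TRUE)
  qaly <- matrix(samples$qalys, ncol = length(strategies), byrow = TRUE)
  # rows are draws; columns follow the within-draw strategy order
  ord <- samples$strategy[seq_along(strategies)]
  out <- lapply(wtp_grid, function(w) {
    nmb <- w * qaly - cost
    best <- nmb == apply(nmb, 1, max)
    p <- colSums(best / rowSums(best)) / nrow(nmb)
    data.frame(wtp = w, strategy = ord, probability = as.numeric(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("ceac", "data.frame")
  out
}

#' Subgroup-level base-case runs
#'
#' Reruns the full pipeline per subgroup with subgroup-specific hazard
#' ratios; gender subgroups additionally use the sex-specific weight
#' (prop_male 1 or 0).  Subgroups with missing HRs are skipped with a
#' warning.
#'
#' @param wb a `cea_workbook`
#' @param subgroup_hrs data.frame with columns `subgroup`, `strategy`,
#'   `hr_os` and optionally `hr_pfs`; one row per subgroup x strategy
#' @return named list per subgroup: list(results = ce_result list,
#'   table = [ce_table()], frontier = [frontier()] result)
#' @export
subgroup_run <- function(wb, subgroup_hrs) {
  stopifnot(all(c("subgroup", "strategy", "hr_os") %in% names(subgroup_hrs)))
  out <- list()
  for (sg in unique(subgroup_hrs$subgroup)) {
    rows <- subgroup_hrs[subgroup_hrs$subgroup == sg, ]
    need <- setdiff(setdiff(names(wb$hrs), "chemotherapy"), rows$strategy)
    if (length(need)) {
      warning(sprintf("subgroup '%s': missing HRs for %s; skipped", sg,
                      paste(need, collapse = ", ")))
      next
    }
    wsg <- wb
    for (i in seq_len(nrow(rows))) {
      wsg$hrs[[rows$strategy[i]]]$os[1] <- rows$hr_os[i]
      if ("hr_pfs" %in% names(rows) && !is.na(rows$hr_pfs[i])) {
        wsg$hrs[[rows$strategy[i]]]$pfs[1] <- rows$hr_pfs[i]
      }
    }
    if (sg %in% c("male", "Male")) wsg$population$prop_male <- 1
    if (sg %in% c("female", "Female")) wsg$population$prop_male <- 0
    res <- run_base_case(wsg)
    out[[sg]] <- list(results = res, table = ce_table(res),
                      frontier = frontier(res))
  }
  out
}
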