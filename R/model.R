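# Base-case model runner: from a parameter workbook to per-strategy
# discounted cost/QALY totals.  Parameter overrides are addressed by name
# ("hr_os.<strategy>", "price.<drug>", "u_pfd", ...) so that sensitivity
# analyses can perturb single inputs without touching the workbook schema.

#' Apply a named parameter override to a workbook
#'
#' Recognised names:
#' \describe{
#'   \item{`discount_rate`, `u_pfd`, `u_pd`, `prop_male`, `bsa`, `crcl`}{scalars}
#'   \item{`weight_mean`}{rescales both sex-specific weights so the
#'     sex-weighted mean equals the value}
#'   \item{`cost_followup`, `cost_bsc`, `cost_subsequent`, `cost_palliative`}{per-cycle / one-off costs}
#'   \item{`ae_cost_mult`}{multiplies every AE unit cost}
#'   \item{`theta_pfs`, `kappa_pfs`, `theta_os`, `kappa_os`}{reference-arm curve parameters}
#'   \item{`hr_os.<strategy>`, `hr_pfs.<strategy>`, `hr_ae.<strategy>`}{hazard-ratio point estimates}
#'   \item{`price.<drug>`}{unit price of a drug across all strategies}
#' }
#'
#' @param wb a `cea_workbook`
#' @param name parameter name
#' @param value new value
#' @return the modified workbook
#' @export
wb_set <- function(wb, name, value) {
  stopifnot_scalar(value, name)
  if (grepl("^hr_(os|pfs|ae)\\.", name)) {
    ep <- sub("^hr_", "", sub("\\..*$", "", name))
    strat <- sub("^hr_(os|pfs|ae)\\.", "", name)
    if (!strat %in% names(wb$hrs)) stop("unknown strategy in override: ", strat)
    wb$hrs[[strat]][[ep]][1] <- value
    return(wb)
  }
  if (grepl("^price\\.", name)) {
    drug <- sub("^price\\.", "", name)
    found <- FALSE
    for (s in names(wb$dosing)) {
      for (i in seq_along(wb$dosing[[s]])) {
        if (wb$dosing[[s]][[i]]$drug == drug) {
          if (!is.na(wb$dosing[[s]][[i]]$price_per_admin)) {
            wb$dosing[[s]][[i]]$price_per_admin <- value
          } else {
            wb$dosing[[s]][[i]]$price_per_mg <- value
          }
          found <- TRUE
        }
      }
    }
    if (!found) stop("unknown drug in override: ", drug)
    return(wb)
  }
  switch(name,
    discount_rate = { wb$settings$discount_rate_annual <- value },
    u_pfd = { wb$utilities$u_pfd <- value },
    u_pd = { wb$utilities$u_pd <- value },
    prop_male = { wb$population$prop_male <- value },
    bsa = { wb$population$bsa <- value },
    crcl = { wb$population$crcl <- value },
    weight_mean = {
      f <- value / mean_weight(wb$population)
      wb$population$weight_male <- wb$population$weight_male * f
      wb$population$weight_female <- wb$population$weight_female * f
    },
    cost_followup = { wb$settings$cost_followup <- value },
    cost_bsc = { wb$settings$cost_bsc <- value },
    cost_subsequent = { wb$settings$cost_subsequent <- value },
    cost_palliative = { wb$settings$cost_palliative <- value },
    ae_cost_mult = {
      wb$ae_items <- lapply(wb$ae_items, function(it) {
        it$unit_cost <- it$unit_cost * value; it
      })
    },
    theta_pfs = { wb$chemo_survival$pfs$theta <- value },
    kappa_pfs = { wb$chemo_survival$pfs$kappa <- value },
    theta_os = { wb$chemo_survival$os$theta <- value },
    kappa_os = { wb$chemo_survival$os$kappa <- value },
    stop("unknown parameter override: ", name))
  wb
}

#' Apply a list of overrides
#'
#' @param wb a `cea_workbook`
#' @param overrides named list / named numeric vector
#' @return the modified workbook
#' @export
wb_override <- function(wb, overrides) {
  for (nm in names(overrides)) wb <- wb_set(wb, nm, overrides[[nm]])
  wb
}

#' Run one strategy through the cohort model
#'
#' Builds the strategy's HR-adjusted PFS/OS curves from the reference
#' chemotherapy log-logistic parameters, computes the partitioned-survival
#' trace, and accumulates discounted costs and QALYs.
#'
#' @param wb a `cea_workbook`
#' @param strategy one of [workbook_strategies()]
#' @param grid optional pre-built [cycle_grid()]
#' @return a `ce_result`
#' @export
run_strategy <- function(wb, strategy, grid = NULL) {
  if (!strategy %in% names(wb$hrs)) stop("unknown strategy: ", strategy)
  if (is.null(grid)) {
    grid <- cycle_grid(wb$grid$cycle_length_days, wb$grid$horizon_years)
  }
  pfs <- parametric_survival("loglogistic",
    c(theta = wb$chemo_survival$pfs$theta, kappa = wb$chemo_survival$pfs$kappa))
  os <- parametric_survival("loglogistic",
    c(theta = wb$chemo_survival$os$theta, kappa = wb$chemo_survival$os$kappa))
  hr_pfs <- wb$hrs[[strategy]]$pfs[1]
  hr_os <- wb$hrs[[strategy]]$os[1]
  trace <- state_occupancy(
    function(t) apply_hr(pfs, hr_pfs, t),
    function(t) apply_hr(os, hr_os, t),
    grid)
  drug_costs <- drug_cost_schedule(wb$dosing[[strategy]], wb$population, grid)
  ae <- ae_burden(wb$ae_items, wb$hrs[[strategy]]$ae[1])
  accumulate(trace, drug_costs, wb$utilities, wb$settings, ae,
             strategy = strategy)
}

#' Run the base case for every strategy
#'
#' @param wb a `cea_workbook`
#' @param overrides optional named overrides, see [wb_set()]
#' @param strategies subset of strategies (default all)
#' @return list of `ce_result`, reference chemotherapy first
#' @export
run_base_case <- function(wb, overrides = NULL, strategies = NULL) {
  if (!is.null(overrides)) wb <- wb_override(wb, overrides)
  if (is.null(strategies)) strategies <- workbook_strategies(wb)
  grid <- cycle_grid(wb$grid$cycle_length_days, wb$grid$horizon_years)
  lapply(strategies, function(s) run_strategy(wb, s, grid))
}

#' ICER runner for sensitivity analyses
#'
#' Returns a deterministic function mapping a named override list to the
#' ICER of `strategy` versus `comparator`.
#'
#' @param wb a `cea_workbook`
#' @param strategy intervention strategy name
#' @param comparator reference strategy name
#' @return function(overrides) -> ICER in USD/QALY
#' @export
make_icer_runner <- function(wb, strategy, comparator = "chemotherapy") {
  stopifnot(strategy %in% names(wb$hrs), comparator %in% names(wb$hrs))
  function(overrides = NULL) {
    res <- run_base_case(wb, overrides, strategies = c(strategy, comparator))
    icer(res[[1]], res[[2]])
  }
}

#' Cost/QALY runner for probabilistic sensitivity analysis
#'
#' @param wb a `cea_workbook`
#' @param strategies subset (default all)
#' @return function(overrides) -> data.frame (strategy, cost, qalys, lys)
#' @export
make_ce_runner <- function(wb, strategies = NULL) {
  if (is.null(strategies)) strategies <- workbook_strategies(wb)
  function(overrides = NULL) {
    ce_table(run_base_case(wb, overrides, strategies = strategies))
  }
}
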