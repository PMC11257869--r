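# Cost and QALY accounting over a cohort trace: drug acquisition with
# anthropometric dosing, adverse-event management costs and disutilities
# (applied once at model entry), per-cycle follow-up / best-supportive-care /
# subsequent-therapy costs, a one-off palliative-care cost at death, and
# annual discounting on 21-day cycles.

#' Modelled patient population anthropometrics
#'
#' Defaults are the modelled Chinese ES-SCLC population: mean weight 69.6 kg
#' (male) / 59.0 kg (female), body surface area 1.72 m2, creatinine
#' clearance 70 ml/min.
#'
#' @param weight_male,weight_female mean body weight in kg
#' @param prop_male proportion of male patients in \[0, 1\]
#' @param bsa body surface area in m2
#' @param crcl creatinine clearance in ml/min
#' @return a `population` object
#' @export
population <- function(weight_male = 69.6, weight_female = 59.0,
                       prop_male = 0.5, bsa = 1.72, crcl = 70) {
  stopifnot(weight_male > 0, weight_female > 0, bsa > 0, crcl >= 0,
            prop_male >= 0, prop_male <= 1)
  structure(list(weight_male = weight_male, weight_female = weight_female,
                 prop_male = prop_male, bsa = bsa, crcl = crcl),
            class = "population")
}

#' Sex-weighted mean body weight
#'
#' @param pop a [population()]
#' @return prop_male * weight_male + (1 - prop_male) * weight_female, in kg
#' @export
mean_weight <- function(pop) {
  pop$prop_male * pop$weight_male + (1 - pop$prop_male) * pop$weight_female
}

#' Carboplatin dose by the Calvert formula
#'
#' dose (mg) = AUC x (creatinine clearance + 25).
#'
#' @param auc target area under the concentration curve (mg/ml x min)
#' @param crcl creatinine clearance in ml/min
#' @return dose in mg
#' @export
calvert_dose <- function(auc, crcl) {
  if (auc <= 0 || crcl < 0) stop("calvert_dose: auc must be > 0 and crcl >= 0")
  auc * (crcl + 25)
}

#' Dosing rule for one drug
#'
#' @param drug drug name
#' @param basis `"per_kg"` (mg/kg), `"per_bsa"` (mg/m2), `"auc_calvert"`
#'   (Calvert AUC target) or `"flat"` (mg or cost per administration)
#' @param dose_value dose in the basis unit
#' @param price_per_mg price in USD per mg (for `flat_cost` rules use
#'   `price_per_admin` instead)
#' @param price_per_admin flat USD cost per administration; overrides mg
#'   pricing when given together with `basis = "flat"` and `dose_value = NA`
#' @param max_cycles last treatment cycle (1-based count) for
#'   `phase = "induction_only"`; `Inf` = until progression
#' @param phase `"induction_only"` or `"until_progression"`
#' @return a `dosing_rule`
#' @export
dosing_rule <- function(drug, basis = c("per_kg", "per_bsa", "auc_calvert", "flat"),
                        dose_value = NA_real_, price_per_mg = NA_real_,
                        price_per_admin = NA_real_, max_cycles = Inf,
                        phase = c("until_progression", "induction_only")) {
  basis <- match.arg(basis)
  phase <- match.arg(phase)
  if (phase == "induction_only" && !is.finite(max_cycles)) {
    stop("induction_only rules need a finite max_cycles")
  }
  if (is.na(price_per_admin)) {
    if (!is.finite(dose_value) || dose_value <= 0) stop("dose_value must be > 0")
    if (!is.finite(price_per_mg) || price_per_mg < 0) stop("price_per_mg must be >= 0")
  }
  structure(list(drug = drug, basis = basis, dose_value = dose_value,
                 price_per_mg = price_per_mg, price_per_admin = price_per_admin,
                 max_cycles = max_cycles, phase = phase),
            class = "dosing_rule")
}

#' Drug acquisition cost for one cycle
#'
#' Sums, over the rules active at (0-based) cycle `k`, dose times unit
#' price.  `per_kg` doses use the sex-weighted mean weight; `per_bsa` the
#' mean body surface area; `auc_calvert` the Calvert formula at the mean
#' creatinine clearance.  Rules with `phase = "induction_only"` contribute
#' nothing once `k + 1 > max_cycles`.
#'
#' @param rules list of [dosing_rule()]
#' @param pop a [population()]
#' @param k cycle index, 0-based
#' @return USD cost for the cycle
#' @export
drug_cost_per_cycle <- function(rules, pop, k) {
  total <- 0
  for (r in rules) {
    if (r$phase == "induction_only" && (k + 1) > r$max_cycles) next
    if (k + 1 > r$max_cycles) next
    if (!is.na(r$price_per_admin)) {
      total <- total + r$price_per_admin
      next
    }
    dose_mg <- switch(r$basis,
      per_kg = r$dose_value * mean_weight(pop),
      per_bsa = r$dose_value * pop$bsa,
      auc_calvert = calvert_dose(r$dose_value, pop$crcl),
      flat = r$dose_value,
      stop(sprintf("unknown dosing basis '%s'", r$basis)))
    total <- total + dose_mg * r$price_per_mg
  }
  total
}

#' Per-cycle drug cost vector for a whole strategy
#'
#' @param rules list of [dosing_rule()]
#' @param pop a [population()]
#' @param grid a [cycle_grid()]
#' @return numeric vector of length `n_cycles` (cost while progression-free
#'   during cycles 0..n_cycles-1)
#' @export
drug_cost_schedule <- function(rules, pop, grid = cycle_grid()) {
  n <- grid$n_cycles
  out <- numeric(n)
  for (r in rules) {
    per_cycle <- drug_cost_per_cycle(list(r), pop, 0)
    active <- if (is.finite(r$max_cycles)) {
      seq_len(min(n, r$max_cycles))
    } else {
      seq_len(n)
    }
    out[active] <- out[active] + per_cycle
  }
  out
}

#' Adverse-event table entry
#'
#' @param name AE name
#' @param freq_chemo grade 3/4 frequency under reference chemotherapy, in
#'   \[0, 1\]
#' @param unit_cost USD management cost per episode
#' @param disutility utility decrement while the AE lasts, in \[0, 1\]
#' @param duration_days episode duration in days
#' @return an `ae_item`
#' @export
ae_item <- function(name, freq_chemo, unit_cost, disutility, duration_days) {
  stopifnot(freq_chemo >= 0, freq_chemo <= 1, unit_cost >= 0,
            disutility >= 0, disutility <= 1, duration_days >= 0)
  structure(list(name = name, freq_chemo = freq_chemo, unit_cost = unit_cost,
                 disutility = disutility, duration_days = duration_days),
            class = "ae_item")
}

#' One-off adverse-event burden of a strategy
#'
#' The grade 3/4 AE frequency of each item under chemotherapy is scaled by
#' the strategy's AE hazard ratio (capped at 1); cost is the
#' frequency-weighted sum of unit costs and the QALY loss the
#' frequency-weighted sum of disutility times duration (in years).  Both
#' are applied once at model entry.
#'
#' @param items list of [ae_item()]
#' @param hr_ae a [hazard_ratio()] (endpoint AE) or positive scalar
#' @return list with `cost` (USD) and `qaly_loss` (QALYs)
#' @export
ae_burden <- function(items, hr_ae = 1) {
  h <- if (inherits(hr_ae, "hazard_ratio")) hr_ae$point else hr_ae
  if (h <= 0) stop("AE hazard ratio must be positive")
  cost <- 0; qaly <- 0
  for (it in items) {
    f <- min(1, it$freq_chemo * h)
    cost <- cost + f * it$unit_cost
    qaly <- qaly + f * it$disutility * it$duration_days / .DAYS_PER_YEAR
  }
  list(cost = cost, qaly_loss = qaly)
}

#' Health-state utilities
#'
#' Defaults are the Chinese utility scores for the progression-free (0.856)
#' and progressed (0.768) states.
#'
#' @param u_pfd,u_pd utilities in \[0, 1\] with `u_pd <= u_pfd`
#' @return a `utility_set`
#' @export
utility_set <- function(u_pfd = 0.856, u_pd = 0.768) {
  stopifnot(u_pd >= 0, u_pfd <= 1, u_pd <= u_pfd)
  structure(list(u_pfd = u_pfd, u_pd = u_pd), class = "utility_set")
}

#' Economic settings
#'
#' @param discount_rate_annual annual discount rate (default 0.05)
#' @param wtp_low,wtp_high willingness-to-pay thresholds in USD/QALY
#'   (defaults 15,217.00 and 38,042.49, i.e. 1.2x and 3.0x 2022 Chinese
#'   per-capita GDP)
#' @param exchange_rate CNY per USD (default 7.0467)
#' @param cost_followup,cost_bsc per-cycle routine follow-up and best
#'   supportive care costs (USD)
#' @param cost_subsequent per-cycle subsequent anticancer-therapy cost in
#'   the progressed state (USD)
#' @param cost_palliative one-off terminal palliative-care cost (USD)
#' @return an `econ_settings`
#' @export
econ_settings <- function(discount_rate_annual = 0.05,
                          wtp_low = 15217.00, wtp_high = 38042.49,
                          exchange_rate = 7.0467,
                          cost_followup = 0, cost_bsc = 0,
                          cost_subsequent = 0, cost_palliative = 0) {
  stopifnot(discount_rate_annual >= 0, wtp_low >= 0, wtp_high >= wtp_low,
            exchange_rate > 0, cost_followup >= 0, cost_bsc >= 0,
            cost_subsequent >= 0, cost_palliative >= 0)
  structure(list(discount_rate_annual = discount_rate_annual,
                 wtp_low = wtp_low, wtp_high = wtp_high,
                 exchange_rate = exchange_rate,
                 cost_followup = cost_followup, cost_bsc = cost_bsc,
                 cost_subsequent = cost_subsequent,
                 cost_palliative = cost_palliative),
            class = "econ_settings")
}

#' Convert CNY amounts to USD
#'
#' @param cny amount(s) in Chinese yuan
#' @param settings an [econ_settings()] carrying the exchange rate
#' @return USD amounts
#' @export
cny_to_usd <- function(cny, settings = econ_settings()) {
  cny / settings$exchange_rate
}

#' Per-cycle discount factor
#'
#' (1 + r)^(-k * cycle_length / 365.25): continuous compounding of the
#' annual rate at cycle resolution.
#'
#' @param k cycle index (0-based), vectorised
#' @param r annual discount rate, >= 0
#' @param grid a [cycle_grid()]
#' @return discount factors in (0, 1\]
#' @export
discount_factor <- function(k, r, grid = cycle_grid()) {
  if (r < 0) stop("discount rate must be non-negative")
  (1 + r)^(-(k * grid$cycle_length_days / .DAYS_PER_YEAR))
}

#' Accumulate discounted costs and QALYs over a trace
#'
#' Sums, over cycles k = 0..n_cycles-1 with occupancy taken at cycle start
#' and discount factor d_k:
#' cost = sum d_k \[PFD_k (drug_k + followup + bsc) + PD_k (subsequent + bsc)
#' + newdeaths_k palliative\] + AE cost, with newdeaths_k = Dead_{k+1} -
#' Dead_k; QALYs = sum d_k (cycle/365.25) \[PFD_k u_pfd + PD_k u_pd\] - AE
#' QALY loss.  Life-years are reported undiscounted.
#'
#' @param trace a [state_occupancy()] trace
#' @param drug_costs per-cycle drug cost vector of length `n_cycles` (see
#'   [drug_cost_schedule()]), or a scalar
#' @param utilities a [utility_set()]
#' @param settings an [econ_settings()]
#' @param ae output of [ae_burden()] (list with `cost`, `qaly_loss`)
#' @param strategy label carried into the result
#' @return a `ce_result`: list with `strategy`, `total_cost`, `total_qalys`,
#'   `total_lys`
#' @export
accumulate <- function(trace, drug_costs, utilities = utility_set(),
                       settings = econ_settings(),
                       ae = list(cost = 0, qaly_loss = 0),
                       strategy = "strategy") {
  grid <- attr(trace, "grid")
  n <- grid$n_cycles
  if (length(drug_costs) == 1L) drug_costs <- rep(drug_costs, n)
  if (length(drug_costs) != n) {
    stop(sprintf("drug_costs must have length %d (one per cycle), got %d",
                 n, length(drug_costs)))
  }
  k <- 0:(n - 1L)
  d <- discount_factor(k, settings$discount_rate_annual, grid)
  pfd <- trace$pfd[k + 1L]; pd <- trace$pd[k + 1L]
  newdeaths <- trace$dead[k + 2L] - trace$dead[k + 1L]
  cyc_years <- grid$cycle_length_days / .DAYS_PER_YEAR

  cost <- sum(d * (pfd * (drug_costs + settings$cost_followup + settings$cost_bsc) +
                   pd * (settings$cost_subsequent + settings$cost_bsc) +
                   newdeaths * settings$cost_palliative)) + ae$cost
  qalys <- sum(d * cyc_years * (pfd * utilities$u_pfd + pd * utilities$u_pd)) -
    ae$qaly_loss
  lys <- sum((pfd + pd) * cyc_years)

  ce_result(strategy, cost, qalys, lys)
}

#' Cost-effectiveness result for one strategy
#'
#' @param strategy label
#' @param total_cost discounted lifetime cost in USD
#' @param total_qalys discounted QALYs
#' @param total_lys undiscounted life-years (optional)
#' @return a `ce_result`
#' @export
ce_result <- function(strategy, total_cost, total_qalys, total_lys = NA_real_) {
  stopifnot(total_cost >= 0)
  structure(list(strategy = strategy, total_cost = total_cost,
                 total_qalys = total_qalys, total_lys = total_lys),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s: cost $%s, QALYs %.5f, LYs %.5f\n", x$strategy,
              format(round(x$total_cost, 2), big.mark = ","),
              x$total_qalys, x$total_lys))
  invisible(x)
}

#' Bind cost-effectiveness results into a data.frame
#'
#' @param results list of `ce_result`
#' @return data.frame (strategy, cost, qalys, lys)
#' @export
ce_table <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    strategy = r$strategy, cost = r$total_cost, qalys = r$total_qalys,
    lys = r$total_lys, stringsAsFactors = FALSE)))
}
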