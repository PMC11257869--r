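# Dosing, adverse-event burden, discounting and cost/QALY accumulation.

test_that("Calvert carboplatin dosing", {
  expect_equal(calvert_dose(5, 70), 475)
  expect_equal(calvert_dose(5, 0), 125)
  expect_equal(calvert_dose(6, 70), 570)
  expect_error(calvert_dose(-1, 70))
  expect_error(calvert_dose(5, -1))
})

test_that("per-cycle drug costs follow dosing basis and phase rules", {
  pop_m <- population(prop_male = 1)
  flat <- list(dosing_rule("x", "flat", dose_value = 1, price_per_mg = 1000))
  expect_equal(drug_cost_per_cycle(flat, pop_m, 0), 1000)

  perkg <- list(dosing_rule("ici", "per_kg", dose_value = 4.5,
                            price_per_mg = 1))
  expect_equal(drug_cost_per_cycle(perkg, pop_m, 0), 4.5 * 69.6)
  # sex-weighted mean weight
  pop_half <- population(prop_male = 0.5)
  expect_equal(drug_cost_per_cycle(perkg, pop_half, 3),
               4.5 * (0.5 * 69.6 + 0.5 * 59.0))

  ind <- list(dosing_rule("chemo", "flat", dose_value = 100, price_per_mg = 1,
                          max_cycles = 4, phase = "induction_only"))
  expect_equal(drug_cost_per_cycle(ind, pop_m, 3), 100)  # 4th cycle (0-based 3)
  expect_equal(drug_cost_per_cycle(ind, pop_m, 4), 0)    # 5th cycle

  bsa <- list(dosing_rule("etoposide", "per_bsa", dose_value = 300,
                          price_per_mg = 0.05))
  expect_equal(drug_cost_per_cycle(bsa, population(bsa = 1.72), 0),
               300 * 1.72 * 0.05)
  auc <- list(dosing_rule("carboplatin", "auc_calvert", dose_value = 5,
                          price_per_mg = 0.1))
  expect_equal(drug_cost_per_cycle(auc, population(crcl = 70), 0), 47.5)
})

test_that("AE burden is the frequency-weighted one-off sum with HR cap", {
  expect_equal(ae_burden(list(), 1), list(cost = 0, qaly_loss = 0))
  it <- ae_item("x", 0.2, 500, 0.1, 36.525)
  b <- ae_burden(list(it), 1)
  expect_equal(b$cost, 100)
  expect_equal(b$qaly_loss, 0.002)
  capped <- ae_burden(list(it), 6)  # 0.2 * 6 caps at 1
  expect_equal(capped$cost, 500)
  expect_equal(capped$qaly_loss, 0.01)
  expect_error(ae_burden(list(it), 0), "positive")
})

test_that("discounting follows the annual rate at cycle resolution", {
  g <- cycle_grid()
  expect_equal(discount_factor(0, 0.05, g), 1)
  expect_equal(discount_factor(0:10, 0, g), rep(1, 11))
  # k*21 = 365.25 days -> exactly one year
  k_year <- 365.25 / 21
  expect_equal(discount_factor(k_year, 0.05, g), 1 / 1.05, tolerance = 1e-12)
  expect_error(discount_factor(1, -0.01, g), "non-negative")
})

test_that("QALYs equal time alive for an immortal undiscounted cohort", {
  g <- cycle_grid()
  tr <- state_occupancy(function(t) rep(1, length(t)),
                        function(t) rep(1, length(t)), g)
  res <- accumulate(tr, drug_costs = 0, utilities = utility_set(1, 1),
                    settings = econ_settings(discount_rate_annual = 0,
                                             wtp_low = 1, wtp_high = 2,
                                             exchange_rate = 7.0467))
  expect_equal(res$total_cost, 0)
  expect_equal(res$total_qalys, 20, tolerance = 21 / 365.25)
  expect_equal(res$total_lys, res$total_qalys)
})

test_that("palliative cost is paid exactly once when everyone dies", {
  g <- cycle_grid()
  die_now <- function(t) ifelse(t == 0, 1, 0)
  tr <- state_occupancy(die_now, die_now, g)
  st <- econ_settings(discount_rate_annual = 0, cost_palliative = 1800)
  res <- accumulate(tr, 0, utility_set(), st)
  expect_equal(res$total_cost, 1800)
})

test_that("death conservation: palliative total equals final mortality", {
  wb <- demo_workbook()
  g <- cycle_grid()
  os <- parametric_survival("loglogistic", unlist(wb$chemo_survival$os))
  pfs <- parametric_survival("loglogistic", unlist(wb$chemo_survival$pfs))
  tr <- state_occupancy(pfs, os, g)
  st <- econ_settings(discount_rate_annual = 0, cost_palliative = 1000)
  res <- accumulate(tr, 0, utility_set(0, 0), st)
  expect_equal(res$total_cost, 1000 * tr$dead[nrow(tr)], tolerance = 1e-9)
})

test_that("accumulation equals an independent cycle-by-cycle oracle", {
  wb <- demo_workbook()
  grid <- cycle_grid()
  strategy <- "serplulimab+chemo"
  res <- run_strategy(wb, strategy, grid)

  # brute-force re-accumulation: scalar loop over all 348 cycles, written
  # directly from the accounting definitions
  pfs <- parametric_survival("loglogistic", unlist(wb$chemo_survival$pfs))
  os <- parametric_survival("loglogistic", unlist(wb$chemo_survival$os))
  hr <- wb$hrs[[strategy]]
  cost <- 0; qalys <- 0
  ae <- ae_burden(wb$ae_items, hr$ae[1])
  st <- wb$settings; ut <- wb$utilities
  for (k in 0:(grid$n_cycles - 1)) {
    t0 <- k * 21 / 30.4375; t1 <- (k + 1) * 21 / 30.4375
    sp0 <- eval_survival(pfs, t0)^hr$pfs[1]
    so0 <- eval_survival(os, t0)^hr$os[1]
    so1 <- eval_survival(os, t1)^hr$os[1]
    pfd <- min(sp0, so0); dead0 <- 1 - so0; pd <- 1 - dead0 - pfd
    newdeaths <- (1 - so1) - (1 - so0)
    d <- (1 + st$discount_rate_annual)^(-(k * 21 / 365.25))
    drug <- drug_cost_per_cycle(wb$dosing[[strategy]], wb$population, k)
    cost <- cost + d * (pfd * (drug + st$cost_followup + st$cost_bsc) +
                        pd * (st$cost_subsequent + st$cost_bsc) +
                        newdeaths * st$cost_palliative)
    qalys <- qalys + d * (21 / 365.25) * (pfd * ut$u_pfd + pd * ut$u_pd)
  }
  cost <- cost + ae$cost
  qalys <- qalys - ae$qaly_loss
  expect_equal(res$total_cost, cost, tolerance = 1e-6)
  expect_equal(res$total_qalys, qalys, tolerance = 1e-6)
})

test_that("cost and discount monotonicity hold on the demo case", {
  wb <- demo_workbook()
  base <- run_strategy(wb, "serplulimab+chemo")
  up <- run_strategy(wb_set(wb, "cost_bsc", wb$settings$cost_bsc * 2),
                     "serplulimab+chemo")
  expect_gte(up$total_cost, base$total_cost)
  disc <- run_strategy(wb_set(wb, "discount_rate", 0.08), "serplulimab+chemo")
  expect_lte(disc$total_cost, base$total_cost)
  expect_lte(disc$total_qalys, base$total_qalys)
  # QALY ceiling: utility-weighted horizon
  expect_lte(base$total_qalys, wb$utilities$u_pfd * 20 + 1e-9)
  expect_lte(base$total_qalys, base$total_lys)
})

test_that("currency conversion inverts exactly", {
  st <- econ_settings()
  usd <- c(100, 21409.67)
  expect_equal(cny_to_usd(usd * 7.0467, st), usd)
})
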