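# One-way DSA, threshold search, probabilistic sensitivity analysis,
# acceptability curves and subgroup runs.

# a tiny deterministic ICER runner: linear in "price", flat in "inert"
.toy_runner <- function(overrides = NULL) {
  price <- overrides[["price"]] %||% 10
  5000 + 300 * price
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("tornado entries rank by spread and keep inert parameters", {
  specs <- list(param_spec("price", 10, 5, 15, "gamma"),
                param_spec("inert", 1, 0.5, 1.5, "uniform"))
  runner <- function(overrides = NULL) .toy_runner(overrides)
  tor <- dsa_oneway(specs, runner)
  expect_identical(tor$param, c("price", "inert"))
  expect_equal(tor$spread[tor$param == "inert"], 0)
  expect_equal(tor$icer_low[tor$param == "price"], 5000 + 300 * 5)
  expect_equal(tor$icer_high[tor$param == "price"], 5000 + 300 * 15)
  expect_false(any(tor$error))
  # every spec appears exactly once
  expect_setequal(tor$param, vapply(specs, `[[`, character(1), "name"))
})

test_that("ICER increases with the discount rate when costs come early", {
  # all costs at entry (AE burden), QALYs accrue later: discounting the
  # QALYs more cannot lower the ICER
  wb <- demo_workbook()
  wb$settings$cost_followup <- 0; wb$settings$cost_bsc <- 0
  wb$settings$cost_subsequent <- 0; wb$settings$cost_palliative <- 0
  for (s in names(wb$dosing)) {
    wb$dosing[[s]] <- lapply(wb$dosing[[s]], function(r) {
      r$max_cycles <- 1; r$phase <- "induction_only"; r
    })
  }
  runner <- make_icer_runner(wb, "serplulimab+chemo")
  icers <- vapply(c(0, 0.04, 0.08),
                  function(r) runner(list(discount_rate = r)), numeric(1))
  expect_true(all(diff(icers) > 0))
})

test_that("DSA on the demo case ranks the OS hazard ratio first", {
  wb <- demo_workbook()
  runner <- make_icer_runner(wb, "serplulimab+chemo")
  specs <- default_dsa_specs(wb, "serplulimab+chemo")
  sub <- specs[c("hr_os.serplulimab+chemo", "weight_mean",
                 "price.serplulimab")]
  tor <- dsa_oneway(sub, runner)
  expect_identical(tor$param[1], "hr_os.serplulimab+chemo")
})

test_that("bisection finds the closed-form root of a linear ICER", {
  spec <- param_spec("price", 10, 0, 20, "uniform")
  runner <- function(overrides = NULL) .toy_runner(overrides)
  # 5000 + 300 p = 8000  =>  p = 10
  expect_equal(threshold_search(spec, 8000, runner), 10, tolerance = 1e-5)
  # no crossing inside the interval
  expect_true(is.na(threshold_search(spec, 20000, runner)))
  # non-monotone runner is refused
  bad <- function(overrides = NULL) (overrides[["price"]] %||% 0 - 10)^2
  expect_error(threshold_search(spec, 5, bad), "monotone")
})

test_that("bisection agrees with a grid-scan oracle on the demo case", {
  wb <- demo_workbook()
  runner <- make_icer_runner(wb, "serplulimab+chemo")
  p0 <- 8.4
  spec <- param_spec("price.serplulimab", p0, 0.01, p0, "gamma")
  wtp <- wb$settings$wtp_high
  root <- threshold_search(spec, wtp, runner)
  expect_false(is.na(root))
  # locate the crossing by scanning a bracketed sub-grid around the root
  grid <- seq(0.01, p0, length.out = 10000)
  sub <- grid[abs(grid - root) < (p0 / 10000) * 50]
  f <- vapply(sub, function(p) runner(list(`price.serplulimab` = p)) - wtp,
              numeric(1))
  cross <- which(diff(sign(f)) != 0)
  expect_length(cross, 1L)
  expect_lt(abs(root - sub[cross]), 2 * (p0 - 0.01) / 9999)
})

test_that("PSA distributions are mean-preserving with the stated spread", {
  set.seed(1)
  g <- param_spec("cost_bsc", 100, 75, 125, "gamma")
  x <- draw_param(g, 10000)
  expect_lt(abs(mean(x) / 100 - 1), 0.02)
  b <- param_spec("u_pfd", 0.856, 0.642, 1, "beta")
  y <- draw_param(b, 10000)
  expect_true(all(y >= 0 & y <= 1))
  expect_lt(abs(mean(y) - 0.856), 0.01)
  ln <- param_spec("hr_os.x", 0.63, 0.49, 0.82, "lognormal")
  z <- draw_param(ln, 10000)
  expect_lt(abs(stats::median(z) - 0.63), 0.01)
  expect_lt(abs(stats::quantile(z, 0.975) - 0.82), 0.03)
})

test_that("degenerate distributions reproduce the base case in every draw", {
  wb <- demo_workbook()
  specs <- list(param_spec("u_pfd", 0.856, 0.856, 0.856, "fixed"),
                param_spec("cost_bsc", 100, 100, 100, "fixed"))
  runner <- make_ce_runner(wb, c("chemotherapy", "serplulimab+chemo"))
  ps <- psa(specs, runner, n = 5, seed = 1)
  base <- runner()
  for (i in 1:5) {
    got <- ps$samples[ps$samples$draw == i, ]
    expect_equal(got$cost, base$cost)
    expect_equal(got$qalys, base$qalys)
  }
})

test_that("PSA is seed-deterministic", {
  wb <- demo_workbook()
  specs <- default_dsa_specs(wb, "serplulimab+chemo")
  runner <- make_ce_runner(wb, c("chemotherapy", "serplulimab+chemo"))
  a <- psa(specs, runner, n = 20, seed = 99)
  b <- psa(specs, runner, n = 20, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_identical(a$samples, b$samples)
  c_ <- psa(specs, runner, n = 20, seed = 100)
  expect_false(identical(a$draws, c_$draws))
})

test_that("CEAC probabilities are proper and match definitions", {
  one <- data.frame(draw = 1:5, strategy = "only",
                    cost = stats::runif(5), qalys = stats::runif(5))
  cc <- ceac(one, wtp_grid = c(0, 1000))
  expect_true(all(cc$probability == 1))

  set.seed(7)
  n <- 400
  s1 <- data.frame(draw = 1:n, strategy = "a", cost = stats::rnorm(n, 100, 30),
                   qalys = stats::rnorm(n, 1, 0.1))
  s2 <- data.frame(draw = 1:n, strategy = "b", cost = stats::rnorm(n, 120, 30),
                   qalys = stats::rnorm(n, 1.2, 0.1))
  both <- rbind(s1, s2)[order(rep(1:n, 2)), ]
  cc2 <- ceac(both, wtp_grid = c(0, 500, 5000))
  sums <- tapply(cc2$probability, cc2$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # at wtp = 0 the cheapest-per-draw strategy wins
  p0 <- cc2$probability[cc2$wtp == 0 & cc2$strategy == "a"]
  frac <- mean(s1$cost < s2$cost)
  expect_equal(p0, frac)
  expect_error(ceac(both, numeric(0)), "empty")
})

test_that("CEAC matches the closed-form normal probability", {
  # two strategies with bivariate-normal (delta cost, delta qaly): the
  # acceptance probability at wtp w is P(w*dq - dc > 0), available in
  # closed form
  set.seed(123)
  n <- 10000
  dc <- stats::rnorm(n, 30000, 8000)
  dq <- stats::rnorm(n, 0.5, 0.15)
  ref_cost <- 20000; ref_q <- 1
  samples <- rbind(
    data.frame(draw = 1:n, strategy = "ref", cost = ref_cost, qalys = ref_q),
    data.frame(draw = 1:n, strategy = "new", cost = ref_cost + dc,
               qalys = ref_q + dq))
  samples <- samples[order(samples$draw), ]
  grid <- seq(0, 120000, by = 20000)
  cc <- ceac(samples, grid)
  for (w in grid) {
    analytic <- stats::pnorm(0, mean = w * 0.5 - 30000,
                             sd = sqrt(w^2 * 0.15^2 + 8000^2),
                             lower.tail = FALSE)
    got <- cc$probability[cc$wtp == w & cc$strategy == "new"]
    expect_lt(abs(got - analytic), 0.02)
  }
})

test_that("subgroup runs reduce to the base case for identical HRs", {
  wb <- demo_workbook()
  strategies <- setdiff(names(wb$hrs), "chemotherapy")
  tab <- do.call(rbind, lapply(strategies, function(s) data.frame(
    subgroup = "all", strategy = s,
    hr_os = wb$hrs[[s]]$os[1], hr_pfs = wb$hrs[[s]]$pfs[1])))
  sg <- subgroup_run(wb, tab)
  base <- ce_table(run_base_case(wb))
  expect_equal(sg$all$table, base)
})

test_that("gender subgroups use sex-specific weight in per-kg dosing", {
  wb <- demo_workbook()
  strategies <- setdiff(names(wb$hrs), "chemotherapy")
  mk <- function(sgname) do.call(rbind, lapply(strategies, function(s)
    data.frame(subgroup = sgname, strategy = s, hr_os = wb$hrs[[s]]$os[1],
               hr_pfs = wb$hrs[[s]]$pfs[1])))
  sg <- subgroup_run(wb, rbind(mk("male"), mk("female")))
  # serplulimab is dosed per kg: per-cycle drug cost scales as 69.6 / 59.0
  male_cost <- drug_cost_per_cycle(wb$dosing[["serplulimab+chemo"]][3],
                                   population(prop_male = 1), 10)
  female_cost <- drug_cost_per_cycle(wb$dosing[["serplulimab+chemo"]][3],
                                     population(prop_male = 0), 10)
  expect_equal(male_cost / female_cost, 69.6 / 59.0)
  expect_gt(sg$male$table$cost[sg$male$table$strategy == "serplulimab+chemo"],
            sg$female$table$cost[sg$female$table$strategy == "serplulimab+chemo"] *
              0.9)
  expect_warning(subgroup_run(wb, mk("partial")[1:2, ]), "missing HRs")
})

test_that("a lower subgroup OS hazard ratio raises incremental QALYs", {
  wb <- demo_workbook()
  strategies <- setdiff(names(wb$hrs), "chemotherapy")
  mk <- function(sgname, f) do.call(rbind, lapply(strategies, function(s)
    data.frame(subgroup = sgname, strategy = s,
               hr_os = wb$hrs[[s]]$os[1] * f, hr_pfs = wb$hrs[[s]]$pfs[1])))
  sg <- subgroup_run(wb, rbind(mk("overall", 1), mk("better", 0.8)))
  q_over <- sg$overall$table
  q_bett <- sg$better$table
  chemo_q <- function(tb) tb$qalys[tb$strategy == "chemotherapy"]
  for (s in strategies) {
    expect_gt(q_bett$qalys[q_bett$strategy == s] - chemo_q(q_bett),
              q_over$qalys[q_over$strategy == s] - chemo_q(q_over))
  }
})
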