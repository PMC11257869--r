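# Three-state cohort model: progression-free disease (PFD), progressed
# disease (PD), death.  State occupancy is derived from the PFS and OS
# curves by partitioned-survival assignment: Dead = 1 - S_OS, PFD =
# min(S_PFS, S_OS), PD = remainder.  This reproduces both marginal curves
# exactly and needs no separate PD -> death rate.

#' Cycle grid for the cohort model
#'
#' @param cycle_length_days cycle length in days (default 21, the treatment
#'   administration interval)
#' @param horizon_years model horizon in years (default 20)
#' @return list with `cycle_length_days`, `horizon_years`, `n_cycles`
#'   (= ceiling(horizon_years * 365.25 / cycle_length_days); 348 for the
#'   defaults) and `times_months`, the cycle-start times in months
#' @export
cycle_grid <- function(cycle_length_days = 21, horizon_years = 20) {
  stopifnot(cycle_length_days > 0, horizon_years > 0)
  n_cycles <- ceiling(horizon_years * .DAYS_PER_YEAR / cycle_length_days)
  structure(list(
    cycle_length_days = cycle_length_days,
    horizon_years = horizon_years,
    n_cycles = as.integer(n_cycles),
    times_months = cycle_to_months(0:n_cycles, cycle_length_days)
  ), class = "cycle_grid")
}

#' Per-cycle conditional transition probability from a survival curve
#'
#' The probability of the event during cycle `k` given event-free survival
#' to its start: 1 - S(t_{k+1}) / S(t_k).  By convention the probability is
#' 1 once S(t_k) = 0 (the cohort is absorbed).
#'
#' @param s survival evaluator: function of time in months, or a
#'   `parametric_survival`
#' @param k cycle index (0-based), vectorised
#' @param grid a [cycle_grid()]
#' @return transition probabilities in \[0, 1\]
#' @export
transition_prob <- function(s, k, grid = cycle_grid()) {
  f <- .as_evaluator(s)
  t0 <- cycle_to_months(k, grid$cycle_length_days)
  t1 <- cycle_to_months(k + 1, grid$cycle_length_days)
  s0 <- f(t0); s1 <- f(t1)
  ifelse(s0 <= 0, 1, pmin(1, pmax(0, 1 - s1 / s0)))
}

.as_evaluator <- function(s) {
  if (inherits(s, "parametric_survival")) {
    function(t) eval_survival(s, t)
  } else if (is.function(s)) {
    s
  } else {
    stop("survival evaluator must be a function or a parametric_survival")
  }
}

#' Cohort occupancy from PFS and OS curves
#'
#' Partitioned-survival state occupancy on a cycle grid.  When the
#' HR-adjusted PFS curve crosses above the OS curve (possible because the
#' two endpoints receive independent hazard-ratio powers), PFD is clamped
#' to S_OS and PD set to 0 at the affected cycles; the number of clamped
#' cycles is recorded in the `n_clamped` attribute.
#'
#' @param s_pfs,s_os survival evaluators (functions of months or
#'   `parametric_survival` objects)
#' @param grid a [cycle_grid()]
#' @return a `cohort_trace`: data.frame with columns `cycle`, `time_months`,
#'   `pfd`, `pd`, `dead`; rows 0..n_cycles; every row sums to 1
#' @export
state_occupancy <- function(s_pfs, s_os, grid = cycle_grid()) {
  f_pfs <- .as_evaluator(s_pfs); f_os <- .as_evaluator(s_os)
  t <- grid$times_months
  sp <- f_pfs(t); so <- f_os(t)
  for (nm in c("sp", "so")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v < -1e-12) || any(v > 1 + 1e-12)) {
      stop("survival evaluator returned values outside [0, 1]")
    }
  }
  sp <- pmin(pmax(sp, 0), 1); so <- pmin(pmax(so, 0), 1)
  n_clamped <- sum(sp > so + 1e-12)
  pfd <- pmin(sp, so)
  dead <- 1 - so
  pd <- pmax(0, so - pfd)  # exact 0 where the curves are clamped
  out <- data.frame(cycle = 0:grid$n_cycles, time_months = t,
                    pfd = pfd, pd = pd, dead = dead)
  structure(out, class = c("cohort_trace", "data.frame"),
            grid = grid, n_clamped = n_clamped)
}

#' @export
print.cohort_trace <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<cohort_trace> %d cycles of %g days (%.1f years horizon)\n",
              g$n_cycles, g$cycle_length_days, g$horizon_years))
  cat(sprintf("  final occupancy: PFD %.4f, PD %.4f, Dead %.4f; clamped cycles: %d\n",
              x$pfd[nrow(x)], x$pd[nrow(x)], x$dead[nrow(x)],
              attr(x, "n_clamped")))
  invisible(x)
}

#' Undiscounted life-years of a trace
#'
#' Sum of time alive across cycles (occupancy at cycle start times cycle
#' length), which equals the left-endpoint Riemann sum of S_OS.
#'
#' @param trace a `cohort_trace`
#' @return life-years
#' @export
trace_life_years <- function(trace) {
  g <- attr(trace, "grid")
  alive <- trace$pfd + trace$pd
  sum(alive[-length(alive)]) * g$cycle_length_days / .DAYS_PER_YEAR
}

#' Write a cohort trace to CSV
#'
#' @param trace a `cohort_trace`
#' @param path output path
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
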