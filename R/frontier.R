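# Incremental cost-effectiveness ratios, stepwise dominance comparison and
# the efficiency frontier.  Strategies are sorted by ascending cost; each
# elimination round drops strategies that are dominated by their previous
# remaining alternative (fewer QALYs at higher cost) or extended-dominated
# (sequential ICER above the next alternative's), until the sequential
# ICERs along the surviving chain are strictly increasing.

#' Incremental cost-effectiveness ratio
#'
#' (cost_a - cost_b) / (qalys_a - qalys_b), sign preserved.  Equal-QALY
#' comparisons have no meaningful ratio and raise an error; resolve them by
#' cost dominance instead.
#'
#' @param a,b `ce_result` objects (or lists with `total_cost`,
#'   `total_qalys`)
#' @return USD per QALY, signed
#' @export
icer <- function(a, b) {
  dq <- a$total_qalys - b$total_qalys
  if (dq == 0) {
    stop("equal QALYs: comparison is a dominance case, not a ratio")
  }
  (a$total_cost - b$total_cost) / dq
}

#' Net monetary benefit
#'
#' @param r a `ce_result`
#' @param wtp willingness-to-pay threshold in USD/QALY, >= 0
#' @return wtp * qalys - cost, in USD
#' @export
nmb <- function(r, wtp) {
  if (any(wtp < 0)) stop("willingness-to-pay must be non-negative")
  wtp * r$total_qalys - r$total_cost
}

# one stepwise round on a cost-ascending table: returns the table with
# incremental cost/qalys vs previous row, sequential ICER, and a flag for
# strategies to eliminate this round ("D" = dominated by previous
# alternative, "ED" = extended dominated by next alternative)
.stepwise_round <- function(tab) {
  n <- nrow(tab)
  tab$inc_cost <- c(NA, diff(tab$cost))
  tab$inc_qalys <- c(NA, diff(tab$qalys))
  tab$seq_icer <- tab$inc_cost / tab$inc_qalys
  tab$flag <- ""
  if (n < 2) return(tab)
  for (i in 2:n) {
    if (tab$inc_qalys[i] < 0 ||
        (tab$inc_qalys[i] == 0 && tab$inc_cost[i] > 0)) {
      tab$flag[i] <- "D"
    }
  }
  # extended dominance: a non-dominated strategy whose sequential ICER
  # exceeds that of the next non-dominated alternative
  icers <- which(tab$flag == "" & !is.na(tab$seq_icer) & tab$inc_qalys > 0)
  if (length(icers) >= 2) {
    for (j in seq_len(length(icers) - 1)) {
      if (tab$seq_icer[icers[j]] > tab$seq_icer[icers[j + 1]]) {
        tab$flag[icers[j]] <- "ED"
      }
    }
  }
  tab
}

#' Stepwise dominance-ranked comparison and efficiency frontier
#'
#' Sorts strategies by ascending cost and eliminates dominated and
#' extended-dominated strategies in rounds until the sequential ICERs along
#' the surviving chain strictly increase.  Final status labels are global:
#' a strategy is `dominated` if some other strategy has lower-or-equal cost
#' and greater-or-equal QALYs (one strictly), `extended_dominated` if it was
#' eliminated without being strictly dominated, `frontier` otherwise.
#'
#' @param results list of `ce_result` (>= 2 strategies)
#' @param comparator optional strategy name for pairwise ICER reporting;
#'   defaults to the cheapest strategy
#' @return a `frontier_result`: list with `table` (one row per strategy:
#'   cost, qalys, status, elimination round, sequential ICER on the final
#'   frontier, pairwise ICER vs the comparator) and `rounds` (the per-round
#'   stepwise tables mirroring a stepwise comparison printout)
#' @export
frontier <- function(results, comparator = NULL) {
  if (length(results) < 2) stop("need at least 2 strategies")
  tab0 <- ce_table(results)
  if (anyDuplicated(tab0$strategy)) stop("duplicate strategy names")
  # deterministic tie-break on identical cost: by name
  tab0 <- tab0[order(tab0$cost, tab0$strategy), ]
  rownames(tab0) <- NULL
  if (is.null(comparator)) comparator <- tab0$strategy[1]
  if (!comparator %in% tab0$strategy) stop("unknown comparator strategy")

  status <- stats::setNames(rep("frontier", nrow(tab0)), tab0$strategy)

  # phase 1: global strict dominance (higher-or-equal cost with
  # lower-or-equal QALYs against any single alternative, one strict)
  for (i in seq_len(nrow(tab0))) {
    dom <- any(tab0$cost <= tab0$cost[i] & tab0$qalys >= tab0$qalys[i] &
               (tab0$cost < tab0$cost[i] | tab0$qalys > tab0$qalys[i]))
    if (dom) status[tab0$strategy[i]] <- "dominated"
  }

  # phase 2: iterative extended-dominance removal (one strategy per pass,
  # recomputing) until sequential ICERs strictly increase along the chain
  keep <- tab0[status[tab0$strategy] == "frontier", , drop = FALSE]
  while (nrow(keep) >= 3) {
    ic <- diff(keep$cost) / diff(keep$qalys)
    viol <- which(diff(ic) <= 0)
    if (!length(viol)) break
    ed <- keep$strategy[viol[1] + 1L]  # the strategy whose ICER is not undercut
    status[ed] <- "extended_dominated"
    keep <- keep[keep$strategy != ed, , drop = FALSE]
  }

  # paper-style stepwise presentation: per displayed round, flag strategies
  # dominated by their previous alternative (D) or with a sequential ICER
  # above the next alternative's (ED), then exclude them and repeat; this
  # reporting converges to the same frontier on well-behaved tables and
  # records the pass in which each strategy drops out
  elim_round <- stats::setNames(rep(NA_integer_, nrow(tab0)), tab0$strategy)
  rounds <- list()
  disp <- tab0
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    stepped <- .stepwise_round(disp)
    rounds[[round_i]] <- stepped
    out <- stepped$flag != "" & status[stepped$strategy] != "frontier"
    if (!any(out)) break
    elim_round[stepped$strategy[out]] <- round_i
    disp <- disp[!out, , drop = FALSE]
    if (nrow(disp) < 2) break
  }

  final <- .stepwise_round(keep)
  tab0$status <- status[tab0$strategy]
  tab0$elim_round <- elim_round[tab0$strategy]
  tab0$seq_icer <- final$seq_icer[match(tab0$strategy, final$strategy)]
  cmp <- tab0[tab0$strategy == comparator, ]
  tab0$pairwise_icer <- vapply(seq_len(nrow(tab0)), function(i) {
    if (tab0$strategy[i] == comparator || tab0$qalys[i] == cmp$qalys) {
      return(NA_real_)
    }
    (tab0$cost[i] - cmp$cost) / (tab0$qalys[i] - cmp$qalys)
  }, numeric(1))

  structure(list(table = tab0, rounds = rounds, comparator = comparator),
            class = "frontier_result")
}

#' @export
print.frontier_result <- function(x, ...) {
  cat(sprintf("<frontier_result> %d strategies, comparator: %s\n",
              nrow(x$table), x$comparator))
  print(transform(x$table, cost = round(cost, 2), qalys = round(qalys, 5),
                  seq_icer = round(seq_icer, 2),
                  pairwise_icer = round(pairwise_icer, 2)))
  invisible(x)
}

#' Strategies on the final efficiency frontier
#'
#' @param fr a [frontier()] result
#' @return character vector of strategy names, ascending cost
#' @export
frontier_strategies <- function(fr) {
  fr$table$strategy[fr$table$status == "frontier"]
}

#' Write the stepwise comparison table to CSV
#'
#' One row per strategy with incremental columns computed against the
#' previous (cheaper) alternative of the first stepwise round, plus status.
#'
#' @param fr a [frontier()] result
#' @param path output CSV path
#' @export
write_stepwise <- function(fr, path) {
  first <- fr$rounds[[1]]
  out <- data.frame(strategy = first$strategy, cost = first$cost,
                    qalys = first$qalys, inc_cost = first$inc_cost,
                    inc_qalys = first$inc_qalys, icer = first$seq_icer,
                    status = fr$table$status[match(first$strategy,
                                                   fr$table$strategy)])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
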