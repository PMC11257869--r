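# Reconstruction of pseudo individual patient data from digitized
# Kaplan-Meier coordinates and published numbers-at-risk tables.  The
# interval-wise inversion solves, within each risk-table interval, for the
# numbers of events and censorings consistent with the digitized step drops
# and the next interval's number at risk; censor times are placed at evenly
# spaced (deterministic) positions within the interval.

#' Digitized Kaplan-Meier curve with numbers at risk
#'
#' @param points data.frame with columns `time` (months, >= 0, strictly
#'   increasing, first row at time 0) and `survival` (fractions in (0, 1\],
#'   non-increasing, first value 1)
#' @param risk_table data.frame with columns `time` and `n_at_risk`
#'   (non-negative, non-increasing, >= 2 rows), or `NULL` if only an
#'   effective sample size is known (see `n_total`)
#' @param arm_label,endpoint metadata carried through to the output
#' @param n_total effective sample size; required when `risk_table` is
#'   `NULL`, otherwise taken from the first risk-table row
#' @return an object of class `digitized_km`
#' @export
digitized_km <- function(points, risk_table = NULL, arm_label = "arm",
                         endpoint = c("OS", "PFS"), n_total = NULL) {
  endpoint <- match.arg(endpoint)
  points <- as.data.frame(points)
  stopifnot(all(c("time", "survival") %in% names(points)))
  points <- points[order(points$time), c("time", "survival")]
  if (nrow(points) < 2) stop("need at least 2 digitized points")
  if (points$time[1] != 0 || abs(points$survival[1] - 1) > 1e-9) {
    stop("first digitized point must be (0, 1)")
  }
  if (any(diff(points$time) <= 0)) stop("digitized times must be strictly increasing")
  if (any(diff(points$survival) > 1e-9)) {
    stop("digitized survival must be non-increasing")
  }
  if (any(points$survival <= 0) || any(points$survival > 1)) {
    stop("digitized survival must lie in (0, 1]")
  }
  if (!is.null(risk_table)) {
    risk_table <- as.data.frame(risk_table)
    stopifnot(all(c("time", "n_at_risk") %in% names(risk_table)))
    risk_table <- risk_table[order(risk_table$time), c("time", "n_at_risk")]
    if (nrow(risk_table) < 2) stop("risk table needs at least 2 rows")
    if (any(risk_table$n_at_risk < 0) ||
        any(risk_table$n_at_risk != round(risk_table$n_at_risk))) {
      stop("n_at_risk must be non-negative integers")
    }
    if (any(diff(risk_table$n_at_risk) > 0)) stop("n_at_risk must be non-increasing")
    n_total <- risk_table$n_at_risk[1]
  } else if (is.null(n_total)) {
    stop("supply either a risk_table or n_total")
  }
  structure(list(points = points, risk_table = risk_table,
                 arm_label = arm_label, endpoint = endpoint,
                 n_total = as.integer(n_total)),
            class = "digitized_km")
}

#' Pseudo individual patient data
#'
#' @param time event/censoring times, all > 0
#' @param event 1 = event, 0 = censored
#' @param arm_label,endpoint metadata
#' @param validate check invariants (disable only internally)
#' @return data.frame of class `pseudo_ipd` with columns `time`, `event`
#' @export
pseudo_ipd <- function(time, event, arm_label = "arm", endpoint = "OS",
                       validate = TRUE) {
  if (validate) {
    stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
    if (any(time <= 0)) stop("all IPD times must be positive")
  }
  structure(data.frame(time = as.numeric(time), event = as.integer(event)),
            arm_label = arm_label, endpoint = endpoint,
            class = c("pseudo_ipd", "data.frame"))
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the step function as
#' a data.frame anchored at S(0) = 1.
#'
#' @param ipd a [pseudo_ipd()] object or data.frame with `time`, `event`
#' @return data.frame (time, survival, n_risk, n_event) of class `km_curve`,
#'   first row (0, 1)
#' @export
km_estimate <- function(ipd) {
  if (nrow(ipd) == 0) stop("empty IPD")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd,
                          conf.type = "none")
  out <- data.frame(time = c(0, sf$time), survival = c(1, sf$surv),
                    n_risk = c(nrow(ipd), sf$n.risk),
                    n_event = c(0, sf$n.event))
  class(out) <- c("km_curve", "data.frame")
  out
}

# evaluate a km_curve (right-continuous step function) at times t
.km_eval <- function(km, t) {
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$survival[pmax(idx, 1)])
}

#' Evaluate a Kaplan-Meier step function
#'
#' Right-continuous evaluation of a [km_estimate()] curve.
#'
#' @param km a `km_curve`
#' @param t evaluation times
#' @return survival fractions
#' @export
km_eval <- function(km, t) .km_eval(km, t)

# time at which survival first drops to <= s (Inf if never)
.km_quantile <- function(km, s) {
  hit <- which(km$survival <= s)
  if (length(hit) == 0) Inf else km$time[hit[1]]
}

#' Reconstruct pseudo-IPD from a digitized KM curve
#'
#' Within each interval between consecutive risk-table rows, the number of
#' censorings is solved iteratively so that the reconstructed number at risk
#' at the start of the next interval matches the published value exactly,
#' while events are allocated at the digitized drop times in proportion to
#' the relative step drops.  Censor times are placed at evenly spaced
#' positions inside the interval (deterministic).  Patients still at risk
#' after the last digitized time are administratively censored there.
#'
#' When the curve carries no risk table, all censoring is assumed to occur
#' after the last event (administrative censoring only), using the stated
#' effective sample size; this degraded mode is flagged with a message.
#'
#' @param km a [digitized_km()] object
#' @return a [pseudo_ipd()] with one record per initially at-risk patient
#' @export
reconstruct_ipd <- function(km) {
  stopifnot(inherits(km, "digitized_km"))
  pts <- km$points
  if (is.null(km$risk_table)) {
    message("no risk table supplied: assuming censoring only after last event")
    return(.reconstruct_no_risk_table(km))
  }
  rt <- km$risk_table
  t_max <- max(pts$time)

  # interval i covers (rt$time[i], rt$time[i+1]]; a final open-ended
  # interval runs from the last risk time to the last digitized point
  bounds <- c(rt$time, Inf)
  n_int <- length(rt$time)

  ev_time <- numeric(0); ev_n <- integer(0)
  cs_time <- numeric(0); cs_n <- integer(0)

  n_cur <- rt$n_at_risk[1]
  s_cur <- 1  # running reconstructed KM value

  for (i in seq_len(n_int)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    in_int <- which(pts$time > lo & pts$time <= hi)
    target <- if (i < n_int) rt$n_at_risk[i + 1] else NA_integer_

    # simulate the interval for a given total number of censorings C,
    # spread evenly; returns allocation and end-of-interval state
    hi_eff <- if (is.finite(hi)) hi else t_max
    sim <- function(C) {
      c_times <- if (C > 0) lo + seq_len(C) * (hi_eff - lo) / (C + 1) else numeric(0)
      n <- n_cur; s <- s_cur
      d_k <- integer(length(in_int)); c_used <- 0L
      for (j in seq_along(in_int)) {
        tk <- pts$time[in_int[j]]
        ncens <- sum(c_times < tk) - c_used
        n <- n - ncens; c_used <- c_used + ncens
        if (n <= 0) { n <- 0; next }
        drop <- max(0, 1 - pts$survival[in_int[j]] / s)
        d <- round(n * drop)
        d <- min(d, n)
        if (d > 0) s <- s * (n - d) / n
        d_k[j] <- d
        n <- n - d
      }
      n <- n - (C - c_used)  # censorings after the last drop in interval
      list(n_end = n, s_end = s, d_k = d_k, c_times = c_times)
    }

    if (is.na(target)) {
      # tail beyond the last risk-table row: events from the curve, then
      # administrative censoring of everyone left at the last digitized time
      res <- sim(0L)
      if (length(in_int)) {
        ev_time <- c(ev_time, pts$time[in_int]); ev_n <- c(ev_n, res$d_k)
      }
      if (res$n_end > 0) {
        cs_time <- c(cs_time, t_max); cs_n <- c(cs_n, res$n_end)
      }
      n_cur <- 0L; s_cur <- res$s_end
    } else {
      C <- max(0L, n_cur - target - sum(sim(0L)$d_k))
      res <- sim(C)
      for (iter in 1:40) {
        if (res$n_end == target) break
        C <- C + (res$n_end - target)
        if (C < 0) break
        res <- sim(C)
      }
      if (res$n_end != target) {
        stop(sprintf(paste0("risk table inconsistent with digitized curve in ",
                            "interval %d (%g, %g]: cannot reach n_at_risk = %d"),
                     i, lo, hi_eff, target))
      }
      if (length(in_int)) {
        ev_time <- c(ev_time, pts$time[in_int]); ev_n <- c(ev_n, res$d_k)
      }
      if (length(res$c_times)) {
        cs_time <- c(cs_time, res$c_times); cs_n <- c(cs_n, rep(1L, length(res$c_times)))
      }
      n_cur <- res$n_end; s_cur <- res$s_end
    }
  }

  time <- c(rep(ev_time, ev_n), rep(cs_time, cs_n))
  event <- c(rep(1L, sum(ev_n)), rep(0L, sum(cs_n)))
  ord <- order(time, -event)
  out <- pseudo_ipd(time[ord], event[ord], arm_label = km$arm_label,
                    endpoint = km$endpoint)
  if (nrow(out) != km$n_total) {
    stop(sprintf("internal allocation error: %d records vs %d at risk",
                 nrow(out), km$n_total))
  }
  out
}

.reconstruct_no_risk_table <- function(km) {
  pts <- km$points
  n <- km$n_total
  n_cur <- n; s <- 1
  ev_time <- numeric(0); ev_n <- integer(0)
  for (j in 2:nrow(pts)) {
    drop <- max(0, 1 - pts$survival[j] / s)
    d <- min(round(n_cur * drop), n_cur)
    if (d > 0) {
      s <- s * (n_cur - d) / n_cur
      ev_time <- c(ev_time, pts$time[j]); ev_n <- c(ev_n, d)
      n_cur <- n_cur - d
    }
  }
  time <- c(rep(ev_time, ev_n), rep(max(pts$time), n_cur))
  event <- c(rep(1L, sum(ev_n)), rep(0L, n_cur))
  pseudo_ipd(time, event, arm_label = km$arm_label, endpoint = km$endpoint)
}

#' Read digitized coordinates and risk table from CSV
#'
#' @param points_csv CSV with columns `time`, `survival`
#' @param risk_csv optional CSV with columns `time`, `n_at_risk`
#' @inheritParams digitized_km
#' @return a [digitized_km()]
#' @export
read_digitized_km <- function(points_csv, risk_csv = NULL, arm_label = "arm",
                              endpoint = "OS", n_total = NULL) {
  pts <- utils::read.csv(points_csv)
  rt <- if (!is.null(risk_csv)) utils::read.csv(risk_csv) else NULL
  digitized_km(pts, rt, arm_label = arm_label, endpoint = endpoint,
               n_total = n_total)
}

#' Write pseudo-IPD to CSV
#'
#' @param ipd a [pseudo_ipd()]
#' @param path output CSV path (columns `time`, `event`)
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(as.data.frame(ipd)[, c("time", "event")], path,
                   row.names = FALSE)
  invisible(path)
}
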