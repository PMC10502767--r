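# Individual-level Monte Carlo: cohort generation under piecewise-constant
# competing risks, four control-sampling designs, and the crude and
# Mantel-Haenszel sample odds ratios used to verify convergence to the
# deterministic estimands.

piecewise_cumhaz <- function(t, rates, bounds) {
  # H(t) for piecewise-constant rates; vectorized over t
  k <- length(rates)
  H <- 0
  out <- numeric(length(t))
  for (i in seq_len(k)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    out <- out + rates[i] * pmax(0, pmin(t, hi) - lo)
  }
  out
}

interval_index <- function(t, bounds) {
  pmin(pmax(findInterval(t, bounds), 1L), length(bounds) - 1L)
}

#' Draw event times from a piecewise-exponential distribution
#'
#' Inverse-CDF sampling for a survival time with piecewise-constant hazard
#' `rates` on the intervals of `bounds`, truncated at the end of follow-up
#' T = `max(bounds)`. Each draw may start at its own left-truncation time
#' `t0` (survival to `t0` is conditioned on), which is how post-migration
#' event times are drawn.
#'
#' @param n Number of draws.
#' @param rates Per-interval hazards, per person-week, all >= 0.
#' @param bounds Interval boundaries (as in a scenario).
#' @param t0 Left-truncation time(s), scalar or length n; default 0.
#' @return Numeric vector of length n: event times in (t0, T], or `NA` for
#'   draws surviving past T.
#' @export
rpiecewise_exp <- function(n, rates, bounds, t0 = 0) {
  stopifnot(length(rates) == length(bounds) - 1L, all(rates >= 0))
  if (length(t0) == 1L) t0 <- rep(t0, n)
  Hb <- c(0, cumsum(rates * diff(bounds)))
  target <- piecewise_cumhaz(t0, rates, bounds) + stats::rexp(n)
  # invert: for u in (Hb[i], Hb[i+1]], t = bounds[i] + (u - Hb[i]) / rates[i]
  pos <- findInterval(target, Hb, left.open = TRUE)
  out <- rep(NA_real_, n)
  ok <- pos >= 1L & pos <= length(rates)
  if (any(ok)) {
    i <- pos[ok]
    out[ok] <- bounds[i] + (target[ok] - Hb[i]) / rates[i]
  }
  out
}

#' Simulate individual exposure and event histories for a scenario
#'
#' The stochastic twin of [integrate_trajectory()]: each of `n` individuals
#' starts unexposed with probability equal to the scenario's initial unexposed
#' proportion. While unexposed and event-free, the individual is subject to
#' competing piecewise-exponential risks of the outcome (baseline hazard) and
#' of becoming exposed (new-exposure rate); after the switch the outcome
#' hazard is the baseline times the hazard ratio. Individuals are removed at
#' the outcome event; follow-up ends at T = `max(interval_bounds)`.
#'
#' @param scenario A `piecewise_scenario`.
#' @param n Number of individuals.
#' @param seed Optional integer seed; if given, `set.seed(seed)` is called so
#'   the cohort is reproducible.
#' @return A data frame with one row per individual: `initial_exposure`
#'   (logical), `switch_time` (week of migration, `NA` if initially exposed or
#'   never exposed), `event_time` (week of outcome, `NA` if event-free at T).
#' @export
simulate_cohort <- function(scenario, n, seed = NULL) {
  validate_scenario(scenario)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  bounds <- scenario$interval_bounds
  R0 <- scenario$baseline_hazard
  R1 <- scenario$hazard_ratio * R0
  E <- scenario$exposure_rate

  init_exposed <- stats::runif(n) >= scenario$initial_unexposed_prop
  switch_time <- rep(NA_real_, n)
  event_time <- rep(NA_real_, n)

  ie <- which(init_exposed)
  if (length(ie)) event_time[ie] <- rpiecewise_exp(length(ie), R1, bounds)

  iu <- which(!init_exposed)
  if (length(iu)) {
    # first transition out of the unexposed state: competing risks with total
    # rate R0 + E; classify by the rates active at the transition time
    jump <- rpiecewise_exp(length(iu), R0 + E, bounds)
    moved <- !is.na(jump)
    if (any(moved)) {
      j <- jump[moved]
      idx <- interval_index(j, bounds)
      p_event <- ifelse(R0[idx] + E[idx] > 0, R0[idx] / (R0[idx] + E[idx]), 1)
      is_event <- stats::runif(length(j)) < p_event
      who <- iu[moved]
      event_time[who[is_event]] <- j[is_event]
      sw <- who[!is_event]
      if (length(sw)) {
        s <- j[!is_event]
        switch_time[sw] <- s
        event_time[sw] <- rpiecewise_exp(length(sw), R1, bounds, t0 = s)
      }
    }
  }
  data.frame(initial_exposure = init_exposed,
             switch_time = switch_time,
             event_time = event_time)
}

exposed_at <- function(histories, t) {
  histories$initial_exposure |
    (!is.na(histories$switch_time) & histories$switch_time <= t)
}

#' Draw a case-control sample from simulated histories
#'
#' Four control-sampling designs:
#' \describe{
#'   \item{`risk_set`}{For each case with event at time t, `m` controls drawn
#'     uniformly without replacement from the individuals still event-free at
#'     t (future cases are eligible, and an individual may serve as control
#'     for several cases); control exposure is the status at t; the case and
#'     its controls form a matched set.}
#'   \item{`unmatched_density`}{The same time-matched draws, but the matched
#'     set structure is discarded, as when the analysis pools over time.}
#'   \item{`cumulative`}{Controls drawn without replacement from individuals
#'     event-free at the end of follow-up (the classical exclusive design);
#'     only available for scenarios without migration.}
#'   \item{`case_cohort`}{Controls drawn without replacement from the full
#'     baseline cohort regardless of outcome; only available for scenarios
#'     without migration, where exposure is a fixed attribute.}
#' }
#'
#' @param histories Data frame from [simulate_cohort()].
#' @param design One of `"risk_set"`, `"unmatched_density"`, `"cumulative"`,
#'   `"case_cohort"`.
#' @param m Controls per case (default 1).
#' @param scenario The generating scenario; required for the migration guard
#'   of the `cumulative` and `case_cohort` designs.
#' @return A data frame of class `cc_sample` with one row per sampled subject:
#'   `role` (`"case"`/`"control"`), `exposed` (logical, status at the
#'   subject's sampling time), `time` (sampling time in weeks), `set`
#'   (matched-set id, `NA` for unmatched designs) and `design`.
#' @export
draw_case_control <- function(histories,
                              design = c("risk_set", "unmatched_density",
                                         "cumulative", "case_cohort"),
                              m = 1L,
                              scenario = NULL) {
  design <- match.arg(design)
  stopifnot(m >= 1L)
  evt <- histories$event_time
  cases <- which(!is.na(evt))
  if (!length(cases)) stop("no cases in the cohort: nothing to sample", call. = FALSE)
  n <- nrow(histories)
  Tend <- max(c(evt, histories$switch_time, 0), na.rm = TRUE)
  if (!is.null(scenario)) Tend <- max(scenario$interval_bounds)

  if (design %in% c("cumulative", "case_cohort")) {
    if (is.null(scenario)) {
      stop(sprintf("design '%s' requires the generating scenario", design), call. = FALSE)
    }
    if (any(scenario$exposure_rate > 0)) {
      stop(sprintf(paste0("design '%s' is only supported for scenarios without ",
                          "exposure migration (all exposure_rate = 0), since it ",
                          "treats exposure as a fixed attribute"), design),
           call. = FALSE)
    }
  }

  if (design %in% c("risk_set", "unmatched_density")) {
    ord <- order(evt, na.last = TRUE) # sorted by event time; non-cases last
    sorted_evt_is_case <- !is.na(evt[ord])
    rank_of <- integer(n)
    rank_of[ord] <- seq_len(n)
    r <- rank_of[cases] # risk set of case = ranks r+1 .. n
    avail <- n - r
    if (any(avail < m)) {
      stop(sprintf("risk set too small: a case at time %g has only %d eligible controls (< m = %d)",
                   evt[cases[which.min(avail)]], min(avail), m), call. = FALSE)
    }
    if (m == 1L) {
      pick <- r + 1L + floor(stats::runif(length(r)) * avail)
      pick <- pmin(pick, n)
      ctrl <- matrix(ord[pick], ncol = 1L)
    } else {
      ctrl <- t(vapply(r, function(ri) ord[ri + sample.int(n - ri, m)],
                       integer(m)))
    }
    tcase <- evt[cases]
    case_rows <- data.frame(
      role = "case",
      exposed = exposed_at(histories[cases, , drop = FALSE], tcase),
      time = tcase,
      set = seq_along(cases)
    )
    ctrl_idx <- as.vector(t(ctrl))
    ctrl_t <- rep(tcase, each = m)
    ctrl_rows <- data.frame(
      role = "control",
      exposed = exposed_at(histories[ctrl_idx, , drop = FALSE], ctrl_t),
      time = ctrl_t,
      set = rep(seq_along(cases), each = m)
    )
    out <- rbind(case_rows, ctrl_rows)
    if (design == "unmatched_density") out$set <- NA_integer_
  } else {
    pool <- if (design == "cumulative") which(is.na(evt)) else seq_len(n)
    need <- m * length(cases)
    if (length(pool) < need) {
      stop(sprintf("control pool too small: %d eligible, %d needed", length(pool), need),
           call. = FALSE)
    }
    picked <- pool[sample.int(length(pool), need)]
    tcase <- evt[cases]
    case_rows <- data.frame(
      role = "case",
      exposed = exposed_at(histories[cases, , drop = FALSE], tcase),
      time = tcase,
      set = NA_integer_
    )
    ctrl_rows <- data.frame(
      role = "control",
      exposed = if (design == "case_cohort") {
        histories$initial_exposure[picked]
      } else {
        exposed_at(histories[picked, , drop = FALSE], Tend)
      },
      time = if (design == "case_cohort") 0 else Tend,
      set = NA_integer_
    )
    out <- rbind(case_rows, ctrl_rows)
  }
  out$design <- design
  rownames(out) <- NULL
  class(out) <- c("cc_sample", "data.frame")
  out
}

sample_cells <- function(sample) {
  c(a = sum(sample$role == "case" & sample$exposed),
    b = sum(sample$role == "case" & !sample$exposed),
    e = sum(sample$role == "control" & sample$exposed),
    f = sum(sample$role == "control" & !sample$exposed))
}

#' Crude (pooled) sample odds ratio
#'
#' Pools cases and controls over time:
#' (exposed cases x unexposed controls) / (unexposed cases x exposed controls).
#'
#' @param sample A `cc_sample`.
#' @return The crude OR.
#' @export
crude_or <- function(sample) {
  z <- sample_cells(sample)
  if (any(z == 0)) {
    stop(sprintf("crude OR undefined: zero cell (a=%d, b=%d, exposed controls=%d, unexposed controls=%d)",
                 z[["a"]], z[["b"]], z[["e"]], z[["f"]]), call. = FALSE)
  }
  (z[["a"]] * z[["f"]]) / (z[["b"]] * z[["e"]])
}

#' Mantel-Haenszel odds ratio over matched sets
#'
#' With each matched set k contributing a 2x2 table (a_k exposed cases, b_k
#' unexposed cases, c_k exposed controls, d_k unexposed controls; n_k
#' subjects), the estimator is
#' \deqn{OR_{MH} = \frac{\sum_k a_k d_k / n_k}{\sum_k b_k c_k / n_k}.}
#' For 1:1 matching this reduces to the ratio of case-exposed-only to
#' control-exposed-only discordant pairs.
#'
#' @param sample A `cc_sample` with matched-set ids.
#' @return The Mantel-Haenszel OR.
#' @export
mantel_haenszel_or <- function(sample) {
  if (all(is.na(sample$set))) {
    stop("Mantel-Haenszel OR requires matched sets (set ids are all NA)", call. = FALSE)
  }
  is_case <- sample$role == "case"
  a_k <- rowsum(as.numeric(is_case & sample$exposed), sample$set)
  b_k <- rowsum(as.numeric(is_case & !sample$exposed), sample$set)
  c_k <- rowsum(as.numeric(!is_case & sample$exposed), sample$set)
  d_k <- rowsum(as.numeric(!is_case & !sample$exposed), sample$set)
  n_k <- a_k + b_k + c_k + d_k
  num <- sum(a_k * d_k / n_k)
  den <- sum(b_k * c_k / n_k)
  if (num == 0 || den == 0) {
    n_disc <- sum((a_k + c_k) > 0 & (b_k + d_k) > 0 & (a_k * d_k + b_k * c_k) > 0)
    stop(sprintf("Mantel-Haenszel OR undefined: no discordant sets in one direction (%d informative sets)",
                 n_disc), call. = FALSE)
  }
  num / den
}

#' Monte Carlo convergence report: which design targets which estimand
#'
#' Simulates `replicates` cohorts of size `n`, draws a case-control sample
#' under each requested design, computes the design's sample OR
#' (Mantel-Haenszel for `risk_set`, crude otherwise) and compares the mean log
#' OR across replicates with the deterministic population quantity the design
#' targets: the matched OR estimand for `risk_set`, the unmatched OR estimand
#' for `unmatched_density`, the population odds ratio ad/bc of the expected
#' closed-cohort 2x2 for `cumulative`, and the cohort risk ratio for
#' `case_cohort`.
#'
#' @param scenario A `piecewise_scenario`.
#' @param designs Character vector of design names (see [draw_case_control()]).
#' @param n Cohort size per replicate.
#' @param replicates Number of independent cohorts.
#' @param m Controls per case.
#' @param seed Integer seed; per-replicate seeds are derived from it so the
#'   report is reproducible.
#' @return A data frame with one row per design: `design`, `target` (name of
#'   the population quantity), `target_value`, `mean_log_or`, `se_log_or`
#'   (standard error of the mean across replicates), `mean_or`
#'   (`exp(mean_log_or)`), `z` (gap z-score of mean log OR vs log target) and
#'   `replicates`.
#' @export
convergence_report <- function(scenario,
                               designs = c("risk_set", "unmatched_density"),
                               n = 10000L, replicates = 10L, m = 1L,
                               seed = 1L) {
  validate_scenario(scenario)
  designs <- match.arg(designs, c("risk_set", "unmatched_density",
                                  "cumulative", "case_cohort"),
                       several.ok = TRUE)
  est <- compute_estimands(scenario)
  targets <- lapply(designs, function(d) design_target(d, est, scenario))

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  logs <- matrix(NA_real_, replicates, length(designs),
                 dimnames = list(NULL, designs))
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    h <- simulate_cohort(scenario, n)
    for (j in seq_along(designs)) {
      smp <- draw_case_control(h, designs[j], m = m, scenario = scenario)
      or <- if (designs[j] == "risk_set") mantel_haenszel_or(smp) else crude_or(smp)
      logs[r, j] <- log(or)
    }
  }
  mean_log <- colMeans(logs)
  se_log <- apply(logs, 2, stats::sd) / sqrt(replicates)
  data.frame(
    design = designs,
    target = vapply(targets, `[[`, "", "name"),
    target_value = vapply(targets, `[[`, 0, "value"),
    mean_log_or = unname(mean_log),
    se_log_or = unname(se_log),
    mean_or = unname(exp(mean_log)),
    z = unname((mean_log - log(vapply(targets, `[[`, 0, "value"))) / se_log),
    replicates = replicates
  )
}

design_target <- function(design, est, scenario) {
  switch(design,
    risk_set = list(name = "matched_or", value = est$matched_or),
    unmatched_density = list(name = "unmatched_or", value = est$unmatched_or),
    cumulative = ,
    case_cohort = {
      if (any(scenario$exposure_rate > 0)) {
        stop(sprintf("design '%s' is only supported without exposure migration", design),
             call. = FALSE)
      }
      traj <- est$trajectory
      k <- length(traj$t)
      tab <- two_by_two(a = traj$A1[k], b = traj$A0[k],
                        c = traj$y[k], d = traj$x[k])
      if (design == "cumulative") {
        list(name = "population_or", value = odds_ratio(tab))
      } else {
        list(name = "risk_ratio", value = risk_ratio(tab))
      }
    }
  )
}
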