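# The four target quantities of a scenario: person-time rate ratio, matched
# and unmatched odds-ratio estimands, and final proportion unexposed.

left_sum <- function(v, dt) sum(v[-length(v)] * dt)

#' Person-time outcome-rate ratio over the study period
#'
#' The exposed:unexposed ratio of (expected cases) / (expected person-time at
#' risk) over the whole follow-up:
#' \deqn{RR = \frac{A_1(T) / \int_0^T y\,dt}{A_0(T) / \int_0^T x\,dt},}
#' with all integrals left-Riemann sums on the trajectory grid.
#'
#' @param traj A `cohort_trajectory`.
#' @return The rate ratio (dimensionless).
#' @export
rate_ratio <- function(traj) {
  stopifnot(inherits(traj, "cohort_trajectory"))
  n <- length(traj$t)
  PT0 <- left_sum(traj$x, traj$dt)
  PT1 <- left_sum(traj$y, traj$dt)
  A0 <- traj$A0[n]
  A1 <- traj$A1[n]
  if (PT0 <= 0 || PT1 <= 0) {
    stop("rate ratio undefined: zero person-time in an exposure group", call. = FALSE)
  }
  if (A0 <= 0) stop("rate ratio undefined: no expected cases in the unexposed", call. = FALSE)
  (A1 / PT1) / (A0 / PT0)
}

#' Unmatched odds-ratio estimand
#'
#' The large-sample limit of the crude odds ratio when density-sampled
#' controls are pooled over time without stratification:
#' \deqn{OR_u(T) = \frac{A_1(T) B_0(T)}{A_0(T) B_1(T)},}
#' where \eqn{A_i} and \eqn{B_i} are the cumulative expected case and control
#' counts by exposure group. Equals the constant hazard ratio only when, in
#' addition, the exposure prevalence is constant over follow-up; otherwise the
#' departure is towards the null.
#'
#' @param traj A `cohort_trajectory`.
#' @return The unmatched OR estimand (dimensionless).
#' @export
unmatched_or <- function(traj) {
  stopifnot(inherits(traj, "cohort_trajectory"))
  n <- length(traj$t)
  A0 <- traj$A0[n]; A1 <- traj$A1[n]; B0 <- traj$B0[n]; B1 <- traj$B1[n]
  if (min(A0, A1, B0, B1) <= 0) {
    stop("unmatched OR undefined: a cumulative case or control count is 0", call. = FALSE)
  }
  (A1 * B0) / (A0 * B1)
}

#' Time-matched odds-ratio estimand
#'
#' The large-sample limit of the matched (risk-set-sampled, 1:1) odds ratio.
#' With case intensity \eqn{a_i(t)} and control-exposure probability
#' \eqn{P_j(t)}, the expected density of matched pairs with the case in group
#' i and the control in group j is \eqn{m_{ij}(t) = a_i(t) P_j(t)}; the
#' estimand is the ratio of expected exposure-discordant pairs
#' \deqn{OR_m = M_{10} / M_{01}, \qquad M_{ij} = \int_0^T a_i(t) P_j(t)\,dt}
#' (left-Riemann sums on the grid). When the hazard ratio is constant over
#' follow-up this equals that hazard ratio identically, whatever the baseline
#' hazard, migration pattern or initial prevalence; for a time-varying hazard
#' ratio it is a weighted mean of the interval hazard ratios.
#'
#' @param traj A `cohort_trajectory`.
#' @return The matched OR estimand (dimensionless).
#' @export
matched_or <- function(traj) {
  m <- matched_pair_mass(traj)
  if (m[["M10"]] <= 0 || m[["M01"]] <= 0) {
    stop("matched OR undefined: an expected discordant-pair mass is 0", call. = FALSE)
  }
  m[["M10"]] / m[["M01"]]
}

matched_pair_mass <- function(traj) {
  stopifnot(inherits(traj, "cohort_trajectory"))
  c(M10 = left_sum(traj$a1 * traj$P0, traj$dt),
    M01 = left_sum(traj$a0 * traj$P1, traj$dt))
}

#' Compute all estimands of a scenario
#'
#' Integrates the trajectory once and derives the person-time rate ratio, the
#' matched and unmatched odds-ratio estimands, the final proportion unexposed,
#' and the underlying person-time, expected case counts and expected
#' discordant-pair masses.
#'
#' @param scenario A `piecewise_scenario`.
#' @return An object of class `estimand_set`: a list with elements
#'   `rate_ratio`, `matched_or`, `unmatched_or`, `final_prop_unexposed`,
#'   `person_time` (named `PT0`, `PT1`, person-weeks), `expected_cases`
#'   (named `A0`, `A1`), `matched_pair_mass` (named `M10`, `M01`) and the
#'   `trajectory`.
#' @examples
#' s <- table2_presets()[[2]]
#' compute_estimands(s)
#' @export
compute_estimands <- function(scenario) {
  traj <- integrate_trajectory(scenario)
  n <- length(traj$t)
  structure(
    list(
      rate_ratio = rate_ratio(traj),
      matched_or = matched_or(traj),
      unmatched_or = unmatched_or(traj),
      final_prop_unexposed = final_proportion_unexposed(traj),
      person_time = c(PT0 = left_sum(traj$x, traj$dt),
                      PT1 = left_sum(traj$y, traj$dt)),
      expected_cases = c(A0 = traj$A0[n], A1 = traj$A1[n]),
      expected_controls = c(B0 = traj$B0[n], B1 = traj$B1[n]),
      matched_pair_mass = matched_pair_mass(traj),
      trajectory = traj
    ),
    class = "estimand_set"
  )
}

#' @export
print.estimand_set <- function(x, ...) {
  cat("Case-control estimands (closed cohort, density sampling)\n")
  cat(sprintf("  person-time rate ratio:   %.4f\n", x$rate_ratio))
  cat(sprintf("  matched OR estimand:      %.4f\n", x$matched_or))
  cat(sprintf("  unmatched OR estimand:    %.4f\n", x$unmatched_or))
  cat(sprintf("  final prop. unexposed:    %.4f\n", x$final_prop_unexposed))
  cat(sprintf("  expected cases A0 = %.4g, A1 = %.4g; person-time PT0 = %.4g, PT1 = %.4g\n",
              x$expected_cases[["A0"]], x$expected_cases[["A1"]],
              x$person_time[["PT0"]], x$person_time[["PT1"]]))
  invisible(x)
}

#' @export
as.data.frame.estimand_set <- function(x, ...) {
  data.frame(
    rate_ratio = x$rate_ratio,
    matched_or = x$matched_or,
    unmatched_or = x$unmatched_or,
    final_prop_unexposed = x$final_prop_unexposed,
    PT0 = x$person_time[["PT0"]], PT1 = x$person_time[["PT1"]],
    A0 = x$expected_cases[["A0"]], A1 = x$expected_cases[["A1"]]
  )
}
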