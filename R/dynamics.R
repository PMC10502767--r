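# Deterministic integration of the two-compartment cohort dynamics.

#' Advance the population state by one explicit Euler subinterval
#'
#' One step of the discretized two-compartment dynamics: the unexposed mass x
#' loses outcome events at hazard `R0` and migrants at rate `E`; the exposed
#' mass y loses events at hazard `R1` and gains exactly the migrants that left
#' x. The update is
#' \deqn{x' = x (1 - R_0 \Delta t - E \Delta t), \quad
#'       y' = y (1 - R_1 \Delta t) + E \Delta t \, x,}
#' so migration conserves mass: the total x + y decreases only through events.
#'
#' @param unexposed_mass,exposed_mass Current compartment masses (persons).
#' @param R0,R1 Outcome hazards in the unexposed and exposed, per person-week.
#' @param E New-exposure (migration) rate, per person-week.
#' @param dt Subinterval length in weeks. The explicit update requires
#'   `(R0 + E) * dt < 1` and `R1 * dt < 1`.
#' @return Numeric vector `c(unexposed, exposed)` after the step.
#' @export
step_population <- function(unexposed_mass, exposed_mass, R0, R1, E, dt) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (R0 < 0 || R1 < 0 || E < 0) stop("rates must be >= 0", call. = FALSE)
  if ((R0 + E) * dt >= 1) {
    stop(sprintf("unstable update: (R0 + E) * dt = %g >= 1; reduce dt",
                 (R0 + E) * dt), call. = FALSE)
  }
  if (R1 * dt >= 1) {
    stop(sprintf("unstable update: R1 * dt = %g >= 1; reduce dt", R1 * dt),
         call. = FALSE)
  }
  c(unexposed_mass * (1 - R0 * dt - E * dt),
    exposed_mass * (1 - R1 * dt) + E * dt * unexposed_mass)
}

#' Integrate the cohort trajectory of a scenario
#'
#' Runs the explicit update of [step_population()] over a grid that subdivides
#' each interval into subintervals of length (approximately) one over
#' `steps_per_week`, with every interval boundary a grid point. At each grid
#' time the case intensities are \eqn{a_i(t) = N(t) P_i(t) R_i(t)} and the
#' density-sampled control intensities \eqn{b_i(t) = a_+(t) P_i(t)}, where
#' \eqn{a_+ = a_0 + a_1} and \eqn{P_i} is the current exposure-group
#' proportion. Cumulative expected case and control counts \eqn{A_i(t)},
#' \eqn{B_i(t)} are left-Riemann sums of the intensities.
#'
#' @param scenario A `piecewise_scenario`.
#' @return An object of class `cohort_trajectory`: a list with the grid `t`
#'   (weeks), subinterval widths `dt` (length one less than the grid), masses
#'   `x` (unexposed) and `y` (exposed), intensities `a0`, `a1`, `b0`, `b1`,
#'   and cumulative counts `A0`, `A1`, `B0`, `B1` (all aligned with `t`,
#'   cumulative counts 0 at t = 0).
#' @export
integrate_trajectory <- function(scenario) {
  validate_scenario(scenario)
  b <- scenario$interval_bounds
  k <- length(b) - 1L
  spw <- scenario$steps_per_week

  t <- 0
  x <- scenario$initial_size * scenario$initial_unexposed_prop
  y <- scenario$initial_size * (1 - scenario$initial_unexposed_prop)
  tt <- xx <- yy <- vector("list", k)
  dts <- vector("list", k)

  for (iv in seq_len(k)) {
    len <- b[iv + 1L] - b[iv]
    n <- max(1L, as.integer(ceiling(len * spw - 1e-9)))
    dt <- len / n
    R0 <- scenario$baseline_hazard[iv]
    R1 <- scenario$hazard_ratio[iv] * R0
    E <- scenario$exposure_rate[iv]
    if ((R0 + E) * dt >= 1 || R1 * dt >= 1) {
      stop(sprintf(
        "interval %d: rate * dt >= 1 ((R0+E)dt = %g, R1 dt = %g); increase steps_per_week",
        iv, (R0 + E) * dt, R1 * dt), call. = FALSE)
    }
    # Euler iterates in closed form: x is geometric, y a linear recurrence
    # y_{j+1} = alpha y_j + beta x_j with x_j = x0 gamma^j.
    gamma <- 1 - (R0 + E) * dt
    alpha <- 1 - R1 * dt
    beta <- E * dt
    j <- seq_len(n)
    xj <- x * gamma^j
    if (beta == 0) {
      yj <- y * alpha^j
    } else if (abs(alpha - gamma) > 1e-12) {
      yj <- y * alpha^j + beta * x * (alpha^j - gamma^j) / (alpha - gamma)
    } else {
      yj <- y * alpha^j + beta * x * j * alpha^(j - 1)
    }
    tt[[iv]] <- b[iv] + dt * j
    xx[[iv]] <- xj
    yy[[iv]] <- yj
    dts[[iv]] <- rep(dt, n)
    x <- xj[n]
    y <- yj[n]
  }

  t <- c(0, unlist(tt))
  x <- c(scenario$initial_size * scenario$initial_unexposed_prop, unlist(xx))
  y <- c(scenario$initial_size * (1 - scenario$initial_unexposed_prop), unlist(yy))
  dt <- unlist(dts)
  # exact boundaries at interval ends (cumulative dt accrues float error)
  t[cumsum(c(1L, vapply(dts, length, 1L)))] <- b

  iv_of <- rep(seq_len(k), vapply(dts, length, 1L))
  iv_at <- c(iv_of, k) # rates at the last grid point: final interval's
  R0t <- scenario$baseline_hazard[iv_at]
  R1t <- (scenario$hazard_ratio * scenario$baseline_hazard)[iv_at]

  tot <- x + y
  P0 <- ifelse(tot > 0, x / tot, 0)
  P1 <- ifelse(tot > 0, y / tot, 0)
  a0 <- x * R0t
  a1 <- y * R1t
  ap <- a0 + a1
  b0 <- ap * P0
  b1 <- ap * P1

  lsum <- function(v) c(0, cumsum(v[-length(v)] * dt))
  structure(
    list(
      t = t, dt = dt, x = x, y = y, P0 = P0, P1 = P1,
      a0 = a0, a1 = a1, b0 = b0, b1 = b1,
      A0 = lsum(a0), A1 = lsum(a1), B0 = lsum(b0), B1 = lsum(b1),
      scenario = scenario
    ),
    class = "cohort_trajectory"
  )
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("Cohort trajectory: %d grid points on [0, %g] weeks\n", n, x$t[n]))
  cat(sprintf("  final masses x = %.6g, y = %.6g (total %.6g of %.6g initial)\n",
              x$x[n], x$y[n], x$x[n] + x$y[n], x$x[1] + x$y[1]))
  cat(sprintf("  expected cases A0 = %.6g, A1 = %.6g; controls B0 = %.6g, B1 = %.6g\n",
              x$A0[n], x$A1[n], x$B0[n], x$B1[n]))
  invisible(x)
}

#' @export
as.data.frame.cohort_trajectory <- function(x, ...) {
  data.frame(t = x$t, x = x$x, y = x$y,
             a0 = x$a0, a1 = x$a1, b0 = x$b0, b1 = x$b1,
             A0 = x$A0, A1 = x$A1, B0 = x$B0, B1 = x$B1)
}

#' Write a trajectory to CSV
#'
#' @param traj A `cohort_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Final proportion of the surviving cohort that is unexposed
#'
#' @param traj A `cohort_trajectory`.
#' @return x(T) / (x(T) + y(T)) at the last grid point.
#' @export
final_proportion_unexposed <- function(traj) {
  stopifnot(inherits(traj, "cohort_trajectory"))
  n <- length(traj$t)
  tot <- traj$x[n] + traj$y[n]
  if (tot <= 0) stop("cohort extinct at end of follow-up: total mass is 0", call. = FALSE)
  traj$x[n] / tot
}
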