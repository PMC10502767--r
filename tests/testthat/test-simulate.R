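test_that("piecewise-exponential draws match the closed-form distribution", {
  bounds <- c(0, 1, 2, 3)
  set.seed(21)
  # zero rates: always censored
  expect_true(all(is.na(rpiecewise_exp(100, c(0, 0, 0), bounds))))
  # constant rate: empirical median near log(2)/r
  r <- 1.2
  d <- rpiecewise_exp(1e5, rep(r, 3), bounds)
  # censored draws count as > T, so the overall median is the exponential one
  expect_equal(median(ifelse(is.na(d), Inf, d)), log(2) / r, tolerance = 0.02)
  # piecewise rates: Kolmogorov distance to the analytic CDF
  rates <- c(0.3, 1.5, 0.2)
  d <- rpiecewise_exp(1e5, rates, bounds)
  obs <- d[!is.na(d)]
  grid <- seq(0.01, 2.99, by = 0.01)
  emp <- ecdf(obs)(grid) * mean(!is.na(d))
  theo <- pexp_piecewise_cdf(grid, rates, bounds)
  expect_lt(max(abs(emp - theo)), 0.01)
  # left truncation: draws start strictly after t0
  d <- rpiecewise_exp(1000, rates, bounds, t0 = 1.5)
  expect_true(all(is.na(d) | d > 1.5))
})

test_that("simulated cohorts track the deterministic trajectory", {
  s <- table2_presets()[[2]]
  h <- simulate_cohort(s, n = 1e5, seed = 5)
  traj <- integrate_trajectory(s)
  k <- length(traj$t)
  # final proportion unexposed among survivors
  surv <- is.na(h$event_time)
  p_hat <- mean(!exposed_at_t(h, 3)[surv])
  p_det <- final_proportion_unexposed(traj)
  se <- sqrt(p_det * (1 - p_det) / sum(surv))
  expect_lt(abs(p_hat - p_det), 3 * se)
  # case counts by exposure status at event
  exp_at_event <- exposed_at_t(h, h$event_time)[!surv]
  n_cases_exposed <- sum(exp_at_event)
  expect_lt(abs(n_cases_exposed - 1e5 * traj$A1[k]),
            3 * sqrt(1e5 * traj$A1[k]))
  expect_lt(abs(sum(!surv) - 1e5 * (traj$A0[k] + traj$A1[k])),
            3 * sqrt(1e5 * (traj$A0[k] + traj$A1[k])))
  # group masses at an interior time
  mid <- which.min(abs(traj$t - 1.5))
  alive <- is.na(h$event_time) | h$event_time > 1.5
  x_hat <- mean(alive & !exposed_at_t(h, 1.5))
  expect_equal(x_hat, traj$x[mid], tolerance = 0.02)
})

test_that("exposure is outcome-independent when the hazard ratio is 1", {
  s <- piecewise_scenario(baseline_hazard = 0.05, hazard_ratio = 1,
                          exposure_rate = 0, initial_unexposed_prop = 0.6)
  h <- simulate_cohort(s, n = 4e4, seed = 17)
  tab <- table(h$initial_exposure, is.na(h$event_time))
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("risk-set samples have the matched structure and track prevalence", {
  s <- table2_presets()[[2]]
  h <- simulate_cohort(s, n = 3e4, seed = 9)
  smp <- draw_case_control(h, "risk_set", m = 2, scenario = s)
  sizes <- table(smp$set, smp$role)
  expect_true(all(sizes[, "case"] == 1))
  expect_true(all(sizes[, "control"] == 2))
  # each control's sampling time is its case's event time
  ctl <- smp[smp$role == "control", ]
  cas <- smp[smp$role == "case", ]
  expect_equal(ctl$time, cas$time[match(ctl$set, cas$set)])
  # control exposure prevalence tracks P1(t) of the deterministic trajectory
  traj <- integrate_trajectory(s)
  p1_at <- approx(traj$t, traj$P1, xout = ctl$time)$y
  expect_lt(abs(mean(ctl$exposed) - mean(p1_at)),
            3 * sqrt(mean(p1_at) * (1 - mean(p1_at)) / nrow(ctl)))
})

test_that("designs with fixed-exposure frames refuse migrating scenarios", {
  s <- table2_presets()[[2]] # has migration
  h <- simulate_cohort(s, n = 2000, seed = 2)
  expect_error(draw_case_control(h, "case_cohort", scenario = s), "migration")
  expect_error(draw_case_control(h, "cumulative", scenario = s), "migration")
  zero <- piecewise_scenario(baseline_hazard = 0.05, hazard_ratio = 2,
                             exposure_rate = 0, initial_unexposed_prop = 0.7)
  hz <- simulate_cohort(zero, n = 5000, seed = 2)
  expect_s3_class(draw_case_control(hz, "case_cohort", scenario = zero), "cc_sample")
  expect_s3_class(draw_case_control(hz, "cumulative", scenario = zero), "cc_sample")
})

test_that("crude and Mantel-Haenszel ORs have the documented closed forms", {
  mk <- function(case_exposed, ctrl_exposed) {
    k <- length(case_exposed)
    structure(data.frame(
      role = rep(c("case", "control"), each = k),
      exposed = c(case_exposed, ctrl_exposed),
      time = rep(seq_len(k), 2),
      set = rep(seq_len(k), 2),
      design = "risk_set"
    ), class = c("cc_sample", "data.frame"))
  }
  # 10 case-exposed-only pairs, 5 control-exposed-only, plus concordant ones
  smp <- mk(c(rep(TRUE, 12), rep(FALSE, 8)),
            c(rep(FALSE, 10), rep(TRUE, 2), rep(TRUE, 5), rep(FALSE, 3)))
  expect_equal(mantel_haenszel_or(smp), 2)
  # agrees with the standard stratified estimator
  arr <- xtabs(~ factor(exposed, c(TRUE, FALSE)) + factor(role) + set, data = smp)
  mh <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(mantel_haenszel_or(smp), unname(mh$estimate))
  # crude OR pools cells and ignores set labels
  expect_equal(crude_or(smp), (12 * 13) / (8 * 7))
  smp2 <- smp
  smp2$set <- rev(smp2$set)
  expect_equal(crude_or(smp2), crude_or(smp))
  # all-concordant matched sample is an error
  conc <- mk(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_error(mantel_haenszel_or(conc), "discordant")
  expect_error(crude_or(mk(c(TRUE, TRUE), c(TRUE, TRUE))), "zero cell")
})

test_that("simulation and sampling are reproducible from the seed", {
  s <- table2_presets()[[2]]
  h1 <- simulate_cohort(s, n = 3000, seed = 123)
  h2 <- simulate_cohort(s, n = 3000, seed = 123)
  expect_identical(h1, h2)
  set.seed(77)
  s1 <- draw_case_control(h1, "risk_set", scenario = s)
  set.seed(77)
  s2 <- draw_case_control(h2, "risk_set", scenario = s)
  expect_identical(s1, s2)
  r1 <- convergence_report(s, "unmatched_density", n = 3000, replicates = 2, seed = 4)
  r2 <- convergence_report(s, "unmatched_density", n = 3000, replicates = 2, seed = 4)
  expect_identical(r1, r2)
})

test_that("cumulative and case-cohort sample ORs target the closed-cohort quantities", {
  zero <- piecewise_scenario(baseline_hazard = 0.06, hazard_ratio = 2.5,
                             exposure_rate = 0, initial_unexposed_prop = 0.7)
  rep <- convergence_report(zero, c("cumulative", "case_cohort"),
                            n = 5e4, replicates = 8, seed = 31)
  expect_equal(rep$target, c("population_or", "risk_ratio"))
  expect_true(all(abs(rep$z) < 3.5))
  # the two targets genuinely differ for this non-rare outcome
  expect_gt(abs(diff(log(rep$target_value))), 0.02)
})
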