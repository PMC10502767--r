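test_that("scenario construction validates its invariants", {
  s <- piecewise_scenario(baseline_hazard = 0.025, hazard_ratio = 0.4,
                          exposure_rate = 0, initial_unexposed_prop = 0.8)
  expect_s3_class(s, "piecewise_scenario")
  expect_equal(s$hazard_ratio, rep(0.4, 3))
  expect_equal(s$steps_per_week, 1000L)
  expect_equal(s$initial_size, 1)

  expect_error(piecewise_scenario(interval_bounds = c(1, 2, 3),
                                  baseline_hazard = 0.025, hazard_ratio = 1,
                                  exposure_rate = 0, initial_unexposed_prop = 0.8),
               "first boundary")
  expect_error(piecewise_scenario(interval_bounds = c(0, 2, 1),
                                  baseline_hazard = 0.025, hazard_ratio = 1,
                                  exposure_rate = 0, initial_unexposed_prop = 0.8),
               "strictly increasing")
  expect_error(piecewise_scenario(baseline_hazard = 0.025, hazard_ratio = 1,
                                  exposure_rate = -0.1, initial_unexposed_prop = 0.8),
               "exposure_rate")
  expect_error(piecewise_scenario(baseline_hazard = 0.025, hazard_ratio = c(1, 0, 1),
                                  exposure_rate = 0, initial_unexposed_prop = 0.8),
               "hazard_ratio")
  expect_error(piecewise_scenario(baseline_hazard = 0.025, hazard_ratio = c(1, 1),
                                  exposure_rate = 0, initial_unexposed_prop = 0.8),
               "length 3")
  expect_error(piecewise_scenario(baseline_hazard = 0.025, hazard_ratio = 1,
                                  exposure_rate = 0, initial_unexposed_prop = 1.2),
               "initial_unexposed_prop")
})

test_that("JSON and YAML scenario files round-trip field by field", {
  s <- piecewise_scenario(interval_bounds = c(0, 0.5, 2, 3),
                          baseline_hazard = c(0.01, 0.02, 0.03),
                          hazard_ratio = c(0.5, 1.5, 2),
                          exposure_rate = c(0, 0.1, 0.2),
                          initial_size = 500,
                          initial_unexposed_prop = 0.75,
                          steps_per_week = 200L)
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_scenario(s, path)
    s2 <- load_scenario(path)
    expect_equal(unclass(s2), unclass(s), tolerance = 1e-12)
  }
})

test_that("optional fields take documented defaults and schema errors are named", {
  s <- load_scenario('{"baseline_hazard": [0.025, 0.025, 0.025],
                       "hazard_ratio": [0.4, 0.4, 0.4],
                       "exposure_rate": [0, 0, 0],
                       "initial_unexposed_prop": 0.8}')
  expect_equal(s$steps_per_week, 1000L)
  expect_equal(s$initial_size, 1)
  expect_equal(s$interval_bounds, c(0, 1, 2, 3))
  # equals the first built-in preset
  expect_equal(unclass(s), unclass(table2_presets()[[1]]))

  expect_error(load_scenario('{"hazard_ratio": [1], "exposure_rate": [0],
                               "initial_unexposed_prop": 0.8}'),
               "baseline_hazard")
  expect_error(load_scenario('{"baseline_hazard": [0.02], "hazard_ratio": [1],
                               "exposure_rate": [-1], "initial_unexposed_prop": 0.8}'),
               "exposure_rate")
  expect_error(load_scenario('{"baseline_hazard": [0.02], "hazard_ratio": [1],
                               "exposure_rate": [0], "initial_unexposed_prop": 0.8,
                               "bogus": 1}'),
               "unknown scenario field")
})

test_that("the 12 built-in presets have the documented rate patterns and validate", {
  ps <- table2_presets()
  expect_length(ps, 12)
  for (s in ps) expect_s3_class(validate_scenario(s), "piecewise_scenario")
  expect_equal(ps[[2]]$hazard_ratio, c(0.4, 0.4, 0.4))
  expect_equal(ps[[2]]$exposure_rate, c(0.1, 0.5, 0.1))
  expect_equal(ps[[12]]$hazard_ratio, c(1.25, 2.5, 5.0))
  expect_equal(ps[[12]]$exposure_rate, c(0.1, 0.1, 0.1))
  for (s in ps) expect_equal(s$interval_bounds, c(0, 1, 2, 3))
})

test_that("packaged preset files equal the in-code constructors", {
  ps <- table2_presets()
  for (i in c(1, 2, 5, 12)) {
    from_file <- load_scenario(preset_path(i))
    expect_equal(unclass(from_file), unclass(ps[[i]]), tolerance = 1e-12)
  }
})
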