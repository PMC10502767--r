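# Scenario definition, validation, IO and built-in presets.

#' Define a piecewise-constant cohort scenario
#'
#' A closed cohort is followed over a study period divided into intervals on
#' which all rates are constant. Within each interval the unexposed experience
#' the outcome at the baseline hazard, the exposed at the baseline hazard times
#' the interval's hazard ratio, and unexposed individuals migrate one-way into
#' the exposed group at the new-exposure rate. Individuals are removed from
#' risk when the outcome occurs; there is no other entry or exit.
#'
#' @param interval_bounds Strictly increasing interval boundaries in weeks,
#'   starting at 0. Default `c(0, 1, 2, 3)`: three one-week intervals.
#' @param baseline_hazard Per-interval outcome hazard in the unexposed, events
#'   per person-week. A scalar is recycled across intervals.
#' @param hazard_ratio Per-interval exposed:unexposed hazard ratio, so the
#'   exposed hazard is `hazard_ratio * baseline_hazard`. Scalar recycled.
#' @param exposure_rate Per-interval rate at which unexposed individuals become
#'   exposed, per person-week. Scalar recycled.
#' @param initial_size Initial cohort size N(0). Defaults to 1, in which case
#'   all masses are proportions of the initial cohort.
#' @param initial_unexposed_prop Initial proportion unexposed, in \[0, 1\].
#' @param steps_per_week Discretization resolution of the explicit integrator,
#'   subintervals per week (default 1000).
#'
#' @return An object of class `piecewise_scenario`.
#' @seealso [integrate_trajectory()], [compute_estimands()], [table2_presets()]
#' @examples
#' piecewise_scenario(
#'   baseline_hazard = 0.025, hazard_ratio = c(0.4, 0.4, 0.4),
#'   exposure_rate = c(0.1, 0.5, 0.1), initial_unexposed_prop = 0.8
#' )
#' @export
piecewise_scenario <- function(interval_bounds = c(0, 1, 2, 3),
                               baseline_hazard,
                               hazard_ratio,
                               exposure_rate,
                               initial_size = 1,
                               initial_unexposed_prop,
                               steps_per_week = 1000L) {
  k <- length(interval_bounds) - 1L
  recycle <- function(v, name) {
    if (length(v) == 1L) v <- rep(as.numeric(v), k)
    if (length(v) != k) {
      stop(sprintf("'%s' must have length %d (one value per interval), got %d",
                   name, k, length(v)), call. = FALSE)
    }
    as.numeric(v)
  }
  s <- structure(
    list(
      interval_bounds = as.numeric(interval_bounds),
      baseline_hazard = recycle(baseline_hazard, "baseline_hazard"),
      hazard_ratio = recycle(hazard_ratio, "hazard_ratio"),
      exposure_rate = recycle(exposure_rate, "exposure_rate"),
      initial_size = as.numeric(initial_size),
      initial_unexposed_prop = as.numeric(initial_unexposed_prop),
      steps_per_week = as.integer(steps_per_week)
    ),
    class = "piecewise_scenario"
  )
  validate_scenario(s)
}

#' Validate a piecewise_scenario
#'
#' Checks all structural invariants: strictly increasing bounds starting at 0,
#' non-negative hazards and exposure rates, strictly positive hazard ratios,
#' per-interval vectors of matching length, an initial proportion in \[0, 1\],
#' positive initial size and a positive integer resolution.
#'
#' @param s A `piecewise_scenario`.
#' @return `s`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_scenario <- function(s) {
  if (!inherits(s, "piecewise_scenario")) {
    stop("not a 'piecewise_scenario' object", call. = FALSE)
  }
  b <- s$interval_bounds
  if (length(b) < 2L || anyNA(b)) {
    stop("interval_bounds: need at least two non-missing boundaries", call. = FALSE)
  }
  if (b[1L] != 0) stop("interval_bounds: first boundary must be 0", call. = FALSE)
  if (any(diff(b) <= 0)) {
    stop("interval_bounds: boundaries must be strictly increasing", call. = FALSE)
  }
  k <- length(b) - 1L
  for (f in c("baseline_hazard", "hazard_ratio", "exposure_rate")) {
    v <- s[[f]]
    if (length(v) != k || anyNA(v)) {
      stop(sprintf("%s: must be a vector of %d non-missing values", f, k),
           call. = FALSE)
    }
  }
  if (any(s$baseline_hazard < 0)) {
    stop("baseline_hazard: values must be >= 0", call. = FALSE)
  }
  if (any(s$hazard_ratio <= 0)) {
    stop("hazard_ratio: values must be > 0", call. = FALSE)
  }
  if (any(s$exposure_rate < 0)) {
    stop("exposure_rate: values must be >= 0", call. = FALSE)
  }
  if (length(s$initial_size) != 1L || is.na(s$initial_size) || s$initial_size <= 0) {
    stop("initial_size: must be a single value > 0", call. = FALSE)
  }
  p0 <- s$initial_unexposed_prop
  if (length(p0) != 1L || is.na(p0) || p0 < 0 || p0 > 1) {
    stop("initial_unexposed_prop: must be a single value in [0, 1]", call. = FALSE)
  }
  spw <- s$steps_per_week
  if (length(spw) != 1L || is.na(spw) || spw < 1L) {
    stop("steps_per_week: must be a positive integer", call. = FALSE)
  }
  invisible(s)
}

#' @export
print.piecewise_scenario <- function(x, ...) {
  k <- length(x$interval_bounds) - 1L
  cat("Piecewise-constant cohort scenario\n")
  cat(sprintf("  %d interval(s) on [0, %g] weeks; bounds: %s\n",
              k, max(x$interval_bounds),
              paste(x$interval_bounds, collapse = ", ")))
  cat(sprintf("  baseline hazard (/pw): %s\n",
              paste(format(x$baseline_hazard), collapse = ", ")))
  cat(sprintf("  hazard ratio:          %s\n",
              paste(format(x$hazard_ratio), collapse = ", ")))
  cat(sprintf("  new-exposure rate:     %s\n",
              paste(format(x$exposure_rate), collapse = ", ")))
  cat(sprintf("  N(0) = %g, initially unexposed = %g, %d steps/week\n",
              x$initial_size, x$initial_unexposed_prop, x$steps_per_week))
  invisible(x)
}

scenario_fields <- c("interval_bounds", "baseline_hazard", "hazard_ratio",
                     "exposure_rate", "initial_size", "initial_unexposed_prop",
                     "steps_per_week")

#' Read a scenario from a JSON or YAML file or string
#'
#' The schema uses exactly the field names of [piecewise_scenario()].
#' `interval_bounds` (default `[0,1,2,3]`), `initial_size` (default 1) and
#' `steps_per_week` (default 1000) are optional; `baseline_hazard`,
#' `hazard_ratio`, `exposure_rate` and `initial_unexposed_prop` are required.
#'
#' @param source A file path ending in `.json`, `.yaml` or `.yml`, or a
#'   character string containing JSON or YAML.
#' @return A validated `piecewise_scenario`.
#' @export
load_scenario <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (file.exists(source)) {
    ext <- tolower(tools::file_ext(source))
    raw <- if (ext == "json") {
      jsonlite::fromJSON(source, simplifyVector = TRUE)
    } else if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(source)
    } else {
      stop("scenario file must have extension .json, .yaml or .yml", call. = FALSE)
    }
  } else if (grepl("^\\s*\\{", source)) {
    raw <- jsonlite::fromJSON(source, simplifyVector = TRUE)
  } else if (grepl("\n|:", source)) {
    raw <- yaml::yaml.load(source)
  } else {
    stop(sprintf("scenario source '%s' is neither an existing file nor inline JSON/YAML",
                 source), call. = FALSE)
  }
  scenario_from_list(raw)
}

scenario_from_list <- function(raw) {
  if (!is.list(raw)) stop("scenario source must parse to a mapping of fields", call. = FALSE)
  unknown <- setdiff(names(raw), scenario_fields)
  if (length(unknown)) {
    stop(sprintf("unknown scenario field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  required <- c("baseline_hazard", "hazard_ratio", "exposure_rate",
                "initial_unexposed_prop")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(sprintf("missing required scenario field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  piecewise_scenario(
    interval_bounds = raw$interval_bounds %||% c(0, 1, 2, 3),
    baseline_hazard = raw$baseline_hazard,
    hazard_ratio = raw$hazard_ratio,
    exposure_rate = raw$exposure_rate,
    initial_size = raw$initial_size %||% 1,
    initial_unexposed_prop = raw$initial_unexposed_prop,
    steps_per_week = raw$steps_per_week %||% 1000L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario to a JSON or YAML file
#'
#' @param s A `piecewise_scenario`.
#' @param path Output path; the format is taken from the extension unless
#'   `format` is given.
#' @param format `"json"` or `"yaml"`; default inferred from `path`.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(s, path, format = NULL) {
  validate_scenario(s)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("yaml", "yml")) "yaml" else "json"
  }
  format <- match.arg(format, c("json", "yaml"))
  x <- unclass(s)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

# Hazard-ratio and new-exposure-rate vectors of the 12 built-in example
# scenarios, in presentation order: four HR patterns (protective constant,
# harmful constant, decreasing, increasing) crossed with three migration
# patterns (none, pulsed, steady).
table2_grid <- function() {
  hr <- list(c(0.4, 0.4, 0.4), c(2.5, 2.5, 2.5),
             c(0.8, 0.4, 0.2), c(1.25, 2.5, 5.0))
  ex <- list(c(0, 0, 0), c(0.1, 0.5, 0.1), c(0.1, 0.1, 0.1))
  out <- vector("list", 12L)
  for (i in 1:4) for (j in 1:3) out[[(i - 1L) * 3L + j]] <- list(hr = hr[[i]], ex = ex[[j]])
  out
}

#' Built-in example scenarios: four hazard-ratio patterns crossed with three
#' exposure-migration patterns
#'
#' Twelve scenarios over three one-week intervals spanning constant protective
#' (HR 0.4), constant harmful (HR 2.5), decreasing (0.8, 0.4, 0.2) and
#' increasing (1.25, 2.5, 5.0) hazard ratios, each under no migration, a pulse
#' of migration in week 2 (rates 0.1, 0.5, 0.1 per person-week) and steady
#' migration (0.1 throughout). These are the scenarios for which the package's
#' reference table of estimands is computed; see [table2_report()].
#'
#' The baseline hazard and initial exposure prevalence are free parameters of
#' the examples (the estimand contrasts they illustrate do not depend on them
#' in the constant-HR rows); the defaults are a baseline hazard of 0.025
#' events per person-week and 80% initially unexposed.
#'
#' @param baseline_hazard_value Scalar baseline hazard, events per person-week.
#' @param initial_unexposed_prop Initial proportion unexposed.
#' @param steps_per_week Integrator resolution passed to each scenario.
#' @return A list of 12 `piecewise_scenario` objects.
#' @export
table2_presets <- function(baseline_hazard_value = 0.025,
                           initial_unexposed_prop = 0.8,
                           steps_per_week = 1000L) {
  lapply(table2_grid(), function(g) {
    piecewise_scenario(
      interval_bounds = c(0, 1, 2, 3),
      baseline_hazard = baseline_hazard_value,
      hazard_ratio = g$hr,
      exposure_rate = g$ex,
      initial_unexposed_prop = initial_unexposed_prop,
      steps_per_week = steps_per_week
    )
  })
}

#' Path of a packaged preset scenario file
#'
#' The 12 presets of [table2_presets()] also ship as JSON scenario files under
#' `inst/extdata/presets/`, one per row, usable with [load_scenario()] and the
#' command-line interface.
#'
#' @param row Preset row number, 1 to 12.
#' @return Path to the installed JSON file.
#' @export
preset_path <- function(row) {
  stopifnot(length(row) == 1L, row %in% 1:12)
  system.file("extdata", "presets", sprintf("table2_row%02d.json", row),
              package = "ccestimands", mustWork = TRUE)
}
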