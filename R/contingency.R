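# Closed-cohort 2x2 algebra: outcome OR, exposure OR, risk ratio, and the
# identities linking sample ORs under different control-sampling schemes to
# population quantities. No continuity corrections: zero cells in denominator
# positions are domain errors, since random variation is outside this layer.

#' Closed-cohort 2x2 table of outcome by exposure
#'
#' Counts of individuals in a closed cohort over a study period:
#' `a` exposed cases, `b` unexposed cases, `c` exposed non-cases, `d`
#' unexposed non-cases.
#'
#' @param a,b,c,d Non-negative counts.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (anyNA(v) || any(v < 0)) stop("all counts must be non-negative", call. = FALSE)
  structure(as.list(v), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("case", "non-case"), c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' Population odds ratio of a closed-cohort 2x2 table
#'
#' The outcome odds ratio ad/bc, identical to the exposure odds ratio of the
#' same table.
#'
#' @param t A `two_by_two`.
#' @return ad / bc.
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$b * t$c <= 0) stop("odds ratio undefined: b * c = 0", call. = FALSE)
  (t$a * t$d) / (t$b * t$c)
}

#' Risk ratio of a closed-cohort 2x2 table
#'
#' The ratio of outcome risks `a/(a+c)` (exposed) over `b/(b+d)` (unexposed).
#'
#' @param t A `two_by_two`.
#' @return The risk ratio.
#' @export
risk_ratio <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$a + t$c <= 0 || t$b + t$d <= 0) {
    stop("risk ratio undefined: an exposure margin is 0", call. = FALSE)
  }
  if (t$b <= 0) stop("risk ratio undefined: no unexposed cases", call. = FALSE)
  (t$a / (t$a + t$c)) / (t$b / (t$b + t$d))
}

#' A draw of controls, tagged by its sampling frame
#'
#' @param exposed,unexposed Non-negative control counts.
#' @param source `"noncases"` for controls sampled from those without the
#'   outcome by the end of the period (the classical exclusive design), or
#'   `"whole_cohort"` for controls sampled from the full baseline cohort
#'   regardless of outcome (the case-cohort design).
#' @return An object of class `control_draw`.
#' @export
control_draw <- function(exposed, unexposed, source = c("noncases", "whole_cohort")) {
  source <- match.arg(source)
  if (anyNA(c(exposed, unexposed)) || exposed < 0 || unexposed < 0) {
    stop("control counts must be non-negative", call. = FALSE)
  }
  structure(list(exposed = exposed, unexposed = unexposed, source = source),
            class = "control_draw")
}

#' Sample odds ratio of cases versus a control draw, and its target
#'
#' With `a` exposed and `b` unexposed cases, the sample exposure OR against a
#' control draw depends on the sampling frame. Controls drawn from the
#' non-cases (`e` exposed, `f` unexposed) give `a f / (b e)`, a consistent
#' estimator of the population odds ratio ad/bc. Controls drawn from the whole
#' baseline cohort (`g` exposed, `h` unexposed) give `(a/b) / (g/h)`, a
#' consistent estimator of the cohort risk ratio (the case-cohort design).
#' Sampling fractions cancel, so the estimate is invariant to the number of
#' controls drawn.
#'
#' @param exposed_cases,unexposed_cases Case counts a and b.
#' @param controls A [control_draw()].
#' @return The sample odds ratio.
#' @export
sample_or_from_controls <- function(exposed_cases, unexposed_cases, controls) {
  stopifnot(inherits(controls, "control_draw"))
  if (unexposed_cases <= 0) stop("sample OR undefined: no unexposed cases", call. = FALSE)
  if (controls$exposed <= 0) stop("sample OR undefined: no exposed controls", call. = FALSE)
  (exposed_cases * controls$unexposed) / (unexposed_cases * controls$exposed)
}
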