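# Reference table of estimands across the built-in scenarios, and writers.

#' Estimand table for the 12 built-in scenarios
#'
#' Computes, for each preset of [table2_presets()], the person-time rate
#' ratio, the matched and unmatched odds-ratio estimands, and the final
#' proportion unexposed. Full-precision columns are accompanied by columns
#' rounded to 2 decimals (`*_2dp`, round-half-even).
#'
#' @inheritParams table2_presets
#' @return A data frame with 12 rows and columns `hazard_ratio` and
#'   `exposure_rate` (comma-separated per-interval values), `rate_ratio`,
#'   `matched_or`, `unmatched_or`, `final_prop_unexposed`, and their `*_2dp`
#'   rounded versions.
#' @examples
#' table2_report()
#' @export
table2_report <- function(baseline_hazard_value = 0.025,
                          initial_unexposed_prop = 0.8,
                          steps_per_week = 1000L) {
  presets <- table2_presets(baseline_hazard_value, initial_unexposed_prop,
                            steps_per_week)
  rows <- lapply(presets, function(s) {
    e <- compute_estimands(s)
    data.frame(
      hazard_ratio = paste(s$hazard_ratio, collapse = ", "),
      exposure_rate = paste(s$exposure_rate, collapse = ", "),
      rate_ratio = e$rate_ratio,
      matched_or = e$matched_or,
      unmatched_or = e$unmatched_or,
      final_prop_unexposed = e$final_prop_unexposed
    )
  })
  out <- do.call(rbind, rows)
  for (col in c("rate_ratio", "matched_or", "unmatched_or", "final_prop_unexposed")) {
    out[[paste0(col, "_2dp")]] <- round(out[[col]], 2)
  }
  rownames(out) <- NULL
  out
}

#' Write a report data frame to CSV or JSON
#'
#' @param df A data frame (e.g. from [table2_report()] or
#'   [convergence_report()]).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path, format = NULL) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA, pretty = TRUE)
  }
  invisible(path)
}
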