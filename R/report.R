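# Survey-level performance report: the standard row of sample size,
# incidence tallies, Chao2 estimate with CI, and effort projections.

#' Survey performance report
#'
#' Assembles the per-survey performance measures: sample size `m`, total
#' incidences, uniques, duplicates, observed richness, the Chao2 estimate
#' (variant chosen by the ICE heterogeneity rule unless overridden) with
#' its 95% CI, the projected additional effort to detect 95% and 100% of
#' the estimated pool, and the percentage of the pool already detected.
#'
#' @param x `incidence_matrix` or `incidence_counts`.
#' @param site,year optional labels carried into the report row.
#' @param variant `"auto"`, `"classic"` or `"bias_corrected"`.
#' @param g fraction for the partial-detection effort column.
#' @return one-row data frame of class `survey_report` with columns
#'   `site`, `year`, `m`, `incidences`, `uniques`, `duplicates`, `sobs`,
#'   `variant`, `sest`, `ci_low`, `ci_high`, `s95_additional`,
#'   `s100_additional`, `percent_detected`.
#' @export
survey_report <- function(x, site = NA_character_, year = NA_integer_,
                          variant = "auto", g = 0.95) {
  if (inherits(x, "incidence_matrix")) x <- counts_with_minfreq(x)
  stopifnot(inherits(x, "incidence_counts"))
  est <- chao2(x, variant = variant)
  eff95 <- tryCatch(effort_to_fraction(est, g = g)$m_additional,
                    error = function(e) NA_real_)
  eff100 <- tryCatch(effort_to_census(est)$m_additional,
                     error = function(e) NA_real_)
  if (est$Q0 == 0) { eff95 <- 0; eff100 <- 0 }
  out <- data.frame(
    site = site, year = year, m = x$m,
    incidences = x$incidences, uniques = x$Q1, duplicates = x$Q2,
    sobs = x$Sobs, variant = est$variant,
    sest = round(est$Sest, 1),
    ci_low = round(est$ci_low, 1), ci_high = round(est$ci_high, 1),
    s95_additional = eff95, s100_additional = eff100,
    percent_detected = percent_detected(est),
    stringsAsFactors = FALSE)
  class(out) <- c("survey_report", "data.frame")
  out
}

#' Write a survey report as CSV and JSON
#'
#' @param report a `survey_report` (or any data frame of report rows).
#' @param path output path without extension; `<path>.csv` and
#'   `<path>.json` are written.
#' @return invisibly, the two file paths.
#' @export
write_survey_report <- function(report, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  write.csv(report, csv, row.names = FALSE)
  jsonlite::write_json(report, js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv = csv, json = js))
}
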