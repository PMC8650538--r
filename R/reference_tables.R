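#' Published UK Biobank country-of-birth summary tables
#'
#' Returns the published cohort summary statistics for UK Biobank
#' participants grouped by country of birth, as shipped with the package:
#' the categorical 2x2 counts for England vs Scotland (gender,
#' antihypertensive medication, smoking, diabetes), per-country CAD
#' prevalence with sample sizes, and the systolic blood pressure summary.
#' These printed tables are the only individual-data-free inputs from which
#' the between-country tests can be recomputed exactly.
#'
#' @return A list with elements `counts` (long-format 2x2 counts),
#'   `prevalence` (country, n, CAD prevalence in percent) and `sbp`
#'   (country, n, mean, sd).
#' @export
ukb_country_tables <- function() {
  ext <- function(f) utils::read.delim(
    system.file("extdata", f, package = "popgrs", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(counts = ext("ukb_table1_counts.tsv"),
       prevalence = ext("ukb_country_prevalence.tsv"),
       sbp = ext("ukb_sbp_summary.tsv"))
}

#' 2x2 count table for one categorical variable
#'
#' @param counts The `counts` element of [ukb_country_tables()] (or any
#'   long-format table with columns variable/level and two count columns).
#' @param variable Which variable to extract.
#' @return A 2x2 matrix (levels x populations) ready for
#'   [chi2_two_by_two()].
#' @export
counts_2x2 <- function(counts, variable) {
  sub <- counts[counts$variable == variable, ]
  if (nrow(sub) != 2)
    abort_popgrs(sprintf("variable '%s' does not have exactly two levels", variable),
                 "popgrs_validation_error")
  m <- as.matrix(sub[, 3:4])
  dimnames(m) <- list(sub$level, names(sub)[3:4])
  m
}

#' Reconstruct case/control counts from a printed prevalence
#'
#' Published prevalences are printed to two decimals; the closest integer
#' case count is `round(n * prevalence)`.
#'
#' @param n Sample size.
#' @param prevalence_pct Prevalence in percent.
#' @return Length-2 integer vector (cases, controls).
#' @export
prevalence_counts <- function(n, prevalence_pct) {
  cases <- round(n * prevalence_pct / 100)
  c(cases = as.integer(cases), controls = as.integer(n - cases))
}

#' Two-sample z test from summary statistics
#'
#' Compares two means given only their printed summaries (mean, SD, n), the
#' only comparison available when raw columns are not published.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Per-group summary statistics.
#' @return A `test_result` with `method = "summary_z"` (two-sided normal p).
#' @export
z_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  z <- (mean1 - mean2) / sqrt(sd1^2 / n1 + sd2^2 / n2)
  new_test_result("summary_z", z, NA_real_, 2 * stats::pnorm(-abs(z)), n1, n2)
}
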