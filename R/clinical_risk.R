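#' Load a Cox 10-year risk score specification
#'
#' A score specification is data, not code: per sex it lists the linear
#' predictor terms (variable, transform, optional guard condition, beta),
#' the baseline 10-year survival `s0`, and the derivation-cohort mean
#' linear predictor `mean_lp`. The 10-year risk of a record with linear
#' predictor `L` is `(1 - s0 ^ exp(L - mean_lp)) * 100` percent.
#'
#' @param path JSON or YAML file with keys `name` and one block per sex
#'   (`F`, `M`), each `{terms: [{variable, transform, condition?, beta}],
#'   s0, mean_lp}`. `transform` is `"identity"` or `"ln"`; `condition` is
#'   `{variable, equals}` and guards terms such as treated/untreated SBP.
#' @return A list of class `cox_score_spec`.
#' @export
load_score_spec <- function(path) {
  if (!file.exists(path)) abort_popgrs(sprintf("score spec not found: %s", path), "popgrs_io_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = FALSE)
  validate_score_spec(raw)
}

phenotype_variables <- c("age", "bmi", "sbp", "tc", "hdl",
                         "smoker", "diabetic", "antihypertensive", "sex")

#' @rdname load_score_spec
#' @param spec A list with the structure described above (already parsed).
#' @export
validate_score_spec <- function(spec) {
  if (is.null(spec$name)) abort_popgrs("score spec needs a name", "popgrs_schema_error")
  for (sx in c("F", "M")) {
    blk <- spec[[sx]]
    if (is.null(blk))
      abort_popgrs(sprintf("score spec '%s' lacks a block for sex %s", spec$name, sx),
                   "popgrs_schema_error")
    if (is.null(blk$s0) || blk$s0 <= 0 || blk$s0 >= 1)
      abort_popgrs(sprintf("s0 must be in (0,1) for sex %s", sx), "popgrs_schema_error")
    if (is.null(blk$mean_lp))
      abort_popgrs(sprintf("mean_lp missing for sex %s", sx), "popgrs_schema_error")
    seen <- character(0)
    for (term in blk$terms) {
      if (is.null(term$variable) || !term$variable %in% phenotype_variables)
        abort_popgrs(sprintf("unknown variable '%s' in score spec '%s'",
                             term$variable %||% "<missing>", spec$name),
                     "popgrs_schema_error")
      tr <- term$transform %||% "identity"
      if (!tr %in% c("identity", "ln"))
        abort_popgrs(sprintf("unknown transform '%s'", tr), "popgrs_schema_error")
      if (!is.numeric(term$beta) && !is.numeric(suppressWarnings(as.numeric(term$beta))))
        abort_popgrs(sprintf("non-numeric beta for '%s'", term$variable), "popgrs_schema_error")
      key <- paste(term$variable,
                   if (is.null(term$condition)) "" else
                     paste(term$condition$variable, term$condition$equals), sep = "|")
      if (key %in% seen)
        abort_popgrs(sprintf("duplicate term for '%s' (same condition) in sex %s",
                             term$variable, sx), "popgrs_schema_error")
      seen <- c(seen, key)
    }
  }
  class(spec) <- "cox_score_spec"
  spec
}

term_applies <- function(term, record) {
  if (is.null(term$condition)) return(rep(TRUE, nrow(record)))
  v <- record[[term$condition$variable]]
  if (is.null(v))
    abort_popgrs(sprintf("condition variable '%s' absent from records",
                         term$condition$variable), "popgrs_schema_error")
  v == term$condition$equals
}

#' Evaluate a Cox 10-year risk score for one record
#'
#' Sums `beta * transform(value)` over the sex-matched terms whose guard
#' condition holds, then converts the centred linear predictor to a 10-year
#' risk percentage via the baseline survival: `(1 - s0^exp(L - mean_lp)) *
#' 100`. The result is clipped to (0, 100) in the numerically extreme tails
#' and is never `NaN`.
#'
#' @param record A one-row phenotype `data.frame` (or a full table; all rows
#'   are evaluated).
#' @param spec A [load_score_spec()] result.
#' @return Risk percent in \[0, 100\], one value per row.
#' @export
evaluate_cox_risk <- function(record, spec) {
  if (!inherits(spec, "cox_score_spec"))
    abort_popgrs("spec must come from load_score_spec()/validate_score_spec()",
                 "popgrs_validation_error")
  record <- as.data.frame(record)
  risk <- rep(NA_real_, nrow(record))
  for (sx in c("F", "M")) {
    rows <- which(record$sex == sx)
    if (!length(rows)) next
    blk <- spec[[sx]]
    sub <- record[rows, , drop = FALSE]
    lp <- rep(0, length(rows))
    for (term in blk$terms) {
      val <- sub[[term$variable]]
      if (is.null(val))
        abort_popgrs(sprintf("records lack variable '%s' required by score '%s'",
                             term$variable, spec$name), "popgrs_schema_error")
      if (is.logical(val)) val <- as.numeric(val)
      tr <- term$transform %||% "identity"
      if (tr == "ln") {
        if (any(val <= 0))
          abort_popgrs(sprintf("ln transform of non-positive %s (sample %s)",
                               term$variable,
                               sub$sample_id[which(val <= 0)[1]] %||% "?"),
                       "popgrs_validation_error")
        val <- log(val)
      }
      lp <- lp + as.numeric(term$beta) * val * term_applies(term, sub)
    }
    surv <- blk$s0 ^ exp(lp - blk$mean_lp)   # exp overflow -> surv 0 -> risk 100
    risk[rows] <- pmin(100, pmax(0, (1 - surv) * 100))
  }
  if (anyNA(risk))
    abort_popgrs("records with sex other than F/M cannot be scored", "popgrs_validation_error")
  risk
}

#' Score a cohort with a Cox risk specification
#'
#' Vectorised [evaluate_cox_risk()] over a phenotype table with row-level
#' error reporting: by default any invalid record (e.g. a non-positive value
#' under a log transform) aborts the run; with `skip_invalid = TRUE` the
#' offending rows score `NA` and a warning summarises them.
#'
#' @param records Phenotype `data.frame`.
#' @param spec A `cox_score_spec`.
#' @param skip_invalid Score invalid rows as `NA` instead of aborting.
#' @return Numeric risk-percent vector aligned with `records`.
#' @export
score_cohort <- function(records, spec, skip_invalid = FALSE) {
  res <- try(evaluate_cox_risk(records, spec), silent = TRUE)
  if (!inherits(res, "try-error")) return(res)
  if (!skip_invalid) stop(attr(res, "condition"))
  # fall back to row-wise evaluation, collecting failures
  out <- rep(NA_real_, nrow(records))
  bad <- 0L
  for (i in seq_len(nrow(records))) {
    ri <- try(evaluate_cox_risk(records[i, , drop = FALSE], spec), silent = TRUE)
    if (inherits(ri, "try-error")) bad <- bad + 1L else out[i] <- ri
  }
  warning(sprintf("score '%s': %d record(s) failed validation and were scored NA",
                  spec$name, bad), call. = FALSE)
  out
}

#' Path to a shipped Framingham score specification
#'
#' Two specifications ship with the package, carrying the published
#' sex-stratified general-CVD Cox model coefficients: `"frs_lipids"` (total
#' and HDL cholesterol, mg/dL) and `"frs_bmi"` (BMI replacing the lipids).
#'
#' @param name `"frs_lipids"` or `"frs_bmi"`.
#' @return File path inside the installed package.
#' @export
frs_spec_path <- function(name = c("frs_lipids", "frs_bmi")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".json"), package = "popgrs", mustWork = TRUE)
}
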