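#' Risk-allele frequency from a genotype matrix
#'
#' RAF of a variant is the sum of non-missing risk-allele dosages divided by
#' twice the number of non-missing samples (i.e. the fraction of genotyped
#' chromosomes carrying the risk allele).
#'
#' @param gm A [genotype_matrix()].
#' @param variant Optional single variant id; if omitted the RAF of every
#'   variant is returned as a named vector.
#' @return Frequency in \[0, 1\] (scalar or named vector). A variant with
#'   all genotypes missing is an error naming the variant.
#' @export
compute_raf <- function(gm, variant = NULL) {
  if (!is.null(variant)) {
    if (!variant %in% colnames(gm))
      abort_popgrs(sprintf("unknown variant '%s'", variant), "popgrs_validation_error")
    gm <- gm[, variant, drop = FALSE]
  }
  n_ok <- colSums(!is.na(gm))
  if (any(n_ok == 0))
    abort_popgrs(sprintf("all genotypes missing at variant %s",
                         colnames(gm)[which(n_ok == 0)[1]]), "popgrs_validation_error")
  raf <- colSums(gm, na.rm = TRUE) / (2 * n_ok)
  if (!is.null(variant)) unname(raf) else raf
}

#' Impute missing dosages by their expected value
#'
#' Each missing genotype is replaced by twice the risk-allele frequency of
#' its variant — the expected dosage under Hardy-Weinberg — leaving
#' non-missing entries untouched. Imputed values are generally non-integer,
#' so the result is a plain numeric matrix.
#'
#' @param gm A [genotype_matrix()] (may contain `NA`).
#' @param rafs Named RAF vector covering every variant with a missing entry
#'   (typically [compute_raf()] on the analysis cohort).
#' @return Numeric matrix, same dimnames as `gm`, no missing entries, with
#'   attribute `n_imputed`: per-sample count of imputed variants.
#' @export
impute_missing <- function(gm, rafs) {
  x <- unclass(gm)
  storage.mode(x) <- "double"
  miss <- is.na(x)
  n_imputed <- as.integer(rowSums(miss))
  if (any(miss)) {
    need <- colnames(x)[colSums(miss) > 0]
    lacking <- setdiff(need, names(rafs))
    if (length(lacking))
      abort_popgrs(sprintf("no RAF supplied for variant(s) with missing data: %s",
                           paste(utils::head(lacking, 5), collapse = ", ")),
                   "popgrs_validation_error")
    fill <- matrix(2 * rafs[colnames(x)], nrow = nrow(x), ncol = ncol(x), byrow = TRUE)
    x[miss] <- fill[miss]
  }
  attr(x, "n_imputed") <- stats::setNames(n_imputed, rownames(x))
  x
}

#' Unweighted and weighted genetic risk scores
#'
#' Per sample, the unweighted score `ugrs` is the total number of risk
#' alleles carried across the K scored variants, and the weighted score
#' `wgrs` is the dosage-weighted sum of per-allele log odds ratios:
#' `ugrs = sum_k X_k`, `wgrs = sum_k ln(OR_k) * X_k`.
#'
#' @param dosages Numeric samples-by-variants dosage matrix with no missing
#'   entries (run [impute_missing()] first); column order must equal the
#'   weight-table order.
#' @param weights A `variant_weights` table.
#' @return A `data.frame` of class `score_table` with columns `sample_id`,
#'   `ugrs`, `wgrs`, `n_imputed` (taken from the `n_imputed` attribute set
#'   by [impute_missing()], 0 otherwise).
#' @export
compute_scores <- function(dosages, weights) {
  if (!inherits(weights, "variant_weights"))
    abort_popgrs("weights must come from read_weights_table()/simulate_weights()",
                 "popgrs_validation_error")
  if (ncol(dosages) != nrow(weights) ||
      !identical(colnames(dosages), weights$rsid))
    abort_popgrs("dosage matrix variants do not match weight table order",
                 "popgrs_validation_error")
  if (anyNA(dosages))
    abort_popgrs("dosage matrix has missing entries; run impute_missing() first",
                 "popgrs_validation_error")
  n_imp <- attr(dosages, "n_imputed") %||% rep(0L, nrow(dosages))
  x <- unclass(dosages)
  storage.mode(x) <- "double"
  out <- data.frame(sample_id = rownames(dosages),
                    ugrs = as.vector(x %*% rep(1, nrow(weights))),
                    wgrs = as.vector(x %*% weights$log_or),
                    n_imputed = as.integer(n_imp),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}
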