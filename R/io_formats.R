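#' Read a risk-variant weight table
#'
#' Reads a tab-separated table of risk loci (one row per biallelic SNP) and
#' derives the per-allele log odds ratio used as the weight in the weighted
#' genetic risk score.
#'
#' @param path Path to a TSV file with header columns
#'   `rsid chrom pos risk_allele other_allele odds_ratio`.
#' @return A `data.frame` of class `variant_weights` with the input columns
#'   plus `log_or = log(odds_ratio)`, in file order.
#' @details Validation: every odds ratio must be a positive number, the risk
#'   and other alleles must be distinct single bases in A/C/G/T, and rsids
#'   must be unique. Violations raise an error naming the offending column or
#'   row.
#' @export
read_weights_table <- function(path) {
  if (!file.exists(path)) abort_popgrs(sprintf("weights file not found: %s", path), "popgrs_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  required <- c("rsid", "chrom", "pos", "risk_allele", "other_allele", "odds_ratio")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    abort_popgrs(sprintf("weights table is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")), "popgrs_schema_error")
  df <- df[required]
  df$pos <- parse_numeric_col(df$pos, "pos")
  df$odds_ratio <- parse_numeric_col(df$odds_ratio, "odds_ratio")
  bad_or <- which(!(df$odds_ratio > 0))
  if (length(bad_or))
    abort_popgrs(sprintf("odds_ratio must be > 0; violated at row %d (value %s)",
                         bad_or[1], df$odds_ratio[bad_or[1]]), "popgrs_validation_error")
  bases <- c("A", "C", "G", "T")
  for (col in c("risk_allele", "other_allele")) {
    bad <- which(!(df[[col]] %in% bases))
    if (length(bad))
      abort_popgrs(sprintf("%s must be a single base A/C/G/T; violated at row %d ('%s')",
                           col, bad[1], df[[col]][bad[1]]), "popgrs_validation_error")
  }
  same <- which(df$risk_allele == df$other_allele)
  if (length(same))
    abort_popgrs(sprintf("risk_allele equals other_allele at row %d (rsid %s)",
                         same[1], df$rsid[same[1]]), "popgrs_validation_error")
  dup <- which(duplicated(df$rsid))
  if (length(dup))
    abort_popgrs(sprintf("duplicate rsid '%s' at row %d", df$rsid[dup[1]], dup[1]),
                 "popgrs_validation_error")
  df$log_or <- log(df$odds_ratio)
  class(df) <- c("variant_weights", "data.frame")
  df
}

parse_numeric_col <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad))
    abort_popgrs(sprintf("non-numeric value '%s' in column '%s' at row %d",
                         x[bad[1]], col, bad[1]), "popgrs_validation_error")
  out
}

#' Construct a genotype (risk-allele dosage) matrix
#'
#' A genotype matrix stores, per sample and variant, the number of copies of
#' the *risk* allele (0, 1 or 2), with `NA` for missing genotypes. Rows are
#' samples, columns variants.
#'
#' @param dosages Integer-like matrix with values in \{0, 1, 2, NA\}.
#' @param sample_ids,variant_ids Row and column identifiers; must be unique
#'   and match the matrix dimensions.
#' @return An integer matrix of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            variant_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids) || is.null(variant_ids))
    abort_popgrs("genotype_matrix requires sample and variant ids", "popgrs_validation_error")
  if (length(sample_ids) != nrow(dosages) || length(variant_ids) != ncol(dosages))
    abort_popgrs("id lists do not match matrix dimensions", "popgrs_validation_error")
  if (anyDuplicated(sample_ids) || anyDuplicated(variant_ids))
    abort_popgrs("duplicate sample or variant ids", "popgrs_validation_error")
  ok <- is.na(dosages) | dosages %in% c(0L, 1L, 2L)
  if (!all(ok))
    abort_popgrs("dosages must be 0, 1, 2 or NA", "popgrs_validation_error")
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(sample_ids, variant_ids)
  class(dosages) <- c("genotype_matrix", class(matrix()))
  dosages
}

#' Read risk-allele dosages from a VCF
#'
#' Parses GT fields of a VCF (4.x, biallelic SNVs) and orients each genotype
#' against the risk allele declared in a weight table: if the risk allele is
#' the ALT allele the dosage is the ALT-allele count, if it is the REF allele
#' the dosage is `2 - ALT count`. Missing genotypes (`./.` or `.`) and
#' half-calls (e.g. `0/.`) become `NA`.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param weights A `variant_weights` table; variants are matched by rsid
#'   against the VCF ID column, falling back to chrom+pos.
#' @param mismatch_policy `"skip"` drops (with a warning) variants whose
#'   REF/ALT pair does not equal the declared risk/other allele pair;
#'   `"error"` aborts on the first such variant.
#' @return A [genotype_matrix()] whose columns are the matched variants in
#'   weight-table order, with attributes `absent` (rsids in the weight table
#'   not found in the VCF) and `dropped` (rsids dropped under `"skip"`).
#' @details Alleles are matched literally; no strand flipping is attempted.
#'   Palindromic (A/T or C/G) variants match literally too and trigger a
#'   warning, since their orientation cannot be verified from alleles alone.
#'   A multi-allelic record matched to a weight is an error.
#' @export
read_vcf_genotypes <- function(path, weights, mismatch_policy = c("skip", "error")) {
  mismatch_policy <- match.arg(mismatch_policy)
  if (!inherits(weights, "variant_weights"))
    abort_popgrs("weights must come from read_weights_table()", "popgrs_validation_error")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vcf_id <- fix[, "ID"]
  vcf_key <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)

  idx <- match(weights$rsid, vcf_id)
  fallback <- is.na(idx)
  idx[fallback] <- match(paste(weights$chrom, weights$pos, sep = ":")[fallback], vcf_key)

  absent <- weights$rsid[is.na(idx)]
  if (length(absent))
    message(sprintf("%d weight-table variant(s) absent from VCF: %s",
                    length(absent), paste(utils::head(absent, 5), collapse = ", ")))

  keep <- which(!is.na(idx))
  dropped <- character(0)
  dosage_cols <- vector("list", length(keep))
  col_ids <- character(length(keep))
  use <- logical(length(keep))
  for (j in seq_along(keep)) {
    w <- keep[j]
    i <- idx[w]
    ref <- unname(fix[i, "REF"]); alt <- unname(fix[i, "ALT"])
    coord <- sprintf("%s:%s (%s)", fix[i, "CHROM"], fix[i, "POS"], weights$rsid[w])
    if (grepl(",", alt, fixed = TRUE))
      abort_popgrs(sprintf("multi-allelic record matched to weight table at %s", coord),
                   "popgrs_vcf_error")
    pair_vcf <- sort(c(ref, alt))
    pair_w <- sort(c(weights$risk_allele[w], weights$other_allele[w]))
    if (!identical(pair_vcf, pair_w)) {
      if (mismatch_policy == "error")
        abort_popgrs(sprintf("REF/ALT (%s/%s) do not match declared alleles (%s/%s) at %s",
                             ref, alt, weights$risk_allele[w], weights$other_allele[w], coord),
                     "popgrs_vcf_error")
      warning(sprintf("skipping %s: REF/ALT (%s/%s) do not match declared alleles",
                      weights$rsid[w], ref, alt), call. = FALSE)
      dropped <- c(dropped, weights$rsid[w])
      next
    }
    if (pair_vcf[1] == complement_base(pair_vcf[2]))
      warning(sprintf("palindromic alleles (%s/%s) at %s matched literally; strand unverifiable",
                      ref, alt, weights$rsid[w]), call. = FALSE)
    alt_count <- parse_gt(gt_raw[i, ], coord)
    dosage_cols[[j]] <- if (weights$risk_allele[w] == alt) alt_count else 2L - alt_count
    col_ids[j] <- weights$rsid[w]
    use[j] <- TRUE
  }
  if (!any(use))
    abort_popgrs("no weight-table variants usable from VCF", "popgrs_vcf_error")
  mat <- do.call(cbind, dosage_cols[use])
  gm <- genotype_matrix(mat, sample_ids = samples, variant_ids = col_ids[use])
  attr(gm, "absent") <- absent
  attr(gm, "dropped") <- dropped
  gm
}

complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

# ALT-allele count from GT strings; NA for "./.", "." and half-calls.
parse_gt <- function(gt, coord) {
  gt[is.na(gt)] <- "."
  out <- rep(NA_integer_, length(gt))
  full_missing <- gt %in% c("./.", ".", ".|.")
  half <- grepl("^[01.][/|][01.]$", gt) & grepl("\\.", gt) & !full_missing
  if (any(half))
    warning(sprintf("%d half-call(s) at %s treated as missing", sum(half), coord),
            call. = FALSE)
  called <- !full_missing & !half
  valid <- grepl("^[01][/|][01]$", gt[called])
  if (!all(valid))
    abort_popgrs(sprintf("malformed GT '%s' at %s", gt[called][!valid][1], coord),
                 "popgrs_vcf_error")
  out[called] <- (substr(gt[called], 1, 1) == "1") + (substr(gt[called], 3, 3) == "1")
  out
}

#' Read a phenotype table
#'
#' Reads a TSV of per-participant clinical covariates, CAD status and
#' population label. Booleans are encoded 0/1 on disk; unknown extra columns
#' are carried through untouched.
#'
#' @param path Path to a TSV with header columns `sample_id population sex
#'   age bmi sbp tc hdl smoker diabetic antihypertensive cad`.
#' @return A `data.frame` with logical columns for
#'   smoker/diabetic/antihypertensive/cad and numeric clinical covariates.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) abort_popgrs(sprintf("phenotype file not found: %s", path), "popgrs_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "population", "sex", "age", "bmi", "sbp", "tc",
                "hdl", "smoker", "diabetic", "antihypertensive", "cad")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    abort_popgrs(sprintf("phenotype table is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")), "popgrs_schema_error")
  if (nrow(df) == 0) {
    for (col in c("age", "bmi", "sbp", "tc", "hdl")) df[[col]] <- numeric(0)
    for (col in c("smoker", "diabetic", "antihypertensive", "cad")) df[[col]] <- logical(0)
    return(df)
  }
  bad_sex <- which(!(df$sex %in% c("F", "M")))
  if (length(bad_sex))
    abort_popgrs(sprintf("sex must be 'F' or 'M'; found '%s' at row %d",
                         df$sex[bad_sex[1]], bad_sex[1]), "popgrs_validation_error")
  for (col in c("age", "bmi", "sbp", "tc", "hdl")) {
    df[[col]] <- parse_numeric_col(df[[col]], col)
    bad <- which(!(df[[col]] > 0))
    if (length(bad))
      abort_popgrs(sprintf("%s must be > 0; violated at row %d", col, bad[1]),
                   "popgrs_validation_error")
  }
  for (col in c("smoker", "diabetic", "antihypertensive", "cad")) {
    bad <- which(!(df[[col]] %in% c("0", "1", "TRUE", "FALSE")))
    if (length(bad))
      abort_popgrs(sprintf("%s must be 0/1; found '%s' at row %d",
                           col, df[[col]][bad[1]], bad[1]), "popgrs_validation_error")
    df[[col]] <- df[[col]] %in% c("1", "TRUE")
  }
  if (anyDuplicated(df$sample_id))
    abort_popgrs("duplicate sample_id in phenotype table", "popgrs_validation_error")
  df
}

#' Write a results (or phenotype) table as TSV
#'
#' Logical columns are written as 0/1; numeric columns at full precision so
#' that write-then-read is the identity on all fields.
#'
#' @param rows A `data.frame`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results_table <- function(rows, path) {
  out <- as.data.frame(rows)
  for (col in names(out)) if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
write_phenotype_table <- function(rows, path) write_results_table(rows, path)

#' Write a weight table as TSV
#' @param weights A `variant_weights` table.
#' @param path Output path.
#' @export
write_weights_table <- function(weights, path) {
  cols <- c("rsid", "chrom", "pos", "risk_allele", "other_allele", "odds_ratio")
  write_results_table(as.data.frame(weights)[cols], path)
}

#' Write a genotype matrix as a minimal plain-text VCF
#'
#' Emits a VCFv4.2 file with CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO,
#' FORMAT(GT) and one genotype column per sample. Used by the synthetic
#' cohort generator; the risk allele is written as ALT where `risk_is_alt`
#' is `TRUE` and as REF otherwise, so both dosage orientations are exercised
#' on re-reading.
#'
#' @param gm A [genotype_matrix()] of risk-allele dosages.
#' @param weights Matching `variant_weights` table (same variants, same order).
#' @param path Output path.
#' @param risk_is_alt Logical vector, one per variant (default alternating).
#' @export
write_vcf_genotypes <- function(gm, weights, path,
                                risk_is_alt = rep_len(c(TRUE, FALSE), ncol(gm))) {
  stopifnot(ncol(gm) == nrow(weights), identical(colnames(gm), weights$rsid))
  gt_str <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gm)), collapse = "\t")), con)
  for (k in seq_len(ncol(gm))) {
    ref <- if (risk_is_alt[k]) weights$other_allele[k] else weights$risk_allele[k]
    alt <- if (risk_is_alt[k]) weights$risk_allele[k] else weights$other_allele[k]
    alt_count <- if (risk_is_alt[k]) gm[, k] else 2L - gm[, k]
    cells <- ifelse(is.na(alt_count), "./.", gt_str[alt_count + 1L])
    writeLines(paste(c(weights$chrom[k], weights$pos[k], weights$rsid[k], ref, alt,
                       ".", "PASS", ".", "GT", cells), collapse = "\t"), con)
  }
  invisible(path)
}
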