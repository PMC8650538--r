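#' Build or validate a pipeline run configuration
#'
#' A run is driven either by a `simulation` block (synthetic cohort) or by
#' real input `paths` (weights TSV, one VCF per population, phenotype TSV)
#' — exactly one of the two. Options cover the GRS imputation scope, the
#' VCF mismatch policy, the clinical score specs to apply, and the
#' comparison thresholds.
#'
#' @param config A named list, or a path to a JSON/YAML file holding one.
#' @return The validated config (class `run_config`), with defaults filled
#'   in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config) else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  has_sim <- !is.null(config$simulation)
  has_paths <- !is.null(config$paths)
  if (has_sim == has_paths)
    abort_popgrs("config must contain exactly one of 'simulation' or 'paths'",
                 "popgrs_config_error")
  if (has_sim && is.null(config$seed))
    abort_popgrs("a seed is required when simulating", "popgrs_config_error")
  config$labels <- config$labels %||% c("England", "Scotland")
  config$grs <- utils::modifyList(
    list(imputation_scope = "pooled", mismatch_policy = "skip"),
    config$grs %||% list())
  if (!config$grs$imputation_scope %in% c("pooled", "per_population"))
    abort_popgrs("imputation_scope must be 'pooled' or 'per_population'",
                 "popgrs_config_error")
  config$score_specs <- config$score_specs %||% c("frs_lipids", "frs_bmi")
  config$compare <- utils::modifyList(list(alpha = 0.05, alpha_adj = 0.001),
                                      config$compare %||% list())
  if (has_sim)
    config$simulation <- utils::modifyList(
      list(n_a = 30000, n_b = 3000, n_variants = 163, n_higher_a = 37,
           n_higher_b = 35, delta = 0.02, missing_rate = 0.002,
           full_scale = FALSE),
      config$simulation)
  class(config) <- c("run_config", "list")
  config
}

#' Run the full two-population risk comparison pipeline
#'
#' Stages, in order: (1) simulate or ingest cohort; (2) genetic risk scores
#' with expected-value imputation; (3) clinical Cox risk scores; (4)
#' population comparisons — CAD prevalence chi-squared, Welch t on uGRS and
#' wGRS, Mann-Whitney on the skewed clinical scores, Kolmogorov-Smirnov on
#' every score distribution; (5) per-SNP risk-allele-frequency scan with
#' Bonferroni correction. All output tables, a summary JSON and a markdown
#' report are written under `out_dir`; re-running with the same config and
#' seed reproduces every output byte for byte.
#'
#' @param config A [run_config()] (or list/path coercible to one).
#' @param out_dir Output directory.
#' @return A list of class `run_report` (also serialised to
#'   `summary.json`): per-population n, prevalence test, score comparison
#'   tables, scan summary, file paths, seed and config hash.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  # -- stage 1: inputs ------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    cohort <- simulate_cohort(n_a = sim$n_a, n_b = sim$n_b,
                              n_variants = sim$n_variants,
                              n_higher_a = sim$n_higher_a,
                              n_higher_b = sim$n_higher_b,
                              delta = sim$delta,
                              missing_rate = sim$missing_rate,
                              full_scale = isTRUE(sim$full_scale),
                              seed = config$seed)
    weights <- cohort$weights
    geno <- cohort$genotypes
    pheno <- cohort$phenotypes
  } else {
    weights <- read_weights_table(config$paths$weights)
    geno <- list(
      a = read_vcf_genotypes(config$paths$vcf_a, weights,
                             mismatch_policy = config$grs$mismatch_policy),
      b = read_vcf_genotypes(config$paths$vcf_b, weights,
                             mismatch_policy = config$grs$mismatch_policy))
    shared <- intersect(colnames(geno$a), colnames(geno$b))
    geno$a <- genotype_matrix(geno$a[, shared, drop = FALSE])
    geno$b <- genotype_matrix(geno$b[, shared, drop = FALSE])
    weights <- weights[match(shared, weights$rsid), ]
    class(weights) <- c("variant_weights", "data.frame")
    pheno <- read_phenotype_table(config$paths$phenotypes)
  }
  lab <- config$labels
  ph_a <- pheno[pheno$population == lab[1], ]
  ph_b <- pheno[pheno$population == lab[2], ]
  if (!nrow(ph_a) || !nrow(ph_b))
    abort_popgrs("stage 'inputs' failed: a population label matched no phenotype rows",
                 "popgrs_config_error")

  # -- stage 2: genetic risk scores ----------------------------------------
  if (config$grs$imputation_scope == "pooled") {
    pooled <- genotype_matrix(rbind(unclass(geno$a), unclass(geno$b)))
    rafs_imp_a <- rafs_imp_b <- compute_raf(pooled)
  } else {
    rafs_imp_a <- compute_raf(geno$a)
    rafs_imp_b <- compute_raf(geno$b)
  }
  scores <- rbind(
    cbind(compute_scores(impute_missing(geno$a, rafs_imp_a), weights),
          population = lab[1], stringsAsFactors = FALSE),
    cbind(compute_scores(impute_missing(geno$b, rafs_imp_b), weights),
          population = lab[2], stringsAsFactors = FALSE))

  # -- stage 3: clinical risk scores ---------------------------------------
  clin <- data.frame(sample_id = pheno$sample_id,
                     population = pheno$population, stringsAsFactors = FALSE)
  for (spec_name in config$score_specs) {
    spec <- load_score_spec(
      if (file.exists(spec_name)) spec_name else frs_spec_path(spec_name))
    clin[[spec$name]] <- score_cohort(pheno, spec)
  }

  # -- stage 4: population comparisons -------------------------------------
  prev_tab <- rbind(c(sum(ph_a$cad), sum(ph_b$cad)),
                    c(sum(!ph_a$cad), sum(!ph_b$cad)))
  prevalence <- list(
    n_a = nrow(ph_a), n_b = nrow(ph_b),
    prev_a = mean(ph_a$cad), prev_b = mean(ph_b$cad),
    relative_difference_pct =
      (mean(ph_b$cad) - mean(ph_a$cad)) / mean(ph_a$cad) * 100,
    test = chi2_two_by_two(prev_tab))

  sc_a <- scores[scores$population == lab[1], ]
  sc_b <- scores[scores$population == lab[2], ]
  cl_a <- clin[clin$population == lab[1], ]
  cl_b <- clin[clin$population == lab[2], ]
  comparisons <- list()
  for (col in c("ugrs", "wgrs"))
    comparisons[[col]] <- list(summary_a = score_summary(sc_a[[col]]),
                               summary_b = score_summary(sc_b[[col]]),
                               welch = welch_ttest(sc_a[[col]], sc_b[[col]]),
                               ks = ks_two_sample(sc_a[[col]], sc_b[[col]]))
  for (col in setdiff(names(clin), c("sample_id", "population")))
    comparisons[[col]] <- list(summary_a = score_summary(cl_a[[col]]),
                               summary_b = score_summary(cl_b[[col]]),
                               mannwhitney = mannwhitney(cl_a[[col]], cl_b[[col]]),
                               ks = ks_two_sample(cl_a[[col]], cl_b[[col]]))

  # -- stage 5: allele-frequency scan --------------------------------------
  scan <- af_scan(geno$a, geno$b, weights, alpha_adj = config$compare$alpha_adj)
  scan_summary <- summarize_scan(scan)

  # -- outputs --------------------------------------------------------------
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  config_hash <- unname(tools::md5sum(cfg_json))

  paths <- c(config = cfg_json,
             scores = file.path(out_dir, "grs_scores.tsv"),
             clinical = file.path(out_dir, "clinical_scores.tsv"),
             raf_report = file.path(out_dir, "raf_by_population.tsv"),
             scan = file.path(out_dir, "af_scan.tsv"),
             summary = file.path(out_dir, "summary.json"),
             report = file.path(out_dir, "report.md"))
  write_results_table(round_df(scores, 6), paths["scores"])
  write_results_table(round_df(clin, 6), paths["clinical"])
  raf_report <- rbind(
    data.frame(rsid = colnames(geno$a), population = lab[1],
               raf = unname(compute_raf(geno$a)),
               n_nonmissing = colSums(!is.na(geno$a)), row.names = NULL),
    data.frame(rsid = colnames(geno$b), population = lab[2],
               raf = unname(compute_raf(geno$b)),
               n_nonmissing = colSums(!is.na(geno$b)), row.names = NULL))
  write_results_table(round_df(raf_report, 6), paths["raf_report"])
  write_results_table(round_df(as.data.frame(scan), 6), paths["scan"])

  report <- structure(list(
    labels = lab, n = c(nrow(ph_a), nrow(ph_b)),
    k_variants = nrow(weights),
    prevalence = prevalence,
    characteristics = list(a = characteristics_summary(ph_a),
                           b = characteristics_summary(ph_b)),
    comparisons = comparisons,
    scan = scan_summary[setdiff(names(scan_summary), "dumbbell")],
    seed = config$seed, config_hash = config_hash,
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
    out_dir = out_dir, paths = paths), class = "run_report")
  # serialized summary carries only run-invariant fields (no timings or
  # absolute paths) so identical (config, seed) reruns are byte-identical
  ser <- unclass(report)
  ser$elapsed_s <- NULL
  ser$out_dir <- NULL
  ser$paths <- basename(unname(paths))
  jsonlite::write_json(prepare_json(ser), paths["summary"],
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  render_report(report, paths["report"])
  report
}

score_summary <- function(x) {
  list(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
       min = min(x), max = max(x), n = length(x))
}

characteristics_summary <- function(ph) {
  out <- list(n = nrow(ph))
  for (col in c("age", "bmi", "sbp", "tc", "hdl"))
    out[[col]] <- c(mean = mean(ph[[col]]), sd = stats::sd(ph[[col]]))
  for (col in c("smoker", "diabetic", "antihypertensive", "cad"))
    out[[paste0(col, "_pct")]] <- 100 * mean(ph[[col]])
  out$female_pct <- 100 * mean(ph$sex == "F")
  out
}

round_df <- function(df, digits) {
  for (col in names(df))
    if (is.double(df[[col]])) df[[col]] <- round(df[[col]], digits)
  df
}

prepare_json <- function(x) {
  if (inherits(x, "test_result")) return(unclass(x))
  if (is.list(x)) return(lapply(unclass(x), prepare_json))
  x
}

format_pvalue <- function(p) {
  ifelse(p < 0.001, "< 0.001", formatC(signif(p, 4), format = "fg", digits = 4))
}

#' Render a markdown report for a pipeline run
#'
#' Writes a human-readable report: per-population characteristics, score
#' summary tables (mean, SD, median, min, max and the between-population
#' p-value), and the allele-frequency scan summary. P-values are shown to 4
#' significant decimals, with values below 0.001 printed as "< 0.001".
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param path Output markdown path.
#' @return The path, invisibly.
#' @export
render_report <- function(report, path) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  lab <- report$labels
  add("# Two-population CAD risk comparison")
  add("")
  add("Populations: %s (n = %s) vs %s (n = %s); %d variants scored; seed %s; config %s.",
      lab[1], format(report$n[1], big.mark = ","),
      lab[2], format(report$n[2], big.mark = ","),
      report$k_variants, report$seed %||% "none", report$config_hash)
  add("")
  add("## CAD prevalence")
  add("")
  pv <- report$prevalence
  add("%s %.2f%%, %s %.2f%% (relative difference %.1f%%); Pearson chi-squared = %.2f, p %s.",
      lab[1], 100 * pv$prev_a, lab[2], 100 * pv$prev_b,
      pv$relative_difference_pct, pv$test$statistic,
      format_pvalue(pv$test$p_value))
  add("")
  add("## Population characteristics")
  add("")
  add("| Variable | %s | %s |", lab[1], lab[2])
  add("|---|---|---|")
  ca <- report$characteristics$a; cb <- report$characteristics$b
  for (col in c("age", "bmi", "sbp", "tc", "hdl"))
    add("| %s, mean (SD) | %.1f (%.1f) | %.1f (%.1f) |", col,
        ca[[col]]["mean"], ca[[col]]["sd"], cb[[col]]["mean"], cb[[col]]["sd"])
  for (col in c("female_pct", "smoker_pct", "diabetic_pct",
                "antihypertensive_pct", "cad_pct"))
    add("| %s | %.1f%% | %.1f%% |", sub("_pct", " %", col), ca[[col]], cb[[col]])
  add("")
  add("## Risk scores")
  add("")
  add("| Score | Population | Mean | SD | Median | Min | Max | p |")
  add("|---|---|---|---|---|---|---|---|")
  for (nm in names(report$comparisons)) {
    cmp <- report$comparisons[[nm]]
    test <- cmp$welch %||% cmp$mannwhitney
    add("| %s | %s | %.3f | %.3f | %.3f | %.3f | %.3f | %s |", nm, lab[1],
        cmp$summary_a$mean, cmp$summary_a$sd, cmp$summary_a$median,
        cmp$summary_a$min, cmp$summary_a$max, format_pvalue(test$p_value))
    add("| %s | %s | %.3f | %.3f | %.3f | %.3f | %.3f | KS %s |", nm, lab[2],
        cmp$summary_b$mean, cmp$summary_b$sd, cmp$summary_b$median,
        cmp$summary_b$min, cmp$summary_b$max, format_pvalue(cmp$ks$p_value))
  }
  add("")
  add("## Risk-allele-frequency scan")
  add("")
  sc <- report$scan
  if (sc$m == 0 || (sc$n_higher_a + sc$n_higher_b + sc$n_nonsignificant) == 0) {
    add("No variants tested.")
  } else {
    add(paste0("Of %d variants, %d had a significantly higher risk-allele ",
               "frequency in %s and %d in %s (Bonferroni-adjusted p < %s); ",
               "%d showed no significant difference."),
        sc$m, sc$n_higher_a, lab[1], sc$n_higher_b, lab[2],
        format(sc$alpha_adj), sc$n_nonsignificant)
    if (sc$n_higher_a + sc$n_higher_b > 0)
      add(paste0("Absolute frequency differences among significant variants ",
                 "ranged from %.1f to %.1f percentage points. The underlying ",
                 "dumbbell table is in af_scan.tsv."),
          100 * sc$min_abs_diff, 100 * sc$max_abs_diff)
  }
  add("")
  writeLines(ln, path)
  invisible(path)
}
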