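#' Built-in population phenotype profiles
#'
#' Returns the parameter set the phenotype simulator draws from: means and
#' SDs for the continuous covariates, Bernoulli rates for the binary ones,
#' truncation bounds, and the CAD prevalence calibration target.
#'
#' The `"england"` and `"scotland"` profiles reproduce the published UK
#' Biobank country-of-birth summary table verbatim, including its lipid
#' values as printed (labelled mg/dL there, though implausible for that
#' unit); `"england_mmol"`/`"scotland_mmol"` substitute realistic mmol/L
#' lipid distributions for users who want physiologic lipids.
#'
#' @param name One of `"england"`, `"scotland"`, `"england_mmol"`,
#'   `"scotland_mmol"`.
#' @return A list with elements `label`, `means`, `sds`, `rates`, `bounds`,
#'   `cad_prevalence`, `n_full`.
#' @export
population_profile <- function(name = c("england", "scotland",
                                        "england_mmol", "scotland_mmol")) {
  name <- match.arg(name)
  bounds <- list(age = c(40, 70), bmi = c(14, 60), sbp = c(70, 250),
                 tc = c(40, 250), hdl = c(5, 120))
  base <- switch(sub("_mmol$", "", name),
    england = list(
      label = "England",
      means = c(age = 56.7, bmi = 27.4, sbp = 138.0, tc = 102.8, hdl = 26.2),
      sds   = c(age = 8.1,  bmi = 4.7,  sbp = 18.5,  tc = 20.6,  hdl = 6.9),
      rates = c(female = 169679 / 317889, smoker = 32484 / 317889,
                diabetic = 24646 / 317889, antihypertensive = 72816 / 317889),
      cad_prevalence = 0.0768, n_full = 317889L),
    scotland = list(
      label = "Scotland",
      means = c(age = 56.6, bmi = 27.49, sbp = 139.0, tc = 103.1, hdl = 26.1),
      sds   = c(age = 8.0,  bmi = 4.7,   sbp = 18.9,  tc = 20.7,  hdl = 6.9),
      rates = c(female = 17411 / 31963, smoker = 4078 / 31963,
                diabetic = 1918 / 31963, antihypertensive = 7577 / 31963),
      cad_prevalence = 0.0898, n_full = 31963L))
  if (grepl("_mmol$", name)) {
    # realistic UK adult lipids in mmol/L; tiny country offsets kept
    base$means["tc"] <- if (base$label == "England") 5.90 else 5.92
    base$means["hdl"] <- if (base$label == "England") 1.45 else 1.44
    base$sds["tc"] <- 1.10; base$sds["hdl"] <- 0.38
    bounds$tc <- c(1.5, 15); bounds$hdl <- c(0.3, 5)
  }
  base$bounds <- bounds
  base
}

#' Plant per-population risk-allele frequencies
#'
#' Builds a two-population frequency table with a chosen number of variants
#' whose risk-allele frequency (RAF) is higher in population A, higher in
#' population B, or identical (null). Baseline frequencies are uniform on
#' `base_freq_range`; a planted variant's RAF in population B is offset by
#' `delta` downwards (direction `higher_A`) or upwards (`higher_B`).
#'
#' @param n_variants Total number of variants.
#' @param n_higher_a,n_higher_b How many variants get a higher RAF in
#'   population A / population B.
#' @param delta Absolute frequency offset (e.g. 0.02 = 2 percentage points).
#' @param base_freq_range Range for the baseline RAF draw; must keep all
#'   offset frequencies strictly inside (0, 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `data.frame` of class `population_freqs` with columns
#'   `variant_id`, `raf_a`, `raf_b`, `direction` (factor
#'   `higher_A`/`higher_B`/`null`).
#' @export
make_frequency_table <- function(n_variants, n_higher_a, n_higher_b, delta,
                                 base_freq_range = c(0.1, 0.9), seed = NULL) {
  if (n_higher_a + n_higher_b > n_variants)
    abort_popgrs("n_higher_a + n_higher_b exceeds n_variants", "popgrs_validation_error")
  if (delta < 0) abort_popgrs("delta must be >= 0", "popgrs_validation_error")
  with_seed(seed, {
    base <- runif(n_variants, base_freq_range[1], base_freq_range[2])
    direction <- rep("null", n_variants)
    planted <- sample.int(n_variants, n_higher_a + n_higher_b)
    direction[planted[seq_len(n_higher_a)]] <- "higher_A"
    if (n_higher_b > 0)
      direction[planted[n_higher_a + seq_len(n_higher_b)]] <- "higher_B"
    if (delta == 0) direction <- rep("null", n_variants)
    raf_a <- base
    raf_b <- base
    raf_b[direction == "higher_A"] <- base[direction == "higher_A"] - delta
    raf_b[direction == "higher_B"] <- base[direction == "higher_B"] + delta
    bad <- which(raf_a <= 0 | raf_a >= 1 | raf_b <= 0 | raf_b >= 1)
    if (length(bad))
      abort_popgrs(sprintf("delta pushes frequency outside (0,1) at variant %d", bad[1]),
                   "popgrs_validation_error")
    out <- data.frame(variant_id = sprintf("rs%06d", seq_len(n_variants)),
                      raf_a = raf_a, raf_b = raf_b,
                      direction = factor(direction,
                                         levels = c("higher_A", "higher_B", "null")),
                      stringsAsFactors = FALSE)
    class(out) <- c("population_freqs", "data.frame")
    out
  })
}

#' Generate a synthetic risk-variant weight table
#'
#' Assigns each variant a chromosome, position, distinct risk/other alleles
#' and a per-allele odds ratio drawn uniformly from `or_range` (defaulting to
#' the >1.03 range typical of genome-wide significant CAD lead SNPs).
#'
#' @param n_variants Number of variants (rsids `rs000001`...).
#' @param or_range Odds-ratio range.
#' @param seed Integer seed.
#' @return A `variant_weights` table.
#' @export
simulate_weights <- function(n_variants, or_range = c(1.03, 1.30), seed = NULL) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    risk <- sample(bases, n_variants, replace = TRUE)
    other <- vapply(risk, function(b) sample(setdiff(bases, b), 1), character(1))
    df <- data.frame(
      rsid = sprintf("rs%06d", seq_len(n_variants)),
      chrom = as.character(sample(1:22, n_variants, replace = TRUE)),
      pos = sort(sample.int(2.4e8, n_variants)),
      risk_allele = risk, other_allele = unname(other),
      odds_ratio = round(runif(n_variants, or_range[1], or_range[2]), 4),
      stringsAsFactors = FALSE)
    df$log_or <- log(df$odds_ratio)
    class(df) <- c("variant_weights", "data.frame")
    df
  })
}

#' Simulate Hardy-Weinberg genotypes for two populations
#'
#' Draws risk-allele dosages independently per variant under Hardy-Weinberg
#' equilibrium: at RAF `p`, dosage 2 with probability `p^2`, 1 with `2p(1-p)`,
#' 0 with `(1-p)^2` (a Binomial(2, p) draw). Entries are then masked missing
#' independently at `missing_rate`.
#'
#' @param freqs A [make_frequency_table()] result.
#' @param n_a,n_b Samples per population.
#' @param missing_rate Per-entry missingness probability in \[0, 1).
#' @param seed Integer seed.
#' @param sample_prefix Two-element character vector of id prefixes.
#' @return `list(a = genotype_matrix, b = genotype_matrix)`.
#' @export
simulate_genotypes <- function(freqs, n_a, n_b, missing_rate = 0, seed = NULL,
                               sample_prefix = c("A", "B")) {
  if (missing_rate < 0 || missing_rate >= 1)
    abort_popgrs("missing_rate must be in [0, 1)", "popgrs_validation_error")
  with_seed(seed, {
    draw <- function(n, p, prefix) {
      k <- length(p)
      m <- matrix(rbinom(n * k, 2L, rep(p, each = n)), nrow = n, ncol = k)
      if (missing_rate > 0)
        m[runif(n * k) < missing_rate] <- NA_integer_
      genotype_matrix(m, sample_ids = sprintf("%s%06d", prefix, seq_len(n)),
                      variant_ids = freqs$variant_id)
    }
    list(a = draw(n_a, freqs$raf_a, sample_prefix[1]),
         b = draw(n_b, freqs$raf_b, sample_prefix[2]))
  })
}

#' Simulate clinical phenotypes for one population
#'
#' Continuous covariates (age, BMI, SBP, TC, HDL) are drawn from normal
#' distributions truncated at the physiologic bounds declared in the
#' profile. Because asymmetric truncation shifts the mean (age truncated at
#' 40-70 would otherwise come out about half a year low), the underlying
#' location parameter is solved so the *truncated* mean equals the profile
#' mean. Binary covariates are Bernoulli at the profile rates. Values are
#' rounded to measurement precision (1 decimal for age/sbp, 2 for the rest)
#' so that tables round-trip exactly through TSV.
#'
#' @param n Number of participants.
#' @param profile A [population_profile()] list (or custom list with the
#'   same shape).
#' @param seed Integer seed.
#' @param id_prefix Sample id prefix.
#' @return A phenotype `data.frame` (without the `cad` column, which
#'   [simulate_disease()] adds).
#' @export
simulate_phenotypes <- function(n, profile, seed = NULL, id_prefix = "S") {
  if (any(profile$rates < 0 | profile$rates > 1))
    abort_popgrs("profile rates must lie in [0, 1]", "popgrs_validation_error")
  with_seed(seed, {
    trunc_mean <- function(mu, sd, lo, hi) {
      a <- (lo - mu) / sd; b <- (hi - mu) / sd
      mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
    }
    rtruncnorm <- function(n, target_mean, sd, lo, hi) {
      if (sd == 0) return(rep(target_mean, n))
      # solve the location so the truncated mean hits the target
      mu <- stats::uniroot(function(m) trunc_mean(m, sd, lo, hi) - target_mean,
                           interval = c(lo, hi), extendInt = "upX")$root
      u <- runif(n, pnorm(lo, mu, sd), pnorm(hi, mu, sd))
      qnorm(u, mu, sd)
    }
    cont <- lapply(names(profile$means), function(v)
      rtruncnorm(n, profile$means[[v]], profile$sds[[v]],
                 profile$bounds[[v]][1], profile$bounds[[v]][2]))
    names(cont) <- names(profile$means)
    data.frame(
      sample_id = sprintf("%s%06d", id_prefix, seq_len(n)),
      population = profile$label,
      sex = ifelse(runif(n) < profile$rates[["female"]], "F", "M"),
      age = round(cont$age, 1), bmi = round(cont$bmi, 2),
      sbp = round(cont$sbp, 1), tc = round(cont$tc, 2), hdl = round(cont$hdl, 2),
      smoker = runif(n) < profile$rates[["smoker"]],
      diabetic = runif(n) < profile$rates[["diabetic"]],
      antihypertensive = runif(n) < profile$rates[["antihypertensive"]],
      stringsAsFactors = FALSE)
  })
}

#' Define the logistic disease (liability) model
#'
#' CAD status is generated as `Bernoulli(plogis(alpha + beta_grs * (wGRS -
#' mean(wGRS)) + sum(betas_clinical * covariate)))`. When
#' `target_prevalence` is set the intercept is found by bisection so the
#' *expected* prevalence (mean fitted probability) matches the target.
#'
#' @param intercept Intercept `alpha`, or `NULL` to calibrate.
#' @param beta_grs Log-odds effect per unit of wGRS (centered).
#' @param betas_clinical Named numeric vector/list of effects on phenotype
#'   columns (logical columns enter as 0/1, continuous columns are centered
#'   at their sample mean).
#' @param target_prevalence Calibration target in (0, 1), or `NULL`.
#' @return A list of class `disease_model`.
#' @export
disease_model <- function(intercept = NULL, beta_grs = 0, betas_clinical = NULL,
                          target_prevalence = NULL) {
  if (is.null(intercept) && is.null(target_prevalence))
    abort_popgrs("supply either intercept or target_prevalence", "popgrs_validation_error")
  if (!is.null(target_prevalence) &&
      (target_prevalence <= 0 || target_prevalence >= 1))
    abort_popgrs("target_prevalence must be in (0, 1)", "popgrs_validation_error")
  structure(list(intercept = intercept, beta_grs = beta_grs,
                 betas_clinical = unlist(betas_clinical),
                 target_prevalence = target_prevalence),
            class = "disease_model")
}

#' Simulate CAD status from scores and phenotypes
#'
#' @param wgrs Per-sample weighted genetic risk score (same order as
#'   `phenotypes`).
#' @param phenotypes Phenotype `data.frame`.
#' @param model A [disease_model()].
#' @param seed Integer seed.
#' @return Logical CAD vector, with attributes `intercept` (the value used,
#'   after any calibration) and `expected_prevalence`.
#' @export
simulate_disease <- function(wgrs, phenotypes, model, seed = NULL) {
  stopifnot(inherits(model, "disease_model"),
            length(wgrs) == nrow(phenotypes))
  lp0 <- model$beta_grs * (wgrs - mean(wgrs))
  for (v in names(model$betas_clinical)) {
    if (!v %in% names(phenotypes))
      abort_popgrs(sprintf("disease model references unknown covariate '%s'", v),
                   "popgrs_validation_error")
    x <- phenotypes[[v]]
    x <- if (is.logical(x)) as.numeric(x) else x - mean(x)
    lp0 <- lp0 + model$betas_clinical[[v]] * x
  }
  alpha <- model$intercept
  if (!is.null(model$target_prevalence)) {
    f <- function(a) mean(plogis(a + lp0)) - model$target_prevalence
    lo <- -40; hi <- 40
    if (f(lo) > 0 || f(hi) < 0)
      abort_popgrs("intercept bisection not bracketed; widen bounds", "popgrs_validation_error")
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
      if (abs(f(mid)) < 1e-10) break
    }
    alpha <- (lo + hi) / 2
  }
  p <- plogis(alpha + lp0)
  cad <- with_seed(seed, runif(length(p)) < p)
  attr(cad, "intercept") <- alpha
  attr(cad, "expected_prevalence") <- mean(p)
  cad
}

#' Generate a complete two-population synthetic cohort
#'
#' Convenience wrapper tying the generators together: weight table, planted
#' frequency table, Hardy-Weinberg genotypes, phenotypes from the two
#' country profiles, weighted genetic risk scores, and calibrated CAD
#' status. Defaults reproduce the study conditions at desk scale: 163
#' variants, 37 planted higher in population A (England) and 35 in
#' population B (Scotland) at a 2-percentage-point offset, prevalence
#' targets 7.68% / 8.98%.
#'
#' @param n_a,n_b Samples per population (defaults 30,000 / 3,000;
#'   `full_scale = TRUE` switches to 317,889 / 31,963).
#' @param n_variants,n_higher_a,n_higher_b,delta Frequency-table design.
#' @param missing_rate Genotype missingness rate.
#' @param profiles List of two [population_profile()]s.
#' @param model A [disease_model()] template; its `target_prevalence` is
#'   overridden per population by the profile target.
#' @param full_scale Use the full published sample sizes.
#' @param seed Master integer seed; all stages derive their own streams.
#' @return A list of class `synthetic_cohort` with elements `weights`,
#'   `freqs`, `genotypes` (list a/b), `phenotypes` (single data.frame with
#'   `cad`), `scores`, `seed`.
#' @export
simulate_cohort <- function(n_a = 30000, n_b = 3000, n_variants = 163,
                            n_higher_a = 37, n_higher_b = 35, delta = 0.02,
                            missing_rate = 0.002,
                            profiles = list(a = population_profile("england"),
                                            b = population_profile("scotland")),
                            model = disease_model(beta_grs = 0.3,
                                                  betas_clinical = c(age = 0.05,
                                                                     sbp = 0.01,
                                                                     smoker = 0.7,
                                                                     diabetic = 0.9,
                                                                     antihypertensive = 0.4),
                                                  target_prevalence = 0.08),
                            full_scale = FALSE, seed = 1L) {
  if (full_scale) {
    n_a <- profiles$a$n_full
    n_b <- profiles$b$n_full
  }
  weights <- simulate_weights(n_variants, seed = derive_seed(seed, 1))
  freqs <- make_frequency_table(n_variants, n_higher_a, n_higher_b, delta,
                                seed = derive_seed(seed, 2))
  freqs$variant_id <- weights$rsid
  geno <- simulate_genotypes(freqs, n_a, n_b, missing_rate,
                             seed = derive_seed(seed, 3))
  ph_a <- simulate_phenotypes(n_a, profiles$a, seed = derive_seed(seed, 4),
                              id_prefix = "A")
  ph_b <- simulate_phenotypes(n_b, profiles$b, seed = derive_seed(seed, 5),
                              id_prefix = "B")

  score_pop <- function(gm) {
    rafs <- compute_raf(gm)
    compute_scores(impute_missing(gm, rafs), weights)
  }
  sc_a <- score_pop(geno$a)
  sc_b <- score_pop(geno$b)

  disease_pop <- function(sc, ph, target, off) {
    m <- model
    m$target_prevalence <- target
    simulate_disease(sc$wgrs, ph, m, seed = derive_seed(seed, off))
  }
  ph_a$cad <- as.logical(disease_pop(sc_a, ph_a, profiles$a$cad_prevalence, 6))
  ph_b$cad <- as.logical(disease_pop(sc_b, ph_b, profiles$b$cad_prevalence, 7))

  structure(list(weights = weights, freqs = freqs, genotypes = geno,
                 phenotypes = rbind(ph_a, ph_b),
                 scores = rbind(cbind(sc_a, population = profiles$a$label,
                                      stringsAsFactors = FALSE),
                                cbind(sc_b, population = profiles$b$label,
                                      stringsAsFactors = FALSE)),
                 seed = seed),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the external representation of a cohort: a plain-text VCF per
#' population, a phenotype TSV, the weight TSV, and a ground-truth TSV
#' (planted RAFs and directions). All files are labelled synthetic.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf_a = file.path(dir, "synthetic_pop_a.vcf"),
    vcf_b = file.path(dir, "synthetic_pop_b.vcf"),
    phenotypes = file.path(dir, "synthetic_phenotypes.tsv"),
    weights = file.path(dir, "synthetic_weights.tsv"),
    truth = file.path(dir, "synthetic_ground_truth.tsv"))
  write_vcf_genotypes(cohort$genotypes$a, cohort$weights, paths["vcf_a"])
  write_vcf_genotypes(cohort$genotypes$b, cohort$weights, paths["vcf_b"])
  write_phenotype_table(cohort$phenotypes, paths["phenotypes"])
  write_weights_table(cohort$weights, paths["weights"])
  truth <- as.data.frame(cohort$freqs)
  write_results_table(truth, paths["truth"])
  invisible(paths)
}
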