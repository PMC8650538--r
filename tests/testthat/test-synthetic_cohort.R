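test_that("frequency tables plant the requested direction structure", {
  ft <- make_frequency_table(163, 37, 35, 0.02, seed = 101)
  expect_identical(as.vector(table(ft$direction)), c(37L, 35L, 91L))
  expect_true(all(ft$raf_a > 0 & ft$raf_a < 1 & ft$raf_b > 0 & ft$raf_b < 1))
  # planted direction always matches the sign of raf_a - raf_b
  expect_true(all(sign(ft$raf_a - ft$raf_b) ==
                    c(higher_A = 1, higher_B = -1, null = 0)[as.character(ft$direction)]))

  # zero offset: everything null
  ft0 <- make_frequency_table(20, 5, 5, 0, seed = 101)
  expect_true(all(ft0$direction == "null"))

  # the largest absolute difference equals the planted offset exactly
  ft3 <- make_frequency_table(10, 5, 5, 0.033, seed = 7)
  expect_equal(max(abs(ft3$raf_a - ft3$raf_b)), 0.033)

  # infeasible offset names a variant
  expect_error(make_frequency_table(10, 5, 5, 0.5, base_freq_range = c(0.6, 0.9),
                                    seed = 1), "outside \\(0,1\\)")
  expect_error(make_frequency_table(10, 6, 5, 0.02), "exceeds n_variants")

  # bit-for-bit reproducibility from the seed
  expect_identical(make_frequency_table(50, 10, 10, 0.02, seed = 5),
                   make_frequency_table(50, 10, 10, 0.02, seed = 5))
})

test_that("genotype simulation follows Hardy-Weinberg proportions", {
  # degenerate frequency: every non-missing dosage is homozygous risk
  fixed <- data.frame(variant_id = "v1", raf_a = 1, raf_b = 1,
                      direction = "null")
  class(fixed) <- c("population_freqs", "data.frame")
  g <- simulate_genotypes(fixed, 50, 10, missing_rate = 0.2, seed = 2)
  expect_true(all(g$a[!is.na(g$a)] == 2L))

  # empirical RAF within binomial tolerance of the planted value
  half <- data.frame(variant_id = "v1", raf_a = 0.5, raf_b = 0.5,
                     direction = "null")
  class(half) <- c("population_freqs", "data.frame")
  g2 <- simulate_genotypes(half, 10000, 10, seed = 3)
  expect_lt(abs(compute_raf(g2$a, "v1") - 0.5), 3 * sqrt(0.25 / 20000))

  # genotype class proportions pass a Hardy-Weinberg goodness-of-fit test
  p <- 0.3
  hw <- data.frame(variant_id = "v1", raf_a = p, raf_b = p, direction = "null")
  class(hw) <- c("population_freqs", "data.frame")
  g3 <- simulate_genotypes(hw, 50000, 10, seed = 4)$a
  obs <- tabulate(g3[, 1] + 1L, 3)
  gof <- chisq.test(obs, p = c((1 - p)^2, 2 * p * (1 - p), p^2))
  expect_gt(gof$p.value, 0.001)

  # missingness is honoured and reproducible
  g4 <- simulate_genotypes(half, 5000, 10, missing_rate = 0.1, seed = 9)
  expect_equal(mean(is.na(g4$a)), 0.1, tolerance = 0.05)
  g5 <- simulate_genotypes(half, 5000, 10, missing_rate = 0.1, seed = 9)
  expect_identical(unclass(g4$a), unclass(g5$a))
  expect_error(simulate_genotypes(half, 10, 10, missing_rate = 1), "missing_rate")
})

test_that("phenotype simulation matches the population profile marginals", {
  prof <- population_profile("england")
  ph <- simulate_phenotypes(100000, prof, seed = 21)
  expect_lt(abs(mean(ph$age) - 56.7), 0.1)
  expect_lt(abs(mean(ph$smoker) - 0.102), 0.005)
  expect_lt(abs(mean(ph$sex == "F") - 0.534), 0.006)
  expect_true(all(ph$age >= 40 & ph$age <= 70))
  expect_true(all(ph$sbp >= 70 & ph$sbp <= 250))

  prof_s <- population_profile("scotland")
  ph_s <- simulate_phenotypes(100000, prof_s, seed = 22)
  expect_lt(abs(mean(ph_s$smoker) - 0.128), 0.005)
  expect_lt(abs(mean(ph_s$sbp) - 139.0), 0.3)

  # zero spread collapses to the mean
  prof0 <- prof
  prof0$sds[] <- 0
  ph0 <- simulate_phenotypes(50, prof0, seed = 1)
  expect_true(all(ph0$age == 56.7))
  expect_true(all(ph0$sbp == 138.0))

  bad <- prof
  bad$rates["smoker"] <- 1.2
  expect_error(simulate_phenotypes(10, bad, seed = 1), "rates")
})

test_that("disease simulation calibrates to the target prevalence", {
  n <- 50000
  wgrs <- rnorm(n, 10.6, 0.5)
  ph <- simulate_phenotypes(n, population_profile("england"), seed = 31)

  m0 <- disease_model(beta_grs = 0, target_prevalence = 0.0768)
  cad <- simulate_disease(wgrs, ph, m0, seed = 32)
  expect_lt(abs(attr(cad, "expected_prevalence") - 0.0768), 1e-4)
  expect_lt(abs(mean(cad) - 0.0768), 3 * sqrt(0.0768 * 0.9232 / n))

  # symmetric null model: prevalence one half
  m50 <- disease_model(intercept = 0, beta_grs = 0)
  cad50 <- simulate_disease(wgrs, ph, m50, seed = 33)
  expect_lt(abs(mean(cad50) - 0.5), 3 * sqrt(0.25 / n))

  # a positive genetic effect separates case and control score means
  m1 <- disease_model(beta_grs = 1.5, target_prevalence = 0.08)
  cad1 <- simulate_disease(wgrs, ph, m1, seed = 34)
  expect_gt(mean(wgrs[cad1]), mean(wgrs[!cad1]))

  expect_error(disease_model(), "intercept or target_prevalence")
  expect_error(disease_model(target_prevalence = 1.5), "target_prevalence")
  expect_error(
    simulate_disease(wgrs, ph, disease_model(beta_grs = 0,
                                             betas_clinical = c(nope = 1),
                                             target_prevalence = 0.1), seed = 1),
    "unknown covariate")
})

test_that("a logistic fit recovers the generating wGRS effect", {
  # parameter recovery across seeded replicates: the fitted beta_grs lies
  # within 3 standard errors of the truth in (at least) 19 of 20 runs
  n <- 50000
  beta_true <- 0.8
  hits <- 0L
  for (r in 1:20) {
    wgrs <- with(list(s = 400 + r), {set.seed(s); rnorm(n, 10.6, 0.5)})
    ph <- simulate_phenotypes(n, population_profile("england"), seed = 500 + r)
    m <- disease_model(beta_grs = beta_true,
                       betas_clinical = c(smoker = 0.7, diabetic = 0.9),
                       target_prevalence = 0.08)
    cad <- simulate_disease(wgrs, ph, m, seed = 600 + r)
    fit <- glm(cad ~ I(wgrs - mean(wgrs)) + smoker + diabetic,
               family = binomial(),
               data = data.frame(cad = as.logical(cad), wgrs = wgrs,
                                 smoker = ph$smoker, diabetic = ph$diabetic))
    est <- summary(fit)$coefficients[2, ]
    if (abs(est["Estimate"] - beta_true) < 3 * est["Std. Error"]) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("full cohorts are reproducible and internally consistent", {
  co <- simulate_cohort(n_a = 2000, n_b = 500, n_variants = 30,
                        n_higher_a = 6, n_higher_b = 5, seed = 77)
  co2 <- simulate_cohort(n_a = 2000, n_b = 500, n_variants = 30,
                         n_higher_a = 6, n_higher_b = 5, seed = 77)
  expect_identical(co$phenotypes, co2$phenotypes)
  expect_identical(unclass(co$genotypes$a), unclass(co2$genotypes$a))
  expect_identical(co$scores, co2$scores)

  expect_identical(nrow(co$phenotypes), 2500L)
  expect_identical(co$phenotypes$sample_id[co$phenotypes$population == "England"],
                   rownames(co$genotypes$a))

  paths <- write_cohort(co, tempfile("cohort"))
  expect_true(all(file.exists(paths)))
  w_back <- read_weights_table(paths["weights"])
  expect_equal(w_back$odds_ratio, co$weights$odds_ratio)
  ph_back <- read_phenotype_table(paths["phenotypes"])
  expect_equal(ph_back$cad, co$phenotypes$cad)
})
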