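test_that("the 2x2 chi-squared matches its reference behaviours", {
  # identical column proportions: statistic exactly 0, p exactly 1
  r <- chi2_two_by_two(matrix(c(10, 90, 30, 270), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # the uncorrected Pearson statistic equals the squared pooled-z statistic
  set.seed(7)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 50) + 1, 2)
    r <- chi2_two_by_two(tab)
    n1 <- sum(tab[, 1]); n2 <- sum(tab[, 2])
    p1 <- tab[1, 1] / n1; p2 <- tab[1, 2] / n2
    pp <- sum(tab[1, ]) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(r$statistic, z^2, tolerance = 1e-10)
  }

  # agreement with the exhaustive permutation oracle at adequate counts
  tab <- matrix(c(300, 700, 330, 670), 2)
  expect_lt(abs(chi2_two_by_two(tab)$p_value - exact_perm_p(tab)), 0.02)
  # small-sample caveat: at n = 20 the lattice discreteness dominates and
  # the asymptotic p (0.361) sits far from the exact permutation p
  expect_equal(exact_perm_p(matrix(c(3, 7, 5, 5), 2)), 0.6499166,
               tolerance = 1e-6)

  expect_error(chi2_two_by_two(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_error(chi2_two_by_two(matrix(1:6, 3)), "2x2")
})

test_that("two-sample tests behave at the null and under large effects", {
  x <- rep(c(1.2, 3.4, 5.6), 4)
  expect_equal(welch_ttest(x, x)$statistic, 0)
  expect_equal(welch_ttest(x, x)$p_value, 1)
  expect_equal(ks_two_sample(x, x)$statistic, 0)

  set.seed(11)
  a <- rnorm(5000); b <- rnorm(5000, 0.5)
  expect_lt(welch_ttest(a, b)$p_value, 1e-6)
  expect_lt(mannwhitney(a, b)$p_value, 1e-6)
  expect_lt(ks_two_sample(a, b)$p_value, 1e-6)

  # degenerate input: a full tie is a warning with p = 1, not a crash
  expect_warning(r <- mannwhitney(rep(1, 5), rep(1, 7)), "tied")
  expect_equal(r$p_value, 1)

  expect_error(welch_ttest(1, 1:3), "observations")
  expect_warning(ks_two_sample(1:5, 1:20), "n < 8")
})

test_that("null Welch p-values are uniform", {
  set.seed(21)
  pvals <- replicate(1000, welch_ttest(rnorm(25), rnorm(25))$p_value)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("the allele-frequency scan flags planted differences correctly", {
  # identical populations: zero significant rows, all diffs zero
  ft <- make_frequency_table(30, 0, 0, 0, seed = 51)
  g <- simulate_genotypes(ft, 500, 500, seed = 52)
  self <- af_scan(g$a, genotype_matrix(unclass(g$a),
                                       sample_ids = paste0("b", 1:500)),
                  alpha_adj = 0.05)
  expect_true(all(self$diff == 0))
  expect_true(all(!self$significant))

  # planted differences at desk scale with a large offset are recovered
  ft2 <- make_frequency_table(40, 8, 6, 0.15, base_freq_range = c(0.25, 0.75),
                              seed = 53)
  g2 <- simulate_genotypes(ft2, 4000, 4000, seed = 54)
  scan <- af_scan(g2$a, g2$b, alpha_adj = 0.001)
  smry <- summarize_scan(scan)
  expect_identical(smry$n_higher_a, 8L)
  expect_identical(smry$n_higher_b, 6L)
  expect_identical(smry$n_nonsignificant, 26L)

  # direction labels are antisymmetric under population swap
  rev_scan <- af_scan(g2$b, g2$a, alpha_adj = 0.001)
  flip <- c(higher_A = "higher_B", higher_B = "higher_A", none = "none")
  expect_identical(unname(flip[scan$direction]), rev_scan$direction)

  # Bonferroni bookkeeping
  expect_true(all(scan$p_adj >= scan$p_raw))
  expect_true(all(scan$p_adj <= 1 & scan$p_raw >= 0 & scan$p_raw <= 1))
  expect_equal(scan$p_adj, pmin(1, attr(scan, "m") * scan$p_raw))
  expect_true(all(scan$direction[scan$significant] != "none"))
})

test_that("scan rows agree with the scalar chi-squared on the same table", {
  ft <- make_frequency_table(25, 5, 5, 0.1, seed = 61)
  g <- simulate_genotypes(ft, 800, 600, missing_rate = 0.05, seed = 62)
  scan <- af_scan(g$a, g$b)
  for (k in seq_len(nrow(scan))) {
    na <- sum(!is.na(g$a[, k])); nb <- sum(!is.na(g$b[, k]))
    ra <- sum(g$a[, k], na.rm = TRUE); rb <- sum(g$b[, k], na.rm = TRUE)
    tab <- matrix(c(ra, 2 * na - ra, rb, 2 * nb - rb), 2)
    ref <- chi2_two_by_two(tab)
    expect_equal(scan$chi2[k], ref$statistic, tolerance = 1e-10)
    expect_equal(scan$p_raw[k], ref$p_value, tolerance = 1e-12)
  }
})

test_that("monomorphic variants are reported, not dropped", {
  a <- genotype_matrix(matrix(0L, 10, 2), paste0("a", 1:10), c("v1", "v2"))
  b <- genotype_matrix(matrix(c(rep(0L, 10), sample(0:2, 10, TRUE)), 10, 2),
                       paste0("b", 1:10), c("v1", "v2"))
  scan <- af_scan(a, b)
  expect_equal(scan$p_raw[1], 1)
  expect_equal(scan$chi2[1], 0)
  expect_identical(scan$direction[1], "none")
  expect_false(scan$significant[1])

  expect_error(af_scan(a, b[, 1, drop = FALSE]), "different variant sets")
})

test_that("scan summaries count directions and difference ranges exactly", {
  rows <- data.frame(rsid = c("r1", "r2", "r3"),
                     raf_a = c(0.50, 0.30, 0.20),
                     raf_b = c(0.45, 0.33, 0.20),
                     diff = c(0.05, -0.03, 0),
                     chi2 = c(20, 15, 0),
                     p_raw = c(1e-6, 1e-5, 1),
                     p_adj = c(3e-6, 3e-5, 1),
                     direction = c("higher_A", "higher_B", "none"),
                     significant = c(TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  attr(rows, "m") <- 3L; attr(rows, "alpha_adj") <- 0.001
  class(rows) <- c("af_scan", "data.frame")
  smry <- summarize_scan(rows)
  expect_identical(smry$n_higher_a, 1L)
  expect_identical(smry$n_higher_b, 1L)
  expect_identical(smry$n_nonsignificant, 1L)
  expect_equal(smry$min_abs_diff, 0.03)
  expect_equal(smry$max_abs_diff, 0.05)
  expect_identical(smry$dumbbell$rsid, c("r2", "r3", "r1"))

  # an all-null scan yields (0, 0, m)
  null_rows <- rows
  null_rows$significant <- FALSE
  smry0 <- summarize_scan(null_rows)
  expect_identical(c(smry0$n_higher_a, smry0$n_higher_b, smry0$n_nonsignificant),
                   c(0L, 0L, 3L))
  expect_true(is.na(smry0$max_abs_diff))

  p <- plot_dumbbell(rows, labels = c("England", "Scotland"))
  expect_s3_class(p, "ggplot")
})
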