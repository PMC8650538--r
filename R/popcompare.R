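new_test_result <- function(method, statistic, df, p_value, n_a, n_b) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 n_a = n_a, n_b = n_b),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.4g (n_a = %d, n_b = %d)\n",
              x$method, x$statistic,
              if (is.na(x$df)) "n/a" else format(x$df, digits = 5),
              x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Pearson's statistic without continuity correction (df = 1), the test used
#' for prevalence and allele-frequency contrasts between two populations.
#' Columns are the two populations, rows the two outcome classes.
#'
#' @param counts 2x2 matrix of non-negative integer counts; all row and
#'   column totals must be positive.
#' @param correct Apply the Yates continuity correction (default off; at
#'   biobank sample sizes it is negligible, and the uncorrected statistic
#'   equals the squared pooled two-proportion z).
#' @return A `test_result` with `method = "chi2"`.
#' @export
chi2_two_by_two <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0))
    abort_popgrs("counts must be a non-negative 2x2 table", "popgrs_validation_error")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    abort_popgrs("chi-squared undefined: a marginal total is zero", "popgrs_validation_error")
  if (all(abs(counts[1, ] / colSums(counts) - counts[1, 1] / sum(counts[, 1])) < 1e-15)) {
    # identical column proportions: statistic exactly 0
    return(new_test_result("chi2", 0, 1, 1, sum(counts[, 1]), sum(counts[, 2])))
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  new_test_result("chi2", ht$statistic, ht$parameter, ht$p.value,
                  sum(counts[, 1]), sum(counts[, 2]))
}

#' Two-sample location and distribution tests
#'
#' `welch_ttest` compares means with the unequal-variance (Welch) t test;
#' `mannwhitney` compares skewed scores with the two-sided Mann-Whitney U
#' test (normal approximation with tie correction); `ks_two_sample`
#' compares whole distributions with the two-sample Kolmogorov-Smirnov test
#' (asymptotic p).
#'
#' @param x,y Numeric samples (each of size >= 2; the KS asymptotic p-value
#'   is unreliable below 8 per side and triggers a warning).
#' @param correct Continuity correction for the Mann-Whitney normal
#'   approximation (default off: plain normal approximation).
#' @return A `test_result`.
#' @export
welch_ttest <- function(x, y) {
  check_two_sample(x, y)
  ht <- stats::t.test(x, y, var.equal = FALSE)
  new_test_result("welch_t", ht$statistic, ht$parameter, ht$p.value,
                  length(x), length(y))
}

check_two_sample <- function(x, y, min_n = 2) {
  if (length(x) < min_n || length(y) < min_n)
    abort_popgrs(sprintf("both samples need >= %d observations", min_n),
                 "popgrs_validation_error")
}

#' @rdname welch_ttest
#' @export
mannwhitney <- function(x, y, correct = FALSE) {
  check_two_sample(x, y)
  if (length(unique(c(x, y))) == 1) {
    warning("all observations tied; Mann-Whitney p set to 1", call. = FALSE)
    return(new_test_result("mannwhitney", length(x) * length(y) / 2, NA_real_, 1,
                           length(x), length(y)))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = correct))
  new_test_result("mannwhitney", ht$statistic, NA_real_, ht$p.value,
                  length(x), length(y))
}

#' @rdname welch_ttest
#' @export
ks_two_sample <- function(x, y) {
  check_two_sample(x, y)
  if (length(x) < 8 || length(y) < 8)
    warning("KS asymptotic p-value unreliable for n < 8 per side", call. = FALSE)
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  new_test_result("ks", ht$statistic, NA_real_, ht$p.value, length(x), length(y))
}

#' Per-SNP risk-allele-frequency scan between two populations
#'
#' For every variant, compares risk-allele counts between populations with a
#' 2x2 allele-count table (risk vs other allele; chromosomes = 2 x
#' non-missing samples), Pearson chi-squared without continuity correction,
#' and Bonferroni adjustment over the m tested variants. The per-variant
#' statistic is computed in closed form (`n (ad-bc)^2` over the product of
#' marginals — identical to [chi2_two_by_two()], verified in the test
#' suite) so that replicate scans stay cheap.
#'
#' @param matrix_a,matrix_b [genotype_matrix()]s for populations A and B
#'   with the same variants in the same order.
#' @param weights Optional `variant_weights`; if supplied, variant order is
#'   checked against it.
#' @param alpha_adj Significance threshold on the *adjusted* p-value
#'   (default 0.001).
#' @return A `data.frame` of class `af_scan` with one row per variant:
#'   `rsid raf_a raf_b diff chi2 p_raw p_adj direction significant`.
#'   A variant monomorphic in both populations gets statistic 0, p 1,
#'   direction `none`.
#' @export
af_scan <- function(matrix_a, matrix_b, weights = NULL, alpha_adj = 0.001) {
  if (!identical(colnames(matrix_a), colnames(matrix_b)))
    abort_popgrs("populations have different variant sets", "popgrs_validation_error")
  if (!is.null(weights) && !identical(colnames(matrix_a), weights$rsid))
    abort_popgrs("matrix variants do not match weight table", "popgrs_validation_error")
  counts <- function(gm) {
    n_ok <- colSums(!is.na(gm))
    risk <- colSums(gm, na.rm = TRUE)
    list(risk = risk, other = 2 * n_ok - risk, chrom = 2 * n_ok)
  }
  ca <- counts(matrix_a); cb <- counts(matrix_b)
  a <- ca$risk; b <- cb$risk; c_ <- ca$other; d <- cb$other
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- ifelse(denom == 0, 0, n * (a * d - b * c_)^2 / denom)
  p_raw <- ifelse(denom == 0, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  m <- length(a)
  p_adj <- pmin(1, m * p_raw)
  raf_a <- a / ca$chrom; raf_b <- b / cb$chrom
  diff <- raf_a - raf_b
  direction <- ifelse(diff > 0, "higher_A", ifelse(diff < 0, "higher_B", "none"))
  out <- data.frame(rsid = colnames(matrix_a), raf_a = raf_a, raf_b = raf_b,
                    diff = diff, chi2 = stat, p_raw = p_raw, p_adj = p_adj,
                    direction = direction, significant = p_adj < alpha_adj,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "m") <- m
  attr(out, "alpha_adj") <- alpha_adj
  attr(out, "n_a") <- nrow(matrix_a)
  attr(out, "n_b") <- nrow(matrix_b)
  class(out) <- c("af_scan", "data.frame")
  out
}

#' Summarise a risk-allele-frequency scan
#'
#' Counts the significant variants by direction, reports the range of
#' absolute frequency differences among them, and returns the table sorted
#' for a dumbbell display (population-A frequency next to population-B
#' frequency per SNP, ordered by signed difference).
#'
#' @param rows An [af_scan()] result.
#' @return A list of class `scan_summary`: `n_higher_a`, `n_higher_b`,
#'   `n_nonsignificant`, `min_abs_diff`, `max_abs_diff` (both over
#'   significant rows; `NA` if none), `m`, `alpha_adj`, and `dumbbell`
#'   (the sorted table).
#' @export
summarize_scan <- function(rows) {
  if (!inherits(rows, "af_scan") || nrow(rows) == 0)
    abort_popgrs("summarize_scan needs a nonempty af_scan result", "popgrs_validation_error")
  sig <- rows[rows$significant, , drop = FALSE]
  structure(list(
    n_higher_a = sum(sig$direction == "higher_A"),
    n_higher_b = sum(sig$direction == "higher_B"),
    n_nonsignificant = sum(!rows$significant),
    min_abs_diff = if (nrow(sig)) min(abs(sig$diff)) else NA_real_,
    max_abs_diff = if (nrow(sig)) max(abs(sig$diff)) else NA_real_,
    m = attr(rows, "m"),
    alpha_adj = attr(rows, "alpha_adj"),
    dumbbell = rows[order(rows$diff), ]), class = "scan_summary")
}

#' Dumbbell plot of per-SNP risk-allele frequencies
#'
#' Displays, for the significant variants of a scan, the risk-allele
#' frequency in each population joined by a segment, split by direction.
#'
#' @param rows An [af_scan()] result.
#' @param labels Population display names, length 2.
#' @param significant_only Plot only Bonferroni-significant variants.
#' @return A ggplot object.
#' @export
plot_dumbbell <- function(rows, labels = c("A", "B"), significant_only = TRUE) {
  df <- if (significant_only) rows[rows$significant, , drop = FALSE] else rows
  if (!nrow(df)) abort_popgrs("no variants to plot", "popgrs_validation_error")
  df <- df[order(df$diff), ]
  df$rsid <- factor(df$rsid, levels = df$rsid)
  long <- rbind(data.frame(rsid = df$rsid, raf = df$raf_a, population = labels[1]),
                data.frame(rsid = df$rsid, raf = df$raf_b, population = labels[2]))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$rsid)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$raf_a, xend = .data$raf_b,
                                       yend = .data$rsid), colour = "grey60") +
    ggplot2::geom_point(data = long,
                        ggplot2::aes(x = .data$raf, colour = .data$population),
                        size = 1.6) +
    ggplot2::labs(x = "risk allele frequency", y = NULL, colour = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}
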