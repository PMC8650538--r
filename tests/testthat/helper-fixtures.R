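# Shared fixtures, built in code at test time.

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# tiny weight table: 2 variants, one risk==ALT, one risk==REF in the VCF below
tiny_weights_path <- function() {
  write_tsv_fixture(c(
    "rsid\tchrom\tpos\trisk_allele\tother_allele\todds_ratio",
    "rs0001\t1\t1000\tA\tG\t1.20",
    "rs0002\t2\t2000\tC\tT\t1.05"))
}

# 3 samples x 2 variants; rs0001 risk allele A is ALT, rs0002 risk allele C
# is REF; S2 has a missing genotype at rs0002
tiny_vcf_path <- function(extra_records = character(0)) {
  write_tsv_fixture(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t1000\trs0001\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0",
    "2\t2000\trs0002\tC\tT\t.\tPASS\t.\tGT\t0/0\t./.\t1/1",
    extra_records), tempfile(fileext = ".vcf"))
}

make_phenotypes <- function(n = 5, seed = 11, population = "England") {
  prof <- population_profile(tolower(population))
  ph <- simulate_phenotypes(n, prof, seed = seed)
  ph$cad <- seq_len(n) %% 2 == 0
  ph
}

# independent brute-force scorer: explicit per-sample, per-variant loop
oracle_scores <- function(dosages, weights) {
  n <- nrow(dosages); k <- ncol(dosages)
  ugrs <- numeric(n); wgrs <- numeric(n)
  for (i in seq_len(n)) {
    u <- 0; w <- 0
    for (j in seq_len(k)) {
      u <- u + dosages[i, j]
      w <- w + log(weights$odds_ratio[j]) * dosages[i, j]
    }
    ugrs[i] <- u; wgrs[i] <- w
  }
  list(ugrs = ugrs, wgrs = wgrs)
}

# exhaustive permutation distribution of the Pearson statistic on a 2x2
# table, collapsed over the hypergeometric sufficient statistic
exact_perm_p <- function(tab) {
  n1 <- sum(tab[, 1]); n2 <- sum(tab[, 2]); s <- sum(tab[1, ]); N <- n1 + n2
  stat <- function(a) {
    m <- matrix(c(a, n1 - a, s - a, n2 - s + a), 2)
    dn <- prod(rowSums(m)) * prod(colSums(m))
    if (dn == 0) return(0)
    N * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 / dn
  }
  obs <- stat(tab[1, 1])
  as <- max(0, s - n2):min(s, n1)
  sum(stats::dhyper(as, s, N - s, n1)[vapply(as, stat, numeric(1)) >= obs - 1e-9])
}

# in-code score spec with a single guarded-free term set, for closed forms
toy_spec <- function(terms_f = list(), terms_m = terms_f, s0 = 0.9, mean_lp = 0) {
  validate_score_spec(list(name = "toy",
                           F = list(terms = terms_f, s0 = s0, mean_lp = mean_lp),
                           M = list(terms = terms_m, s0 = s0, mean_lp = mean_lp)))
}

one_record <- function(sex = "F", age = 55, bmi = 27, sbp = 130, tc = 180,
                       hdl = 50, smoker = FALSE, diabetic = FALSE,
                       antihypertensive = FALSE) {
  data.frame(sample_id = "X1", population = "England", sex = sex, age = age,
             bmi = bmi, sbp = sbp, tc = tc, hdl = hdl, smoker = smoker,
             diabetic = diabetic, antihypertensive = antihypertensive,
             cad = FALSE, stringsAsFactors = FALSE)
}
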