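test_that("snp_het computes MAF, HET_O, HET_E and F by the definitions", {
  hs <- snp_het(cnt(25, 50, 25), cnt(25, 50, 25))
  expect_equal(hs$maf_a, 0.5)
  expect_equal(hs$het_o_a, 0.5)
  expect_equal(hs$het_e_a, 0.5)
  expect_equal(hs$f_a, 0)

  hs2 <- snp_het(cnt(10, 80, 10), cnt(25, 50, 25))
  expect_equal(hs2$maf_a, 0.5)
  expect_equal(hs2$het_o_a, 0.8)
  expect_equal(hs2$f_a, 0.6)

  hs3 <- snp_het(cnt(98, 2, 0), cnt(50, 50, 0))
  expect_equal(hs3$maf_a, 0.01)
  expect_equal(hs3$het_o_a, 0.02)
  expect_equal(hs3$het_e_a, 0.0198)
  expect_equal(hs3$f_a, (0.02 - 0.0198) / 0.0198)

  expect_error(snp_het(cnt(100, 0, 0), cnt(100, 0, 0)), "monomorphic")
})

test_that("paired comparison handles nulls, shifts and label swaps", {
  x <- runif(100)
  same <- paired_cohort_test(x, x)
  expect_equal(same$p, 1)
  expect_identical(same$direction, "none")

  up <- paired_cohort_test(x, x + 1, labels = c("a", "b"))
  expect_lt(up$p, 1e-10)
  expect_identical(up$direction, "b-higher")

  sw <- paired_cohort_test(x + 1, x, labels = c("a", "b"))
  expect_equal(sw$p, up$p)
  expect_identical(sw$direction, "a-higher")
})

test_that("signed-rank p agrees with full sign-assignment enumeration", {
  set.seed(601)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    d <- rnorm(n) + 0.4
    expect_equal(paired_cohort_test(rep(0, n), d)$p, signed_rank_enum_p(d),
                 tolerance = 1e-10)
  }
})

test_that("genotype-ratio FET matches enumeration and known tables", {
  # [[5,0],[0,5]]: only the two extreme tables are as improbable
  r <- genotype_ratio_test(cnt(0, 5, 0), cnt(5, 0, 5))
  expect_equal(r$p, 2 / 252)
  expect_identical(r$direction, "A-higher")

  r2 <- genotype_ratio_test(cnt(0, 10, 10), cnt(0, 10, 10))
  expect_equal(r2$p, 1)
  expect_identical(r2$direction, "none")

  # cohort transposition symmetry
  set.seed(602)
  for (i in 1:30) {
    a <- cnt(sample(0:12, 1), sample(0:12, 1), sample(0:12, 1))
    b <- cnt(sample(0:12, 1), sample(0:12, 1), sample(0:12, 1))
    expect_equal(genotype_ratio_test(a, b)$p, genotype_ratio_test(b, a)$p)
    # against the reference implementation on the same 2x2 table
    tb <- rbind(c(a[, "het"], a[, "hom_minor"]),
                c(b[, "het"], b[, "hom_minor"]))
    if (all(rowSums(tb) > 0) && all(colSums(tb) > 0))
      expect_equal(genotype_ratio_test(a, b)$p, fisher.test(tb)$p.value,
                   tolerance = 1e-9)
  }
  # degenerate margin: no information
  dg <- genotype_ratio_test(cnt(10, 0, 3), cnt(10, 0, 5))
  expect_equal(dg$p, 1)
  expect_identical(dg$direction, "none")
})

test_that("allelic scan reports exact p and a 1-df chi-square", {
  al <- allelic_test(cnt(25, 50, 25), cnt(25, 50, 25))
  expect_equal(al$p, 1)
  expect_equal(al$chisq, 0)
  expect_identical(al$direction, "none")

  al2 <- allelic_test(cnt(90, 10, 0), cnt(50, 40, 10), labels = c("x", "y"))
  expect_identical(al2$direction, "y-higher")
  tb <- rbind(c(10, 190), c(60, 140))
  expect_equal(al2$p, fisher.test(tb)$p.value, tolerance = 1e-9)
  expect_equal(al2$chisq, suppressWarnings(
    chisq.test(tb, correct = FALSE)$statistic[[1]]))

  # adjusted test flags a constant dosage column
  cst <- allelic_test_adjusted(rep(1L, 40), rep(c("a", "b"), 20))
  expect_equal(cst$p, 1)
  expect_match(cst$note, "constant")
})

test_that("count asymmetry meta-test is exact, symmetric and label-safe", {
  mk_scan <- function(ka, kb, labels = c("A", "B")) {
    data.frame(p = rep(0.01, ka + kb),
               direction = c(rep(paste0(labels[1], "-higher"), ka),
                             rep(paste0(labels[2], "-higher"), kb)))
  }
  for (k in c(3, 50)) {
    r <- significant_count_comparison(mk_scan(k, k), alpha_grid = 0.05)
    expect_equal(r$p_binomial, 1)
    expect_identical(r$direction, "none")
  }
  # exact two-sided binomial agrees with the enumeration oracle
  set.seed(603)
  for (i in 1:20) {
    ka <- sample(0:40, 1); kb <- sample(0:40, 1)
    if (ka + kb == 0) next
    r <- significant_count_comparison(mk_scan(ka, kb), alpha_grid = 0.05)
    expect_equal(r$p_binomial, binom_enum_p(ka, ka + kb), tolerance = 1e-12)
  }
  # swapping cohort labels together with directions leaves p unchanged
  r1 <- significant_count_comparison(mk_scan(30, 18), alpha_grid = 0.05)
  r2 <- significant_count_comparison(mk_scan(18, 30), alpha_grid = 0.05)
  expect_equal(r1$p_binomial, r2$p_binomial)
  # mismatched direction labels are an error, not a silent zero count
  expect_error(significant_count_comparison(mk_scan(5, 5, c("x", "y"))),
               "labels")
  # no significant SNPs at a level: counts 0, p = 1
  none <- data.frame(p = rep(0.5, 10), direction = rep("A-higher", 10))
  r0 <- significant_count_comparison(none, alpha_grid = 0.01)
  expect_equal(r0$n_a_higher + r0$n_b_higher, 0)
  expect_equal(r0$p_binomial, 1)
})

test_that("stratified comparison is null-calibrated and flags degenerate strata", {
  sp <- small_sim(seed = 604, n = 200, m = 2000)
  g <- sp$genotypes
  cn <- genotype_counts(g)
  panel <- qc_filter(g, counts = cn)$panel
  idx <- match(panel, g$snps$snp_id)
  lv <- levels(g$cohort)
  hs <- snp_het(cn[[lv[1]]][idx, ], cn[[lv[2]]][idx, ])
  st <- stratified_comparison(hs, measure = "f", labels = lv)
  expect_equal(nrow(st), 4)
  expect_true(all(st$q >= 0.05 | is.na(st$q)) || sum(st$q < 0.05) <= 1)
  # stored stats equal a recomputation from the raw matrix (bookkeeping)
  cn2 <- genotype_counts(g, panel)
  hs2 <- snp_het(cn2[[lv[1]]], cn2[[lv[2]]])
  expect_equal(hs2, hs, tolerance = 1e-12)

  # annotation scheme with a single-SNP stratum gets flagged
  snps <- g$snps[idx, ]
  snps$association_category[] <- "none"
  snps$association_category[1] <- "disease"
  st2 <- stratified_comparison(hs, snps, scheme = "association_category",
                               measure = "f", labels = lv)
  expect_identical(st2$note[st2$stratum == "disease"], "single-SNP stratum")
})
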