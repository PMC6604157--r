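test_that("simulation is deterministic given the config seed", {
  a <- small_sim(seed = 11)
  b <- small_sim(seed = 11)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$snps, b$snps)
  c <- small_sim(seed = 12)
  expect_false(identical(a$genotypes$dosage, c$genotypes$dosage))
})

test_that("heterozygote excess follows the configured closed form", {
  # f = -0.05 in one cohort at p = 0.4: P(het) = 2*0.4*0.6*1.05 = 0.504
  cfg <- sim_config(n_per_cohort = 10000, n_snps = 40,
                    maf_distribution = list(law = "uniform",
                                            min = 0.399, max = 0.401),
                    f_cohort = list(biobank = 0, wellderly = -0.05),
                    seed = 21)
  sp <- simulate_cohort_pair(cfg)
  cn <- genotype_counts(sp$genotypes)
  hs <- snp_het(cn$biobank, cn$wellderly)
  se <- sqrt(0.5 * 0.5 / 10000)  # binomial sampling error per SNP, averaged
  expect_lt(abs(mean(hs$het_o_a) - 0.48), 4 * se / sqrt(40))
  expect_lt(abs(mean(hs$het_o_b) - 0.504), 4 * se / sqrt(40))
  # per-SNP F centred near -f in the excess cohort, near 0 in the other
  expect_lt(abs(mean(hs$f_a)), 0.01)
  expect_lt(abs(mean(hs$f_b) - 0.05 / 1), 0.01)
})

test_that("genotype frequencies match the configured law (chi-square GOF)", {
  cfg <- sim_config(n_per_cohort = 10000, n_snps = 30,
                    maf_distribution = list(law = "uniform",
                                            min = 0.1, max = 0.5),
                    f_cohort = list(biobank = 0.02, wellderly = -0.04),
                    seed = 31)
  sp <- simulate_cohort_pair(cfg)
  g <- sp$genotypes
  # recover per-SNP expected probabilities from realized allele frequencies
  cn <- genotype_counts(g)
  for (who in list(c("biobank", 0.02), c("wellderly", -0.04))) {
    cm <- cn[[who[1]]]
    f <- as.numeric(who[2])
    n <- rowSums(cm)
    p <- (2 * cm[, "hom_minor"] + cm[, "het"]) / (2 * n)
    # chi-square GOF against the (p, f) law, df = 1 (p estimated)
    probs <- cbind((1 - p)^2 + p * (1 - p) * f,
                   2 * p * (1 - p) * (1 - f),
                   p^2 + p * (1 - p) * f)
    stat <- rowSums((cm - probs * n)^2 / pmax(probs * n, 1e-12))
    gof_p <- pchisq(stat, df = 1, lower.tail = FALSE)
    expect_gt(min(gof_p), 0.001 / 30)  # no SNP wildly off the law
  }
})

test_that("allele counts satisfy the bookkeeping identity", {
  sp <- small_sim(seed = 41)
  cn <- genotype_counts(sp$genotypes)$combined
  n <- rowSums(cn)
  mac <- colSums(sp$genotypes$dosage)
  expect_identical(as.integer(mac),
                   as.integer(2 * n - 2 * cn[, "hom_major"] - cn[, "het"]))
})

test_that("negative genotype probabilities are rejected", {
  # f < -p/(1-p) drives the minor-homozygote probability negative
  cfg <- sim_config(n_per_cohort = 10, n_snps = 20,
                    maf_distribution = list(law = "uniform",
                                            min = 0.01, max = 0.02),
                    f_cohort = list(biobank = 0, wellderly = -0.5),
                    seed = 51)
  expect_error(simulate_cohort_pair(cfg), "negative genotype probability")
})

test_that("f can vary by MAF and annotation class", {
  fb <- function(maf, cls) ifelse(maf >= 0.25 & cls == "noncoding", -0.2, 0)
  cfg <- sim_config(n_per_cohort = 3000, n_snps = 400,
                    f_cohort = list(biobank = 0, wellderly = fb), seed = 61)
  sp <- simulate_cohort_pair(cfg)
  cn <- genotype_counts(sp$genotypes)
  hs <- snp_het(cn$biobank, cn$wellderly)
  hi <- sp$snps$annotation_class == "noncoding" & hs$maf_combined >= 0.3
  lo <- hs$maf_combined < 0.2
  expect_gt(mean(hs$f_b[hi]), 0.15)
  expect_lt(abs(mean(hs$f_b[lo])), 0.05)
})

test_that("simulated EHR respects the age window and independence at zero linkage", {
  sp <- small_sim(seed = 71, n = 400, m = 100)
  het <- het_rate(sp$genotypes, sp$snps$snp_id)$rates
  ehr <- simulate_ehr(sp$samples, het, sim_config(n_per_cohort = 400,
                                                  n_snps = 100), seed = 72)
  expect_true(all(ehr$age >= 41 & ehr$age <= 80))
  C <- charlson_scores(ehr)$comorbidity_points
  expect_gt(cor.test(het, C, method = "spearman", exact = FALSE)$p.value, 0.01)
  # out-of-window configuration is rejected
  expect_error(sim_config(ehr_params = list(age_range = c(85, 85))),
               "within \\[41, 80\\]")
})

test_that("comorbidity linkage induces heterozygosity-dependent burden", {
  sp <- small_sim(seed = 81, n = 800, m = 200)
  het <- het_rate(sp$genotypes, sp$snps$snp_id)$rates
  cfg <- sim_config(n_per_cohort = 800, n_snps = 200,
                    ehr_params = list(het_link = 1))
  ehr <- simulate_ehr(sp$samples, het, cfg, seed = 82)
  C <- charlson_scores(ehr)$comorbidity_points
  expect_gt(cor(het, C, method = "spearman"), 0.1)
})
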