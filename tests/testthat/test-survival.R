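test_that("Charlson age bands, catalogue points and the survival curve", {
  expect_identical(age_points(55), 2L)
  expect_identical(age_points(80), 4L)
  expect_identical(age_points(40), 0L)
  expect_identical(age_points(41), 1L)
  expect_identical(age_points(50.9), 1L)  # floored to 50
  expect_error(age_points(81), "above age 80")

  expect_identical(comorbidity_points(character(0)), 0L)
  expect_identical(comorbidity_points(c("diabetes_uncomplicated", "leukemia")),
                   3L)
  expect_identical(comorbidity_points(c("solid_tumor_metastatic", "aids")),
                   12L)
  expect_error(comorbidity_points("gout"), "unknown condition")
  expect_error(comorbidity_points(c("liver_mild", "liver_moderate_severe")),
               "severity")
  # additivity over disjoint conditions
  cat <- charlson_catalogue()
  expect_identical(comorbidity_points(c("copd", "hemiplegia")),
                   comorbidity_points("copd") + cat[["hemiplegia"]])

  expect_equal(charlson_probability(0, 0), 0.983)
  expect_equal(charlson_probability(2, 1), 0.983^exp(2.7))
  grid <- expand.grid(A = 0:4, C = 0:12)
  lz <- charlson_probability(grid$A, grid$C, log = TRUE)
  expect_true(all(is.finite(lz) & lz <= log(0.983)))
  # strictly decreasing in A + C (asserted on the exact log scale)
  zs <- tapply(lz, grid$A + grid$C, unique)
  expect_true(all(diff(unlist(zs)) < 0))
})

test_that("survival regression recovers an injected heterozygosity effect", {
  set.seed(801)
  sp <- small_sim(seed = 802, n = 180, m = 400)
  het <- het_rate(sp$genotypes, sp$snps$snp_id)$rates
  cfg <- sim_config(n_per_cohort = 180, n_snps = 400,
                    ehr_params = list(het_beta = 10, outcome_sd = 0.05))
  ehr <- simulate_ehr(sp$samples, het, cfg, seed = 803)
  fit <- regress_survival(ehr, het, pcs = NULL, response = "recorded")
  co <- fit$coefficients
  b <- co$estimate[co$term == "HetRate"]
  se <- co$se[co$term == "HetRate"]
  expect_lt(abs(b - 10), 4 * se)
  expect_false(fit$degenerate)

  # with noise near zero and flat covariates the slope is exact
  cfg0 <- sim_config(n_per_cohort = 180, n_snps = 400,
                     ehr_params = list(het_beta = 5, outcome_sd = 1e-9,
                                       age_range = c(55, 55),
                                       prevalence = c(aids = 1e-9)))
  ehr0 <- simulate_ehr(sp$samples, het, cfg0, seed = 804)
  fit0 <- regress_survival(ehr0, het, pcs = NULL, response = "recorded")
  b0 <- fit0$coefficients$estimate[fit0$coefficients$term == "HetRate"]
  expect_equal(b0, 5, tolerance = 1e-5)
})

test_that("a constant heterozygosity column is flagged as rank-deficient", {
  ehr <- data.frame(sample_id = paste0("s", 1:40),
                    age = rep(51:60, 4),
                    gender = rep(c("male", "female"), 20),
                    conditions = "",
                    stringsAsFactors = FALSE)
  het <- setNames(rep(0.2, 40), ehr$sample_id)
  fit <- regress_survival(ehr, het)
  expect_true(fit$degenerate)
  expect_true("HetRate" %in% fit$dropped)
})

test_that("per-gender fits isolate a male-only injected effect", {
  set.seed(805)
  sp <- small_sim(seed = 806, n = 250, m = 400)
  het <- het_rate(sp$genotypes, sp$snps$snp_id)$rates
  cfg <- sim_config(n_per_cohort = 250, n_snps = 400,
                    ehr_params = list(het_beta = c(male = 20, female = 0),
                                      outcome_sd = 0.03))
  ehr <- simulate_ehr(sp$samples, het, cfg, seed = 807)
  fm <- regress_survival(ehr, het, subset = "male", response = "recorded")
  ff <- regress_survival(ehr, het, subset = "female", response = "recorded")
  pm <- fm$coefficients$p[fm$coefficients$term == "HetRate"]
  pf <- ff$coefficients$p[ff$coefficients$term == "HetRate"]
  expect_lt(pm, 0.05)
  expect_gt(pf, 0.05)
  # gender indicator only enters the pooled fit
  expect_false("gender" %in% fm$coefficients$term)
})

test_that("extreme-group comparison tests and skips as specified", {
  set.seed(808)
  n <- 300
  ehr <- data.frame(sample_id = paste0("s", 1:n),
                    age = sample(51:60, n, TRUE),
                    gender = "male",
                    conditions = sample(c("", "aids;dementia", "solid_tumor_metastatic;copd"),
                                        n, TRUE, prob = c(0.5, 0.25, 0.25)),
                    stringsAsFactors = FALSE)
  z <- charlson_scores(ehr)$survival_prob
  het <- setNames(ifelse(z > 0.9, rnorm(n, 0.25, 0.01), rnorm(n, 0.20, 0.01)),
                  ehr$sample_id)
  r <- extreme_group_comparison(ehr, het, subset = "male")
  expect_lt(r$p, 1e-4)
  expect_identical(r$direction, "high-survival-higher")
  # an age band excluding everyone is skipped, not an error
  r2 <- extreme_group_comparison(ehr[ehr$age > 55, ], het, age_band = c(41, 50))
  expect_true(is.na(r2$p))
  expect_match(r2$note, "empty")
})
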