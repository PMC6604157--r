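test_that("match_distance is the variance-weighted L1 sum over six components", {
  w <- c(0.3, 0.2, 0.15, 0.1, 0.08, 0.05, 0.02)
  a <- rep(0, 7)
  expect_equal(match_distance(a, a, w), 0)
  b <- c(1, rep(0, 6))
  expect_equal(match_distance(a, b, c(0.1, w[-1])), 0.1)
  set.seed(501)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(match_distance(x, y, w),
                 sum(abs(x[1:6] - y[1:6]) * w[1:6]))
    expect_equal(match_distance(x, y, w, metric = "l2"),
                 sum((x[1:6] - y[1:6])^2 * w[1:6]))
  }
  expect_error(match_distance(1:3, 1:3, w), "n_components")
})

test_that("PCA scores are deterministic, sign-fixed and separate populations", {
  sp <- small_sim(seed = 502, n = 80, m = 500)
  g <- sp$genotypes
  p1 <- run_pca(g, k = 4)
  p2 <- run_pca(g, k = 4)
  expect_identical(p1$scores, p2$scores)
  expect_true(all(diff(p1$var_explained) <= 1e-12))
  expect_lte(sum(p1$var_explained), 1)

  # two identical samples get identical score rows
  d <- g$dosage
  d[2, ] <- d[1, ]
  g2 <- cohort_genotypes(d, g$cohort, g$snps)
  s <- run_pca(g2, k = 3)$scores
  expect_equal(s[1, ], s[2, ], tolerance = 1e-8)

  # strong structure: PC1 separates Balding-Nichols subpopulations
  spst <- simulate_cohort_pair(sim_config(n_per_cohort = 100, n_snps = 2000,
                                          fst = 0.05, seed = 503))
  pst <- run_pca(spst$genotypes, k = 2)
  pc1 <- pst$scores[, 1]
  pop <- spst$samples$pop
  between <- (mean(pc1[pop == 1]) - mean(pc1[pop == 2]))^2
  within <- var(pc1[pop == 1]) + var(pc1[pop == 2])
  expect_gt(between, within)

  # k beyond the rank errors
  tiny <- tiny_geno(rbind(c(0L, 1L), c(1L, 0L), c(2L, 1L), c(1L, 2L)),
                    c("a", "a", "b", "b"))
  expect_error(run_pca(tiny, k = 3), "rank|samples")
})

test_that("greedy matching is deterministic, improves with restarts, and is near-optimal", {
  sp <- small_sim(seed = 504, n = 40, m = 300)
  g <- sp$genotypes
  pca <- run_pca(g, k = 6)
  lv <- levels(g$cohort)
  ids_a <- rownames(g$dosage)[g$cohort == lv[1]]
  ids_b <- rownames(g$dosage)[g$cohort == lv[2]]
  m1 <- greedy_match(pca, ids_a, ids_b, n_restarts = 10, seed = 9)
  m2 <- greedy_match(pca, ids_a, ids_b, n_restarts = 10, seed = 9)
  expect_identical(m1$pairs, m2$pairs)
  expect_equal(m1$total_distance, sum(m1$pairs$distance))
  expect_false(anyDuplicated(m1$pairs$id_b) > 0)
  # total distance non-increasing in the number of restarts (same seed)
  t1 <- greedy_match(pca, ids_a, ids_b, n_restarts = 1, seed = 9)$total_distance
  t5 <- greedy_match(pca, ids_a, ids_b, n_restarts = 5, seed = 9)$total_distance
  expect_lte(t5, t1)

  # cohort B a copy of cohort A in PC space: perfect zero-distance matching
  sc <- pca$scores
  sc[ids_b[seq_along(ids_a)], ] <- sc[ids_a, ]
  pcopy <- structure(list(scores = sc, var_explained = pca$var_explained,
                          k = pca$k), class = "pca_result")
  mc <- greedy_match(pcopy, ids_a, ids_b[seq_along(ids_a)], seed = 1)
  expect_equal(mc$total_distance, 0)

  # one A sample: greedy equals the global nearest neighbour
  m_one <- greedy_match(pca, ids_a[1], ids_b, n_restarts = 3, seed = 2)
  D <- sapply(ids_b, function(j) match_distance(pca$scores[ids_a[1], ],
                                                pca$scores[j, ],
                                                pca$var_explained))
  expect_equal(m_one$total_distance, min(D))

  # greedy total is bounded below by the brute-force optimal assignment
  set.seed(505)
  for (i in 1:5) {
    sc6 <- matrix(rnorm(12 * 6), 12)
    rownames(sc6) <- paste0("x", 1:12)
    p6 <- structure(list(scores = sc6, var_explained = rep(1 / 6, 6), k = 6),
                    class = "pca_result")
    gm <- greedy_match(p6, paste0("x", 1:6), paste0("x", 7:12),
                       n_restarts = 10, seed = i)
    Dm <- distance_matrix <- matrix(0, 6, 6)
    for (a in 1:6) for (b in 1:6)
      Dm[a, b] <- match_distance(sc6[a, ], sc6[6 + b, ], rep(1 / 6, 6))
    expect_gte(gm$total_distance + 1e-12, assignment_optimum(Dm))
  }
  expect_error(greedy_match(pca, ids_b, ids_a[1:10]), "larger")
})

test_that("pair filtering and the inflation factor behave as defined", {
  pairs <- structure(list(pairs = data.frame(id_a = letters[1:4],
                                             id_b = LETTERS[1:4],
                                             distance = c(0.5, 2, 1, 3)),
                          total_distance = 6.5, n_restarts = 1),
                     class = "matched_pairs")
  expect_equal(nrow(filter_pairs(pairs, 0.4)$pairs), 0)
  expect_identical(filter_pairs(pairs, Inf)$pairs, pairs$pairs)
  f <- filter_pairs(pairs, 1.5)
  expect_equal(nrow(f$pairs), 2)
  expect_equal(f$total_distance, 1.5)

  expect_equal(genomic_inflation(rep(qchisq(0.5, 1), 5))$lambda_gc, 1)
  x <- rexp(101)
  expect_equal(genomic_inflation(2 * x)$lambda_gc,
               2 * genomic_inflation(x)$lambda_gc)
  set.seed(506)
  draws <- rchisq(1e5, df = 1)
  expect_equal(genomic_inflation(draws)$lambda_gc, 1, tolerance = 0.02)
  expect_error(genomic_inflation(numeric(0)), "no statistics")
})
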