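#' Construct a test-result record
#'
#' Uniform one-row container for the package's statistical tests.
#'
#' @param test test name.
#' @param statistic test statistic (NA if not applicable).
#' @param p two-sided p-value in \[0, 1\] (NA for skipped tests).
#' @param direction which side is higher, or "none".
#' @param note optional annotation (degeneracy, skips).
#' @return one-row data.frame with class `test_result`.
#' @export
test_result <- function(test, statistic, p, direction = "none", note = "") {
  if (!is.na(p) && (p < 0 || p > 1)) stop("p outside [0, 1]")
  structure(data.frame(test = test, statistic = statistic, p = p,
                       direction = direction, note = note,
                       stringsAsFactors = FALSE),
            class = c("test_result", "data.frame"))
}

#' Per-SNP heterozygosity statistics
#'
#' For each SNP and cohort computes the minor-allele frequency
#' `p = (2 n_hom_minor + n_het) / 2n`, the observed heterozygosity
#' `HET_O = n_het / n`, the Hardy-Weinberg expectation `HET_E = 2p(1-p)`,
#' and the excess of heterozygosity `F = (HET_O - HET_E) / HET_E` (zero at
#' exact HWE, positive for heterozygote excess). Frequencies refer to the
#' combined-cohort minor allele, so a cohort-specific frequency may slightly
#' exceed 0.5; `HET_E` and `F` are unaffected by that orientation.
#'
#' @param counts_a,counts_b integer matrices (SNPs x 3) with columns
#'   `hom_major`, `het`, `hom_minor`, e.g. from [genotype_counts()].
#' @return data.frame with one row per SNP: `maf_a`, `het_o_a`, `het_e_a`,
#'   `f_a`, the `_b` counterparts, and `maf_combined`.
#' @export
snp_het <- function(counts_a, counts_b) {
  one <- function(cn) {
    n <- rowSums(cn)
    if (any(n < 1)) stop("each SNP needs at least one genotype per cohort")
    p <- (2 * cn[, "hom_minor"] + cn[, "het"]) / (2 * n)
    het_o <- cn[, "het"] / n
    het_e <- 2 * p * (1 - p)
    list(maf = p, het_o = het_o, het_e = het_e, f = (het_o - het_e) / het_e)
  }
  a <- one(counts_a); b <- one(counts_b)
  na <- rowSums(counts_a); nb <- rowSums(counts_b)
  mac <- 2 * (counts_a[, "hom_minor"] + counts_b[, "hom_minor"]) +
    counts_a[, "het"] + counts_b[, "het"]
  maf_combined <- mac / (2 * (na + nb))
  if (any(mac == 0 | mac == 2 * (na + nb)))
    stop("monomorphic SNP: filter before computing heterozygosity statistics")
  data.frame(maf_a = a$maf, het_o_a = a$het_o, het_e_a = a$het_e, f_a = a$f,
             maf_b = b$maf, het_o_b = b$het_o, het_e_b = b$het_e, f_b = b$f,
             maf_combined = maf_combined)
}

#' Paired cohort comparison of a per-SNP measure
#'
#' Wilcoxon signed-rank test (the paired analogue of the Mann-Whitney U
#' test) on per-SNP differences between the cohorts. Zero differences are
#' dropped (classic Wilcoxon convention); the null distribution is exact for
#' up to 25 non-zero differences without ties and a normal approximation
#' with continuity correction otherwise.
#'
#' @param values_a,values_b numeric vectors paired by SNP.
#' @param labels length-2 character used to phrase the direction.
#' @return a [test_result()] row; direction names the cohort with the larger
#'   positive rank mass.
#' @export
paired_cohort_test <- function(values_a, values_b, labels = c("A", "B")) {
  stopifnot(length(values_a) == length(values_b))
  d <- values_b - values_a
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (!length(nz)) return(test_result("wilcoxon_signed_rank", 0, 1, "none"))
  exact <- length(nz) <= 25 && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    wilcox.test(nz, exact = exact, correct = TRUE))
  r <- rank(abs(nz))
  vplus <- sum(r[nz > 0]); vminus <- sum(r[nz < 0])
  dir <- if (vplus > vminus) paste0(labels[2], "-higher")
         else if (vplus < vminus) paste0(labels[1], "-higher") else "none"
  test_result("wilcoxon_signed_rank", unname(wt$statistic), wt$p.value, dir)
}

#' Genotype-ratio association scan between cohorts
#'
#' For every SNP, a two-sided Fisher exact test on the 2x2 table of
#' heterozygote versus homozygote counts across the two cohorts: either
#' het vs minor-allele homozygotes (the Dd/DD comparison) or het vs
#' major-allele homozygotes (Dd/dd). The two-sided p sums the probabilities
#' of all tables at most as probable as the observed one. A table with a
#' zero margin carries no information and is reported as p = 1 with no
#' direction.
#'
#' @param counts_a,counts_b SNPs x 3 genotype count matrices (see
#'   [genotype_counts()]).
#' @param mode "het_vs_hom_minor" or "het_vs_hom_major".
#' @param labels length-2 character naming the cohorts.
#' @return data.frame per SNP: `p`, `odds_a`, `odds_b` (het:hom ratios) and
#'   `direction` (cohort with the larger het:hom odds, "none" on ties or
#'   degenerate tables).
#' @export
genotype_ratio_test <- function(counts_a, counts_b,
                                mode = c("het_vs_hom_minor", "het_vs_hom_major"),
                                labels = c("A", "B")) {
  mode <- match.arg(mode)
  hom <- if (mode == "het_vs_hom_minor") "hom_minor" else "hom_major"
  ha <- counts_a[, "het"]; hb <- counts_b[, "het"]
  oa <- counts_a[, hom];   ob <- counts_b[, hom]
  p <- .fet2x2_p(as.integer(ha), as.integer(oa),
                 as.integer(hb), as.integer(ob))
  cross_a <- as.numeric(ha) * as.numeric(ob)
  cross_b <- as.numeric(hb) * as.numeric(oa)
  degenerate <- (ha + hb == 0) | (oa + ob == 0) | (ha + oa == 0) | (hb + ob == 0)
  direction <- ifelse(degenerate | cross_a == cross_b, "none",
                      ifelse(cross_a > cross_b,
                             paste0(labels[1], "-higher"),
                             paste0(labels[2], "-higher")))
  data.frame(p = p, odds_a = ha / oa, odds_b = hb / ob,
             direction = direction, stringsAsFactors = FALSE)
}

#' Allelic association scan between cohorts
#'
#' Per-SNP two-sided Fisher exact test on the 2x2 minor/major allele-count
#' table across cohorts, plus the 1-df Pearson chi-square statistic used for
#' the genomic-inflation factor. For covariate-adjusted allelic tests see
#' [allelic_test_adjusted()].
#'
#' @inheritParams genotype_ratio_test
#' @return data.frame per SNP: `p`, `chisq`, `direction` (cohort with the
#'   higher minor-allele frequency).
#' @export
allelic_test <- function(counts_a, counts_b, labels = c("A", "B")) {
  mac_a <- 2 * counts_a[, "hom_minor"] + counts_a[, "het"]
  mac_b <- 2 * counts_b[, "hom_minor"] + counts_b[, "het"]
  tot_a <- 2 * rowSums(counts_a); tot_b <- 2 * rowSums(counts_b)
  p <- .fet2x2_p(as.integer(mac_a), as.integer(tot_a - mac_a),
                 as.integer(mac_b), as.integer(tot_b - mac_b))
  # Pearson chi-square on the allele-count table
  n <- tot_a + tot_b; mac <- mac_a + mac_b
  e_a <- tot_a * mac / n
  denom <- mac * (n - mac) * tot_a * tot_b
  chisq <- ifelse(denom == 0, 0, (mac_a * tot_b - mac_b * tot_a)^2 * n / denom)
  fa <- mac_a / tot_a; fb <- mac_b / tot_b
  direction <- ifelse(fa == fb | mac == 0 | mac == n, "none",
                      ifelse(fa > fb, paste0(labels[1], "-higher"),
                             paste0(labels[2], "-higher")))
  data.frame(p = p, chisq = chisq, direction = direction,
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted allelic association for one SNP
#'
#' Logistic regression of cohort membership on per-sample dosage plus
#' principal-component covariates; Wald p for the dosage term. A constant
#' dosage column is reported as a degenerate no-signal result.
#'
#' @param dosage integer vector of per-sample minor-allele dosages.
#' @param cohort two-level factor.
#' @param pcs matrix of per-sample covariates (e.g. PC scores), or NULL.
#' @return a [test_result()] row.
#' @export
allelic_test_adjusted <- function(dosage, cohort, pcs = NULL) {
  cohort <- as.factor(cohort)
  stopifnot(nlevels(cohort) == 2)
  if (length(unique(dosage[!is.na(dosage)])) < 2)
    return(test_result("logistic_wald", NA_real_, 1, "none",
                       note = "constant dosage"))
  df <- data.frame(y = as.integer(cohort) - 1L, dosage = dosage)
  if (!is.null(pcs)) df <- cbind(df, as.data.frame(pcs))
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  if (!"dosage" %in% rownames(sm))
    return(test_result("logistic_wald", NA_real_, 1, "none",
                       note = "dosage dropped (collinear)"))
  est <- sm["dosage", 1]; p <- sm["dosage", 4]
  dir <- if (est > 0) paste0(levels(cohort)[2], "-higher")
         else if (est < 0) paste0(levels(cohort)[1], "-higher") else "none"
  test_result("logistic_wald", est, p, dir)
}

#' Count-asymmetry meta-test over an association scan
#'
#' At each nominal significance level, counts the SNPs whose per-SNP test
#' falls below the level separately by direction, and applies an exact
#' two-sided binomial test of the split against equal probability 1/2 (the
#' two-sided p sums binomial outcome probabilities not exceeding that of the
#' observed count). Equal heterozygosity in the two cohorts predicts a
#' symmetric split.
#'
#' @param scan data.frame with columns `p` and `direction` (from
#'   [genotype_ratio_test()] or [allelic_test()]).
#' @param alpha_grid nominal per-SNP significance levels.
#' @param labels length-2 character naming the cohorts (must match the
#'   directions in `scan`).
#' @return data.frame per level: `alpha`, `n_a_higher`, `n_b_higher`,
#'   `p_binomial`, `direction`.
#' @export
significant_count_comparison <- function(scan,
                                         alpha_grid = c(0.05, 0.01, 0.001),
                                         labels = c("A", "B")) {
  if (!nrow(scan)) stop("empty scan")
  dir_a <- paste0(labels[1], "-higher")
  dir_b <- paste0(labels[2], "-higher")
  known <- unique(scan$direction)
  if (length(setdiff(known, c(dir_a, dir_b, "none"))))
    stop("scan directions do not match `labels`: ",
         paste(setdiff(known, c(dir_a, dir_b, "none")), collapse = ", "))
  rows <- lapply(alpha_grid, function(alpha) {
    sig <- !is.na(scan$p) & scan$p < alpha
    ka <- sum(sig & scan$direction == dir_a)
    kb <- sum(sig & scan$direction == dir_b)
    pb <- if (ka + kb == 0) 1 else binom.test(ka, ka + kb, p = 0.5)$p.value
    data.frame(alpha = alpha, n_a_higher = ka, n_b_higher = kb,
               p_binomial = pb,
               direction = if (ka > kb) dir_a else if (kb > ka) dir_b else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default MAF stratification bins
#'
#' Right-open bins \[0.01, 0.05), \[0.05, 0.1), \[0.1, 0.25) and the closed
#' top bin \[0.25, 0.5\].
#' @return numeric vector of bin edges.
#' @export
maf_bin_edges <- function() c(0.01, 0.05, 0.1, 0.25, 0.5)

# map combined MAF to bin labels; NA outside the covered range
maf_bin_of <- function(maf, edges = maf_bin_edges()) {
  cut(maf, breaks = edges, right = FALSE, include.lowest = TRUE,
      labels = sprintf("[%g,%g)", head(edges, -1), edges[-1]))
}

#' Stratified cohort comparison of a heterozygosity measure
#'
#' Splits SNPs into strata — combined-MAF bins or an annotation key — and,
#' within each stratum, runs the paired signed-rank comparison of the chosen
#' measure together with per-cohort means and standard errors (SNPs treated
#' as units). Raw p-values are reported alongside Benjamini-Hochberg
#' adjusted q-values computed across the strata of this comparison.
#'
#' @param stats per-SNP statistics from [snp_het()].
#' @param snps matching SNP table (needed for annotation schemes).
#' @param scheme "maf" (default bins from [maf_bin_edges()]), or the name of
#'   a SNP-table column such as "association_category" or "gene_list".
#' @param measure one of "maf", "het_o", "f".
#' @param edges MAF bin edges when `scheme = "maf"`.
#' @param labels cohort names for direction phrasing.
#' @return data.frame per stratum: `stratum`, `n_snps`, means and SEs per
#'   cohort, `p`, `direction`, `q` (BH within this call), `note` (flags
#'   empty or single-SNP strata).
#' @export
stratified_comparison <- function(stats, snps = NULL, scheme = "maf",
                                  measure = c("f", "het_o", "maf"),
                                  edges = maf_bin_edges(),
                                  labels = c("A", "B")) {
  measure <- match.arg(measure)
  va <- stats[[paste0(measure, "_a")]]
  vb <- stats[[paste0(measure, "_b")]]
  strata <- if (identical(scheme, "maf")) {
    maf_bin_of(stats$maf_combined, edges)
  } else {
    if (is.null(snps) || is.null(snps[[scheme]]))
      stop("annotation scheme needs a SNP table column: ", scheme)
    factor(snps[[scheme]])
  }
  n_unmapped <- sum(is.na(strata))
  rows <- lapply(levels(strata), function(s) {
    idx <- which(!is.na(strata) & strata == s)
    if (!length(idx))
      return(data.frame(stratum = s, n_snps = 0L, mean_a = NA_real_,
                        se_a = NA_real_, mean_b = NA_real_, se_b = NA_real_,
                        p = NA_real_, direction = "none",
                        note = "empty stratum", stringsAsFactors = FALSE))
    tr <- paired_cohort_test(va[idx], vb[idx], labels)
    data.frame(stratum = s, n_snps = length(idx),
               mean_a = mean(va[idx]), se_a = sd(va[idx]) / sqrt(length(idx)),
               mean_b = mean(vb[idx]), se_b = sd(vb[idx]) / sqrt(length(idx)),
               p = tr$p, direction = tr$direction,
               note = if (length(idx) < 2) "single-SNP stratum" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "measure") <- measure
  out
}
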