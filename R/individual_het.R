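#' Individual heterozygosity rate
#'
#' The proportion of heterozygous sites each sample carries across a fixed
#' SNP panel (typically the common noncoding SNPs, combined MAF > 0.1).
#' Because every sample is scored on exactly the same panel with no missing
#' genotypes, no standardisation is needed.
#'
#' @param g a [cohort_genotypes] object with no missing dosages on the panel.
#' @param panel character vector of SNP ids.
#' @return list of class `het_rate_result`: `rates` (named per-sample
#'   proportions), `panel_size`, `cohort` (factor aligned with `rates`).
#' @export
het_rate <- function(g, panel) {
  if (!length(panel)) stop("empty panel")
  d <- g$dosage[, panel, drop = FALSE]
  if (anyNA(d)) stop("missing dosages on the panel; run QC first")
  rates <- rowMeans(d == 1L)
  structure(list(rates = rates, panel_size = length(panel),
                 cohort = g$cohort),
            class = "het_rate_result")
}

#' Permutation null for cohort mean heterozygosity rate
#'
#' Builds pseudo-cohorts by, independently for every SNP column, sampling
#' `n_a` of the combined `n_a + n_b` genotypes without replacement, and
#' records the mean heterozygosity rate of the pseudo-cohort in each
#' permutation. The recorded statistic depends on a permuted column only
#' through how many of its heterozygotes land in the pseudo-cohort, which
#' given the column's heterozygote total `H_j` is exactly hypergeometric
#' `(n_a + n_b, H_j, n_a)`; the null is therefore drawn as one
#' hypergeometric variate per column per permutation — identical in law to
#' permuting full columns, at a fraction of the cost.
#'
#' Empirical p-values use the add-one convention
#' `p = (1 + #exceedances) / (n_perm + 1)`, so a cohort mean outside the
#' whole null range reports the minimal achievable p rather than zero.
#'
#' @param g a [cohort_genotypes] object (combined cohorts).
#' @param panel SNP ids defining the heterozygosity-rate panel.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list of class `permutation_result`: `observed` (named cohort mean
#'   rates), `null` (length `n_perm` pseudo-cohort means, pseudo-cohort size
#'   = first cohort's size), `p_high`/`p_low` (named per cohort, one-sided
#'   each), `n_perm`, `seed`.
#' @export
permutation_null <- function(g, panel, n_perm = 10000L, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  hr <- het_rate(g, panel)
  lv <- levels(g$cohort)
  n_a <- sum(g$cohort == lv[1]); n_b <- sum(g$cohort == lv[2])
  m <- length(panel)
  d <- g$dosage[, panel, drop = FALSE]
  H <- colSums(d == 1L)                      # heterozygotes per column
  null <- numeric(n_perm)
  for (b in seq_len(n_perm))
    null[b] <- sum(rhyper(m, H, n_a + n_b - H, n_a)) / (n_a * m)
  observed <- c(mean(hr$rates[g$cohort == lv[1]]),
                mean(hr$rates[g$cohort == lv[2]]))
  names(observed) <- lv
  p_high <- vapply(observed, function(o) (1 + sum(null >= o)) / (n_perm + 1),
                   numeric(1))
  p_low <- vapply(observed, function(o) (1 + sum(null <= o)) / (n_perm + 1),
                  numeric(1))
  structure(list(observed = observed, null = null,
                 p_high = p_high, p_low = p_low,
                 n_perm = as.integer(n_perm), seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations\n", x$n_perm))
  for (cn in names(x$observed))
    cat(sprintf("  %s: mean het rate %.5f  p_high=%.3g  p_low=%.3g\n",
                cn, x$observed[cn], x$p_high[cn], x$p_low[cn]))
  invisible(x)
}

#' Common-SNP panel for the heterozygosity rate
#'
#' Selects the noncoding SNPs on a QC panel whose combined MAF exceeds the
#' given threshold (default 0.1; 0.25 is the usual robustness alternative).
#'
#' @param g a [cohort_genotypes] object.
#' @param panel QC-passing SNP ids.
#' @param maf_min combined MAF threshold (exclusive).
#' @param noncoding_only restrict to `annotation_class == "noncoding"` when
#'   the SNP table carries that column.
#' @return character vector of SNP ids.
#' @export
het_rate_panel <- function(g, panel, maf_min = 0.1, noncoding_only = TRUE) {
  cn <- genotype_counts(g, panel)
  n2 <- 2 * rowSums(cn$combined)
  mac <- 2 * cn$combined[, "hom_minor"] + cn$combined[, "het"]
  maf <- pmin(mac, n2 - mac) / n2
  keep <- maf > maf_min
  if (noncoding_only && !is.null(g$snps$annotation_class)) {
    cls <- g$snps$annotation_class[match(panel, g$snps$snp_id)]
    keep <- keep & cls == "noncoding"
  }
  panel[keep]
}
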