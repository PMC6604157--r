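#' Variant QC configuration
#'
#' @param hwe_p_threshold retain SNPs with exact Hardy-Weinberg p above this
#'   (default 0.001).
#' @param combined_maf_min retain SNPs with combined minor-allele frequency
#'   above this (default 0.01).
#' @param excluded_interval optional list `(chrom, start, end)` (1-based,
#'   inclusive) removed from the panel — the MHC-style exclusion.
#' @param hwe_scope "combined" (default) tests Hardy-Weinberg on the pooled
#'   cohorts; "per_cohort" requires both cohorts to pass.
#' @param ld_window_snps,ld_step_snps,ld_r2_max sliding-window LD pruning
#'   parameters for [ld_prune()]: window of 50 SNPs advancing 5 SNPs per
#'   step, dropping SNPs until all retained within-window pairs have squared
#'   dosage correlation below 0.5.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(hwe_p_threshold = 0.001, combined_maf_min = 0.01,
                      excluded_interval = NULL,
                      hwe_scope = c("combined", "per_cohort"),
                      ld_window_snps = 50L, ld_step_snps = 5L,
                      ld_r2_max = 0.5) {
  hwe_scope <- match.arg(hwe_scope)
  stopifnot(hwe_p_threshold > 0, hwe_p_threshold < 1,
            combined_maf_min > 0, combined_maf_min < 1,
            ld_r2_max > 0, ld_r2_max <= 1,
            ld_window_snps >= ld_step_snps, ld_step_snps >= 1)
  structure(list(hwe_p_threshold = hwe_p_threshold,
                 combined_maf_min = combined_maf_min,
                 excluded_interval = excluded_interval,
                 hwe_scope = hwe_scope,
                 ld_window_snps = as.integer(ld_window_snps),
                 ld_step_snps = as.integer(ld_step_snps),
                 ld_r2_max = ld_r2_max),
            class = "qc_config")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact p from the conditional distribution of the heterozygote
#' count given the observed allele counts: the sum of the probabilities of
#' all heterozygote counts no more probable than the observed one
#' (Wigginton-style enumeration). Vectorised over SNPs.
#'
#' @param n_hom_minor,n_het,n_hom_major genotype counts (non-negative; at
#'   least one genotype per SNP).
#' @return numeric vector of p-values in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_minor, n_het, n_hom_major) {
  .hwe_exact_p(as.integer(n_hom_minor), as.integer(n_het),
               as.integer(n_hom_major))
}

# is a SNP row inside the excluded interval?
in_interval <- function(snps, iv) {
  if (is.null(iv)) return(rep(FALSE, nrow(snps)))
  snps$chrom == as.character(iv$chrom) &
    snps$pos >= iv$start & snps$pos <= iv$end
}

#' SNP inclusion filters
#'
#' Applies, in order: (1) consistent alleles in both cohorts (guaranteed by
#' construction for a merged [cohort_genotypes]; counted when a merge
#' recorded mismatches); (2) at least one minor allele in each cohort;
#' (3) no missing genotypes; (4) autosomal and outside the excluded
#' interval; (5) Hardy-Weinberg exact p above threshold; (6) combined MAF
#' above threshold. Each excluded SNP is attributed to the first criterion
#' it fails, so the report is a reproducible accounting of the panel.
#'
#' @param g a [cohort_genotypes] object.
#' @param cfg a [qc_config()].
#' @param counts optional precomputed [genotype_counts()] for `g`, to avoid
#'   recounting in tight replicate loops.
#' @return list: `panel` (character vector of retained SNP ids), `report`
#'   (data.frame `criterion`, `n_excluded`), `n_input`, `n_retained`.
#'   Filtering to an empty panel is an error.
#' @export
qc_filter <- function(g, cfg = qc_config(), counts = NULL) {
  snps <- g$snps
  m <- nrow(snps)
  cn <- if (is.null(counts)) genotype_counts(g) else counts
  lv <- levels(g$cohort)
  called_a <- rowSums(cn[[lv[1]]]); called_b <- rowSums(cn[[lv[2]]])
  n_a <- sum(g$cohort == lv[1]); n_b <- sum(g$cohort == lv[2])

  fail <- rep(NA_integer_, m)  # first failing criterion, NA = retained
  mark <- function(fail, cond, k) ifelse(is.na(fail) & cond, k, fail)

  # 1. allele consistency across cohorts (recorded at merge time)
  mismatch <- attr(g, "allele_mismatch")
  if (!is.null(mismatch)) fail <- mark(fail, snps$snp_id %in% mismatch, 1L)
  # 2. at least one minor allele in each cohort
  mac_a <- 2 * cn[[lv[1]]][, "hom_minor"] + cn[[lv[1]]][, "het"]
  mac_b <- 2 * cn[[lv[2]]][, "hom_minor"] + cn[[lv[2]]][, "het"]
  fail <- mark(fail, mac_a == 0 | mac_b == 0, 2L)
  # 3. no missing genotypes in either cohort
  fail <- mark(fail, called_a < n_a | called_b < n_b, 3L)
  # 4. autosomal, outside the excluded interval
  autosome <- snps$chrom %in% as.character(1:22)
  fail <- mark(fail, !autosome | in_interval(snps, cfg$excluded_interval), 4L)
  # 5. Hardy-Weinberg exact test
  todo <- is.na(fail)
  hwe_p <- rep(NA_real_, m)
  if (any(todo)) {
    hp <- function(cm) hwe_exact_test(cm[todo, "hom_minor"], cm[todo, "het"],
                                      cm[todo, "hom_major"])
    hwe_p[todo] <- if (cfg$hwe_scope == "combined") hp(cn$combined) else
      pmin(hp(cn[[lv[1]]]), hp(cn[[lv[2]]]))
    fail <- mark(fail, !is.na(hwe_p) & hwe_p <= cfg$hwe_p_threshold, 5L)
  }
  # 6. combined MAF
  mac <- mac_a + mac_b
  maf <- pmin(mac, 2 * (called_a + called_b) - mac) /
    (2 * pmax(called_a + called_b, 1L))
  fail <- mark(fail, maf <= cfg$combined_maf_min, 6L)

  criteria <- c("allele_mismatch", "monomorphic_in_a_cohort",
                "missing_genotypes", "non_autosomal_or_excluded_interval",
                "hwe_failure", "low_combined_maf")
  report <- data.frame(criterion = criteria,
                       n_excluded = tabulate(fail, nbins = 6L))
  panel <- snps$snp_id[is.na(fail)]
  if (!length(panel)) stop("no SNPs survive QC")
  list(panel = panel, report = report, n_input = m, n_retained = length(panel))
}

#' Sliding-window LD pruning
#'
#' Greedy pruning on combined-cohort dosage correlations: within each window
#' of `ld_window_snps` position-sorted SNPs, while any retained pair has
#' squared Pearson correlation at or above `ld_r2_max`, the later-positioned
#' SNP of the worst pair is dropped (ties: larger position, then larger id);
#' the window then advances by `ld_step_snps`. Correlations are composite
#' (dosage) r-squared, appropriate for unphased hard calls.
#'
#' @param g a [cohort_genotypes] object.
#' @param panel character vector of SNP ids to prune (position order is
#'   taken from the SNP table).
#' @param cfg a [qc_config()].
#' @return character vector, the retained subset of `panel`.
#' @export
ld_prune <- function(g, panel, cfg = qc_config()) {
  if (!length(panel)) return(character(0))
  snps <- g$snps[match(panel, g$snps$snp_id), ]
  keep <- rep(TRUE, nrow(snps))
  d <- g$dosage[, panel, drop = FALSE]
  storage.mode(d) <- "double"
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    idx <- idx[order(snps$pos[idx])]
    start <- 1L
    repeat {
      win <- idx[seq.int(start, min(start + cfg$ld_window_snps - 1L,
                                    length(idx)))]
      act <- win[keep[win]]
      while (length(act) >= 2) {
        r2 <- suppressWarnings(stats::cor(d[, act, drop = FALSE]))^2
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        mx <- max(r2)
        if (mx < cfg$ld_r2_max) break
        hits <- which(r2 == mx, arr.ind = TRUE)
        # later-positioned member of the worst pair; ties by position then id
        drop_local <- max(hits)  # columns are position-ordered within chrom
        keep[act[drop_local]] <- FALSE
        act <- act[-drop_local]
      }
      if (start + cfg$ld_window_snps - 1L >= length(idx)) break
      start <- start + cfg$ld_step_snps
    }
  }
  panel[keep]
}
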