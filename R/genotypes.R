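#' Two-cohort genotype container
#'
#' Bundles a hard-call dosage matrix with cohort labels and the SNP table.
#' Dosages count copies of the \emph{combined-cohort minor allele} (0, 1 or 2);
#' [recode_minor()] enforces that convention.
#'
#' @param dosage integer matrix, samples x SNPs, values in \{0, 1, 2\} (NA
#'   allowed before QC). Row names are sample ids, column names SNP ids.
#' @param cohort factor (or character) of length `nrow(dosage)` with exactly
#'   two levels naming the cohorts.
#' @param snps data.frame with one row per SNP column, in column order, with
#'   at least `snp_id`, `chrom`, `pos`, `ref`, `alt`, `minor_allele`. Optional
#'   annotation columns: `annotation_class` ("noncoding"/"nonsynonymous"),
#'   `gene`, `association_category` ("none"/"disease"/"trait"), `gene_list`
#'   (""/"recessive"/"dominant").
#' @return An object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(dosage, cohort, snps) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  storage.mode(dosage) <- "integer"
  rng <- if (anyNA(dosage)) suppressWarnings(range(dosage, na.rm = TRUE))
         else range(dosage)
  if (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L))
    stop("dosages must be 0, 1 or 2")
  cohort <- as.factor(cohort)
  if (length(cohort) != nrow(dosage))
    stop("`cohort` length must equal the number of samples")
  if (nlevels(cohort) != 2L)
    stop("exactly two cohorts are required, got ", nlevels(cohort))
  if (!is.data.frame(snps) || nrow(snps) != ncol(dosage))
    stop("`snps` must have one row per SNP column")
  need <- c("snp_id", "chrom", "pos", "ref", "alt", "minor_allele")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("`snps` lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(snps$snp_id)) stop("duplicated snp ids")
  if (is.null(colnames(dosage))) colnames(dosage) <- snps$snp_id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  # positions strictly increasing within each chromosome
  for (ch in unique(snps$chrom)) {
    ps <- snps$pos[snps$chrom == ch]
    if (any(diff(ps) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  structure(list(dosage = dosage, cohort = cohort, snps = snps),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  tab <- table(x$cohort)
  cat(sprintf("<cohort_genotypes> %d samples (%s) x %d SNPs\n",
              nrow(x$dosage),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              ncol(x$dosage)))
  invisible(x)
}

#' Recode dosages so that stored counts refer to the combined minor allele
#'
#' The minor allele is defined on the cohorts combined. Columns whose counted
#' allele has combined frequency above 0.5 are complemented (`2 - dosage`) and
#' `minor_allele` updated. At a frequency of exactly 0.5 the lexicographically
#' smaller allele string is designated minor, so the recode is deterministic
#' and independent of input order.
#'
#' @param g a [cohort_genotypes] object (dosages counting `alt`, say).
#' @return the object with dosages counting the combined minor allele.
#' @export
recode_minor <- function(g) {
  d <- g$dosage
  n_called <- if (anyNA(d)) colSums(!is.na(d)) else rep(nrow(d), ncol(d))
  freq <- colSums(d, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  counted <- g$snps$minor_allele
  other <- ifelse(counted == g$snps$alt, g$snps$ref, g$snps$alt)
  flip <- freq > 0.5 | (freq == 0.5 & counted > other)
  if (any(flip)) {
    d[, flip] <- 2L - d[, flip]
    g$snps$minor_allele[flip] <- other[flip]
    g$dosage <- d
  }
  g
}

#' Per-SNP genotype counts by cohort
#'
#' @param g a [cohort_genotypes] object.
#' @param panel optional character vector of SNP ids to restrict to.
#' @return list with per-cohort (named by cohort level) and `combined`
#'   integer matrices of size SNPs x 3 with columns `hom_major`, `het`,
#'   `hom_minor` (dosage 0/1/2 of the minor allele).
#' @export
genotype_counts <- function(g, panel = NULL) {
  d <- g$dosage
  if (!is.null(panel)) d <- d[, panel, drop = FALSE]
  lv <- levels(g$cohort)
  cc <- .count_dosage(d, as.integer(g$cohort))
  lab <- c("hom_major", "het", "hom_minor")
  dimnames(cc[[1]]) <- dimnames(cc[[2]]) <- list(colnames(d), lab)
  out <- list(cc[[1]], cc[[2]])
  names(out) <- lv
  out$combined <- out[[1]] + out[[2]]
  out
}
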