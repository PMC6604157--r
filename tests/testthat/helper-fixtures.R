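# small in-code fixtures shared across test files

# genotype counts matrix from a named triple
cnt <- function(hom_major, het, hom_minor) {
  cbind(hom_major = hom_major, het = het, hom_minor = hom_minor)
}

# a tiny cohort_genotypes object from an explicit dosage matrix
tiny_geno <- function(dosage, cohort, chrom = "1",
                      pos = 1000L * seq_len(ncol(dosage))) {
  m <- ncol(dosage)
  snps <- data.frame(snp_id = sprintf("s%03d", seq_len(m)), chrom = chrom,
                     pos = pos, ref = "A", alt = "G", minor_allele = "G",
                     stringsAsFactors = FALSE)
  colnames(dosage) <- snps$snp_id
  rownames(dosage) <- sprintf("i%03d", seq_len(nrow(dosage)))
  cohort_genotypes(dosage, cohort, snps)
}

# a quick small simulated pair for plumbing tests
small_sim <- function(seed = 1, n = 60, m = 300, ...) {
  simulate_cohort_pair(sim_config(n_per_cohort = n, n_snps = m, seed = seed,
                                  ...))
}
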