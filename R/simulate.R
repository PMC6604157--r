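#' Simulation configuration for a two-cohort genotype study
#'
#' Builds the configuration consumed by [simulate_cohort_pair()] and
#' [simulate_ehr()]. Defaults emulate the matched-pair design the package
#' analyses: two cohorts of 426 individuals genotyped on a shared panel of
#' biallelic SNPs laid on a single pseudo-autosome, with minor-allele
#' frequencies drawn uniformly on \[0.01, 0.5\].
#'
#' The per-cohort coefficient `f` plays the role of an inbreeding-like
#' departure from Hardy-Weinberg equilibrium: for a SNP with minor-allele
#' frequency `p`, genotype probabilities are
#' `P(het) = 2p(1-p)(1-f)`, `P(hom minor) = p^2 + p(1-p)f`,
#' `P(hom major) = (1-p)^2 + p(1-p)f`, so `f < 0` yields heterozygote excess.
#' `f` may be a scalar per cohort or a function of `(maf, annotation_class)`
#' returning one value per SNP, which allows excess to be injected only into
#' chosen MAF ranges or annotation classes.
#'
#' With `fst > 0`, each subpopulation's SNP frequency is drawn from a
#' Balding-Nichols law `Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)` around the
#' ancestral `p`, and samples are assigned to subpopulations with the
#' per-cohort mixing proportions in `cohort_mix` (rows = cohorts), so the two
#' cohorts can be given unequal ancestry composition.
#'
#' @param n_per_cohort samples per cohort; a length-2 vector gives the two
#'   cohorts unequal sizes (e.g. a smaller index cohort and a larger pool to
#'   match against).
#' @param n_snps number of SNPs on the shared panel.
#' @param cohort_names length-2 character, cohort labels.
#' @param maf_distribution list; `law = "uniform"` with `min`, `max` (support
#'   must lie within \[0.01, 0.5\]).
#' @param f_cohort named list (one element per cohort) of scalars or
#'   functions `f(maf, annotation_class)`.
#' @param fst Balding-Nichols differentiation between subpopulations
#'   (0 = no structure).
#' @param cohort_mix 2 x n_pops matrix of subpopulation proportions per
#'   cohort; default is an even mix when `fst > 0`.
#' @param annotation_fractions list with elements `nonsynonymous`, `disease`,
#'   `trait` (per-SNP fractions) and `recessive_genes`, `dominant_genes`
#'   (per-gene fractions).
#' @param gene_size consecutive SNPs per synthetic gene.
#' @param masked_interval optional `c(start, end)` (1-based, inclusive) on the
#'   pseudo-autosome; SNPs inside stand in for a region (such as the MHC) that
#'   QC must exclude. They are simulated like any other SNP.
#' @param ld_dup list `(prop, flip)`: a fraction `prop` of SNP columns is
#'   overwritten with a noisy copy (per-genotype resampling probability
#'   `flip`) of the preceding column, creating high-LD adjacent pairs that
#'   exercise the pruner. Not a realistic LD model.
#' @param ehr_params list for [simulate_ehr()]: `age_range` (within
#'   \[41, 80\]), `p_female`, `prevalence` (named per-condition), `het_link`
#'   (log-odds shift of every condition per SD of heterozygosity rate),
#'   `het_beta` (linear effect of heterozygosity rate on the recorded 10-year
#'   survival outcome; scalar or named `c(male=, female=)`), `outcome_sd`
#'   (residual noise of the recorded outcome).
#' @param seed integer seed; simulation is deterministic given the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_cohort = 426L,
                       n_snps = 20000L,
                       cohort_names = c("biobank", "wellderly"),
                       maf_distribution = list(law = "uniform",
                                               min = 0.01, max = 0.5),
                       f_cohort = NULL,
                       fst = 0,
                       cohort_mix = NULL,
                       annotation_fractions = list(nonsynonymous = 0.10,
                                                   disease = 0.05,
                                                   trait = 0.05,
                                                   recessive_genes = 0.10,
                                                   dominant_genes = 0.10),
                       gene_size = 5L,
                       masked_interval = NULL,
                       ld_dup = list(prop = 0, flip = 0.02),
                       ehr_params = list(),
                       seed = NULL) {
  stopifnot(all(n_per_cohort >= 1), length(n_per_cohort) %in% 1:2,
            n_snps >= 1, length(cohort_names) == 2)
  n_per_cohort <- rep_len(as.integer(n_per_cohort), 2L)
  if (maf_distribution$law != "uniform")
    stop("unsupported maf law: ", maf_distribution$law)
  if (maf_distribution$min < 0.01 || maf_distribution$max > 0.5 ||
      maf_distribution$min >= maf_distribution$max)
    stop("maf support must lie within [0.01, 0.5]")
  if (is.null(f_cohort)) {
    f_cohort <- list(0, 0)
    names(f_cohort) <- cohort_names
  }
  if (!all(cohort_names %in% names(f_cohort)))
    stop("`f_cohort` must be named by cohort")
  stopifnot(fst >= 0, fst < 1)
  if (fst > 0 && is.null(cohort_mix))
    cohort_mix <- matrix(0.5, 2, 2, dimnames = list(cohort_names, NULL))
  if (!is.null(cohort_mix)) {
    stopifnot(nrow(cohort_mix) == 2, all(cohort_mix >= 0))
    if (any(abs(rowSums(cohort_mix) - 1) > 1e-8))
      stop("cohort_mix rows must sum to 1")
  }
  ehr_defaults <- list(
    age_range = c(41L, 80L), p_female = 0.5,
    prevalence = c(myocardial_infarction = 0.08, congestive_heart_failure = 0.06,
                   peripheral_vascular_disease = 0.05, cerebrovascular_disease = 0.06,
                   dementia = 0.03, copd = 0.10, connective_tissue_disease = 0.03,
                   peptic_ulcer_disease = 0.04, diabetes_uncomplicated = 0.15,
                   diabetes_end_organ = 0.04, ckd_moderate_severe = 0.05,
                   hemiplegia = 0.01, leukemia = 0.005, malignant_lymphoma = 0.01,
                   solid_tumor = 0.06, solid_tumor_metastatic = 0.01,
                   liver_mild = 0.04, liver_moderate_severe = 0.01, aids = 0.005),
    het_link = 0, het_beta = 0, outcome_sd = 0.02)
  ehr_params <- modifyList(ehr_defaults, ehr_params)
  if (ehr_params$age_range[1] < 41 || ehr_params$age_range[2] > 80)
    stop("ehr ages must lie within [41, 80]")
  bad <- setdiff(names(ehr_params$prevalence), names(charlson_catalogue()))
  if (length(bad)) stop("unknown condition in prevalence: ",
                        paste(bad, collapse = ", "))
  structure(list(n_per_cohort = n_per_cohort,
                 n_snps = as.integer(n_snps),
                 cohort_names = cohort_names,
                 maf_distribution = maf_distribution,
                 f_cohort = f_cohort, fst = fst, cohort_mix = cohort_mix,
                 annotation_fractions = annotation_fractions,
                 gene_size = as.integer(gene_size),
                 masked_interval = masked_interval,
                 ld_dup = ld_dup, ehr_params = ehr_params, seed = seed),
            class = "sim_config")
}

# resolve a per-cohort f spec (scalar or function) to one value per SNP
resolve_f <- function(spec, maf, annotation_class) {
  f <- if (is.function(spec)) spec(maf, annotation_class) else
    rep_len(spec, length(maf))
  if (length(f) != length(maf)) stop("f function must return one value per SNP")
  f
}

# sample dosages (minor-allele counts) for one homogeneous group:
# m SNPs with genotype probability columns, n samples; returns m x n
sample_dosage <- function(p_hom_major, p_het, n) {
  .sample_dosage(p_hom_major, p_hom_major + p_het, as.integer(n))
}

#' Simulate a matched pair of cohort genotype sets
#'
#' Draws the shared SNP panel, per-SNP annotations, and hard-call genotypes
#' for both cohorts under the generative model described in [sim_config()].
#' Dosages are recoded to the combined-cohort minor allele before return.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `genotypes` (a [cohort_genotypes]), `snps`
#'   (the SNP table, identical to `genotypes$snps`) and `samples`
#'   (data.frame `sample_id`, `cohort`, `pop`).
#' @export
simulate_cohort_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- config$n_snps; nn <- config$n_per_cohort
  md <- config$maf_distribution
  p_anc <- runif(m, md$min, md$max)

  ## annotations -------------------------------------------------------
  af <- config$annotation_fractions
  cls <- rep("noncoding", m)
  cls[sample.int(m, round(af$nonsynonymous * m))] <- "nonsynonymous"
  assoc <- rep("none", m)
  n_dis <- round(af$disease * m); n_tr <- round(af$trait * m)
  pick <- sample.int(m, n_dis + n_tr)
  assoc[pick[seq_len(n_dis)]] <- "disease"
  assoc[pick[n_dis + seq_len(n_tr)]] <- "trait"
  gene <- sprintf("GENE%04d", ceiling(seq_len(m) / config$gene_size))
  genes <- unique(gene)
  gl <- rep("", length(genes)); names(gl) <- genes
  n_rec <- round(af$recessive_genes * length(genes))
  n_dom <- round(af$dominant_genes * length(genes))
  pickg <- sample.int(length(genes), n_rec + n_dom)
  gl[pickg[seq_len(n_rec)]] <- "recessive"
  gl[pickg[n_rec + seq_len(n_dom)]] <- "dominant"

  snps <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(m)),
    chrom = "1", pos = 1000L * seq_len(m),
    ref = "A", alt = "G", minor_allele = "G",
    annotation_class = cls, gene = gene,
    association_category = assoc, gene_list = unname(gl[gene]),
    stringsAsFactors = FALSE)

  ## subpopulation frequencies ----------------------------------------
  n_pops <- if (is.null(config$cohort_mix)) 1L else ncol(config$cohort_mix)
  if (config$fst > 0) {
    a <- p_anc * (1 - config$fst) / config$fst
    b <- (1 - p_anc) * (1 - config$fst) / config$fst
    p_pop <- vapply(seq_len(n_pops), function(k) rbeta(m, a, b), numeric(m))
  } else {
    p_pop <- matrix(p_anc, m, n_pops)
  }

  ## genotypes ---------------------------------------------------------
  ntot <- sum(nn)
  dos <- matrix(NA_integer_, m, ntot)
  cohort <- rep(config$cohort_names, times = nn)
  pop <- integer(ntot)
  for (ci in 1:2) {
    cn <- config$cohort_names[ci]
    n <- nn[ci]
    f <- resolve_f(config$f_cohort[[cn]], p_anc, snps$annotation_class)
    mix <- if (is.null(config$cohort_mix)) 1 else config$cohort_mix[ci, ]
    pop_c <- sample.int(n_pops, n, replace = TRUE, prob = mix)
    cols <- if (ci == 1L) seq_len(n) else nn[1] + seq_len(n)
    pop[cols] <- pop_c
    for (k in seq_len(n_pops)) {
      idx <- which(pop_c == k)
      if (!length(idx)) next
      p <- p_pop[, k]
      p_het <- 2 * p * (1 - p) * (1 - f)
      p_hmin <- p^2 + p * (1 - p) * f
      p_hmaj <- (1 - p)^2 + p * (1 - p) * f
      if (any(p_het < 0 | p_hmin < 0 | p_hmaj < 0))
        stop("(p, f) combination yields negative genotype probability")
      dos[, cols[idx]] <- sample_dosage(p_hmaj, p_het, length(idx))
    }
  }

  ## optional high-LD duplicated columns ------------------------------
  if (config$ld_dup$prop > 0 && m >= 2) {
    n_dup <- floor(config$ld_dup$prop * m)
    tgt <- sample(2:m, n_dup)
    for (j in tgt) {
      src <- dos[j - 1L, ]
      refl <- runif(ntot) < config$ld_dup$flip
      src[refl] <- sample(0:2, sum(refl), replace = TRUE)
      dos[j, ] <- src
    }
  }

  samples <- data.frame(
    sample_id = sprintf("%s_%04d", cohort,
                        c(seq_len(nn[1]), seq_len(nn[2]))),
    cohort = cohort, pop = pop, stringsAsFactors = FALSE)
  dosage <- t(dos)
  dimnames(dosage) <- list(samples$sample_id, snps$snp_id)
  g <- cohort_genotypes(dosage, factor(cohort, levels = config$cohort_names),
                        snps)
  g <- recode_minor(g)
  list(genotypes = g, snps = g$snps, samples = samples)
}

#' Simulate EHR-like records linked to heterozygosity rates
#'
#' Generates age, gender and a Charlson-catalogue condition list per sample.
#' `het_link` tilts every condition's log-odds by the sample's standardized
#' heterozygosity rate (a qualitative comorbidity linkage); `het_beta` adds an
#' exact linear heterozygosity effect (optionally per gender) plus Gaussian
#' noise to the recorded 10-year survival outcome, providing a known ground
#' truth for regression-recovery checks — a purely categorical comorbidity
#' pathway cannot encode an exact linear slope.
#'
#' @param samples data.frame with a `sample_id` column (e.g. from
#'   [simulate_cohort_pair()]).
#' @param het_rates numeric vector of per-sample heterozygosity rates, same
#'   length/order as `samples`.
#' @param config a [sim_config()]; only `ehr_params` is used.
#' @param seed optional integer seed.
#' @return data.frame `sample_id`, `age`, `gender`, `conditions`
#'   (semicolon-separated condition ids, "" if none) and `survival_10yr`
#'   (Charlson 10-year survival probability plus any injected effect/noise).
#' @export
simulate_ehr <- function(samples, het_rates, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            length(het_rates) == nrow(samples))
  if (!is.null(seed)) set.seed(seed)
  ep <- config$ehr_params
  if (ep$age_range[1] < 41 || ep$age_range[2] > 80)
    stop("ehr ages must lie within [41, 80]")
  ns <- nrow(samples)
  age <- ep$age_range[1] +
    sample.int(ep$age_range[2] - ep$age_range[1] + 1L, ns, TRUE) - 1L
  gender <- ifelse(runif(ns) < ep$p_female, "female", "male")
  zhet <- if (sd(het_rates) > 0) as.numeric(scale(het_rates)) else
    rep(0, ns)
  prev <- ep$prevalence
  lodds <- outer(zhet * ep$het_link, qlogis(prev), `+`)
  hit <- matrix(runif(ns * length(prev)), ns) < plogis(lodds)
  colnames(hit) <- names(prev)
  # one severity variant per condition family: keep the severer one
  families <- list(c("diabetes_uncomplicated", "diabetes_end_organ"),
                   c("solid_tumor", "solid_tumor_metastatic"),
                   c("liver_mild", "liver_moderate_severe"))
  for (fam in families) {
    if (!all(fam %in% colnames(hit))) next
    both <- hit[, fam[1]] & hit[, fam[2]]
    hit[both, fam[1]] <- FALSE
  }
  conditions <- apply(hit, 1, function(r) paste(colnames(hit)[r], collapse = ";"))
  A <- vapply(age, age_points, integer(1))
  C <- vapply(strsplit(conditions, ";", fixed = TRUE), function(x)
    comorbidity_points(x[nzchar(x)]), integer(1))
  z <- charlson_probability(A, C)
  beta <- ep$het_beta
  b_i <- if (length(beta) == 2 && !is.null(names(beta)))
    unname(beta[gender]) else rep_len(beta, ns)
  outcome <- z + b_i * het_rates + rnorm(ns, 0, ep$outcome_sd)
  data.frame(sample_id = samples$sample_id, age = age, gender = gender,
             conditions = conditions, survival_10yr = outcome,
             stringsAsFactors = FALSE)
}
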