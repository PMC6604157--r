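#' Pipeline run configuration
#'
#' Exactly one of `sim` (a [sim_config()]) or `input` (paths to existing
#' data) must be given. Stage option lists are merged over defaults, so a
#' caller only names what deviates.
#'
#' @param sim a [sim_config()] for synthetic input, or NULL.
#' @param input list for ingested input: `genotypes` (path), `dialect`
#'   ("vcf"/"tsv"), `cohort_labels` (named vector or 2-column TSV path
#'   sample_id/cohort), optional `ehr` (path).
#' @param qc a [qc_config()].
#' @param match list: `enabled`, `k`, `n_components`, `n_restarts`,
#'   `max_distance` (NULL = keep all pairs).
#' @param scan list: `alpha_grid`, `strata` (subset of "maf",
#'   "association_category", "gene_list").
#' @param hetrate list: `enabled`, `maf_min`, `n_perm`.
#' @param survival list: `enabled`; EHR comes from `input$ehr` or, for
#'   synthetic runs, from [simulate_ehr()].
#' @param enrich list: `enabled`, `gmt` (path or named list of paths), `q`.
#' @param out_dir output directory for stage TSVs and the manifest.
#' @param seed global integer seed; per-stage child seeds are fixed offsets
#'   of it, so disabling one stage does not reshuffle another's draws.
#' @param verbose emit one progress line per stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, input = NULL, qc = qc_config(),
                       match = list(), scan = list(), hetrate = list(),
                       survival = list(), enrich = list(),
                       out_dir = tempfile("hetspan_run_"), seed = 1L,
                       verbose = TRUE) {
  if (is.null(sim) == is.null(input))
    stop("exactly one of `sim` or `input` must be given")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  match <- modifyList(list(enabled = FALSE, k = 6L, n_components = 6L,
                           n_restarts = 10L, max_distance = NULL), match)
  scan <- modifyList(list(alpha_grid = c(0.05, 0.01, 0.001),
                          strata = "maf"), scan)
  hetrate <- modifyList(list(enabled = TRUE, maf_min = 0.1, n_perm = 1000L),
                        hetrate)
  survival <- modifyList(list(enabled = FALSE), survival)
  enrich <- modifyList(list(enabled = FALSE, gmt = NULL, q = 0.10), enrich)
  if (survival$enabled && is.null(sim) && is.null(input$ehr))
    stop("survival stage enabled but no EHR table available")
  if (enrich$enabled && is.null(enrich$gmt))
    stop("enrichment stage enabled but no GMT collection given")
  if (is.null(seed)) stop("a seed is mandatory")
  structure(list(sim = sim, input = input, qc = qc, match = match,
                 scan = scan, hetrate = hetrate, survival = survival,
                 enrich = enrich, out_dir = out_dir,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

# fixed per-stage seed offsets: inserting a stage never reshuffles others
stage_seed <- function(cfg, stage) {
  cfg$seed + c(simulate = 11L, match = 23L, hetrate = 37L, ehr = 41L)[[stage]]
}

#' Run the full cohort-heterozygosity analysis pipeline
#'
#' Orchestrates simulate/ingest, QC, optional genetic matching, the
#' heterozygosity scans and meta-tests, the individual heterozygosity rate
#' with its permutation null, optional survival modelling, and optional
#' gene-set enrichment. Every stage's tables are written to
#' `config$out_dir` and listed with md5 hashes in `manifest.json`; the same
#' config and seed reproduce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return list (invisibly): `genotypes`, `panel`, `qc_report`, optional
#'   `matching`, `het_stats`, `scans`, `meta`, `stratified`, `het_rate`,
#'   `permutation`, optional `survival`, `enrichment`, plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  say <- function(...) if (config$verbose) message(sprintf(...))
  out <- list()
  tables <- list()
  manifest <- list(seed = config$seed, stages = list())
  log_stage <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(stage = stage), list(...))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## input -------------------------------------------------------------
  lv <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    if (is.null(sim$seed)) sim$seed <- stage_seed(config, "simulate")
    simres <- run_stage("simulate", simulate_cohort_pair(sim))
    g <- simres$genotypes
    say("simulate: %d samples x %d SNPs", nrow(g$dosage), ncol(g$dosage))
    log_stage("simulate", n_samples = nrow(g$dosage), n_snps = ncol(g$dosage),
              seed = sim$seed)
  } else {
    inp <- config$input
    labs <- inp$cohort_labels
    if (is.character(labs) && length(labs) == 1 && file.exists(labs)) {
      lt <- data.table::fread(labs, data.table = FALSE)
      labs <- setNames(lt[[2]], lt[[1]])
    }
    rd <- run_stage("ingest",
                    read_genotypes(inp$genotypes, inp$dialect, labs))
    g <- rd$genotypes
    say("ingest: %d samples x %d SNPs (%d records rejected)",
        nrow(g$dosage), ncol(g$dosage), rd$n_rejected)
    log_stage("ingest", path = inp$genotypes, n_rejected = rd$n_rejected)
  }
  lv <- levels(g$cohort)
  out$genotypes <- g

  ## qc -----------------------------------------------------------------
  qc <- run_stage("qc", qc_filter(g, config$qc))
  say("qc: %d / %d SNPs retained", qc$n_retained, qc$n_input)
  tables$qc_report <- qc$report
  log_stage("qc", n_input = qc$n_input, n_retained = qc$n_retained)
  panel <- qc$panel
  out$qc_report <- qc$report

  ## matching -----------------------------------------------------------
  if (config$match$enabled) {
    mt <- config$match
    res <- run_stage("match", {
      pca <- run_pca(g, k = mt$k, panel = panel)
      ids_a <- rownames(g$dosage)[g$cohort == lv[1]]
      ids_b <- rownames(g$dosage)[g$cohort == lv[2]]
      swap <- length(ids_a) > length(ids_b)
      pairs <- greedy_match(pca, if (swap) ids_b else ids_a,
                            if (swap) ids_a else ids_b,
                            n_restarts = mt$n_restarts,
                            seed = stage_seed(config, "match"),
                            n_components = mt$n_components)
      if (!is.null(mt$max_distance))
        pairs <- filter_pairs(pairs, mt$max_distance)
      cn0 <- genotype_counts(g, panel)
      before <- genomic_inflation(allelic_test(cn0[[lv[1]]], cn0[[lv[2]]])$chisq)
      g2 <- subset_samples(g, c(pairs$pairs$id_a, pairs$pairs$id_b))
      cn1 <- genotype_counts(g2, panel)
      after <- genomic_inflation(allelic_test(cn1[[lv[1]]], cn1[[lv[2]]])$chisq)
      list(pca = pca, pairs = pairs, genotypes = g2,
           lambda_before = before$lambda_gc, lambda_after = after$lambda_gc)
    })
    say("match: %d pairs, lambda_gc %.3f -> %.3f", nrow(res$pairs$pairs),
        res$lambda_before, res$lambda_after)
    tables$matched_pairs <- res$pairs$pairs
    tables$inflation <- data.frame(stage = c("before", "after"),
                                   lambda_gc = c(res$lambda_before,
                                                 res$lambda_after))
    log_stage("match", n_pairs = nrow(res$pairs$pairs),
              lambda_before = res$lambda_before,
              lambda_after = res$lambda_after)
    out$matching <- res
    g <- res$genotypes
    qc2 <- run_stage("qc", qc_filter(g, config$qc))
    panel <- qc2$panel
  }

  ## scans ---------------------------------------------------------------
  cn <- genotype_counts(g, panel)
  hs <- run_stage("scan", snp_het(cn[[lv[1]]], cn[[lv[2]]]))
  hs <- cbind(snp_id = panel, hs, stringsAsFactors = FALSE)
  scans <- run_stage("scan", list(
    dd = genotype_ratio_test(cn[[lv[1]]], cn[[lv[2]]],
                             "het_vs_hom_minor", labels = lv),
    dd_major = genotype_ratio_test(cn[[lv[1]]], cn[[lv[2]]],
                                   "het_vs_hom_major", labels = lv),
    allelic = allelic_test(cn[[lv[1]]], cn[[lv[2]]], labels = lv)))
  meta <- run_stage("scan", do.call(rbind, lapply(names(scans), function(nm)
    cbind(scan = nm,
          significant_count_comparison(scans[[nm]], config$scan$alpha_grid,
                                       labels = lv)))))
  snps_panel <- g$snps[match(panel, g$snps$snp_id), ]
  strat <- run_stage("scan", do.call(rbind, lapply(config$scan$strata,
    function(sc) do.call(rbind, lapply(c("maf", "het_o", "f"), function(ms)
      cbind(scheme = sc, measure = ms,
            stratified_comparison(hs, snps_panel, scheme = sc, measure = ms,
                                  labels = lv)))))))
  say("scan: %d panel SNPs; meta-test rows: %d", length(panel), nrow(meta))
  tables$het_stats <- hs
  tables$meta_tests <- meta
  tables$stratified <- strat
  log_stage("scan", n_snps = length(panel))
  out$het_stats <- hs; out$scans <- scans; out$meta <- meta
  out$stratified <- strat

  ## individual heterozygosity rate --------------------------------------
  if (config$hetrate$enabled) {
    hrp <- het_rate_panel(g, panel, maf_min = config$hetrate$maf_min)
    res <- run_stage("hetrate", {
      hr <- het_rate(g, hrp)
      pm <- permutation_null(g, hrp, n_perm = config$hetrate$n_perm,
                             seed = stage_seed(config, "hetrate"))
      list(het = hr, perm = pm)
    })
    say("hetrate: panel %d SNPs; perm p (high side): %s", length(hrp),
        paste(sprintf("%s=%.3g", lv, res$perm$p_high), collapse = " "))
    tables$het_rates <- data.frame(sample_id = names(res$het$rates),
                                   cohort = as.character(res$het$cohort),
                                   het_rate = unname(res$het$rates))
    tables$permutation <- data.frame(
      cohort = lv, observed_mean = unname(res$perm$observed),
      p_high = unname(res$perm$p_high), p_low = unname(res$perm$p_low))
    log_stage("hetrate", panel_size = length(hrp),
              n_perm = config$hetrate$n_perm)
    out$het_rate <- res$het; out$permutation <- res$perm
  }

  ## survival -------------------------------------------------------------
  if (config$survival$enabled) {
    res <- run_stage("survival", {
      if (is.null(out$het_rate)) stop("survival stage needs the hetrate stage")
      het <- out$het_rate$rates
      ehr <- if (!is.null(config$input$ehr)) read_ehr(config$input$ehr) else
        simulate_ehr(data.frame(sample_id = names(het)), het, config$sim,
                     seed = stage_seed(config, "ehr"))
      pcs <- if (!is.null(out$matching)) out$matching$pca else
        run_pca(g, k = max(6L, 5L), panel = panel)
      fits <- lapply(c("all", "male", "female"), function(s)
        regress_survival(ehr, het, pcs, subset = s))
      names(fits) <- c("all", "male", "female")
      extremes <- lapply(c("male", "female"), function(s)
        extreme_group_comparison(ehr, het, subset = s))
      names(extremes) <- c("male", "female")
      list(ehr = ehr, fits = fits, extremes = extremes)
    })
    say("survival: n=%d; HetRate p (all) = %.3g", res$fits$all$n,
        res$fits$all$coefficients$p[res$fits$all$coefficients$term == "HetRate"])
    tables$survival_fits <- do.call(rbind, lapply(names(res$fits), function(s)
      cbind(subset = s, res$fits[[s]]$coefficients)))
    log_stage("survival", n_all = res$fits$all$n)
    out$survival <- res
  }

  ## enrichment ------------------------------------------------------------
  if (config$enrich$enabled) {
    res <- run_stage("enrich", {
      ns <- snps_panel$snp_id[snps_panel$annotation_class == "nonsynonymous"]
      sub <- hs[match(ns, hs$snp_id), ]
      fa <- setNames(sub$f_a, sub$snp_id)
      fb <- setNames(sub$f_b, sub$snp_id)
      snp_to_gene <- setNames(snps_panel$gene, snps_panel$snp_id)
      tops <- exclusive_sets(select_top_decile(fa, config$enrich$q),
                             select_top_decile(fb, config$enrich$q),
                             snp_to_gene)
      background <- unique(snp_to_gene[ns])
      gmts <- config$enrich$gmt
      if (!is.list(gmts)) gmts <- setNames(as.list(gmts),
                                           sub("\\.gmt$", "", basename(gmts)))
      enr <- do.call(rbind, lapply(names(gmts), function(cl) {
        coll <- read_gene_sets(gmts[[cl]], collection_name = cl)
        rbind(cbind(cohort = lv[1],
                    hypergeom_enrichment(tops$genes_a, background, coll, cl)),
              cbind(cohort = lv[2],
                    hypergeom_enrichment(tops$genes_b, background, coll, cl)))
      }))
      list(tops = tops, enrichment = enr)
    })
    say("enrich: %d x %d exclusive top SNPs", length(res$tops$exclusive_a),
        length(res$tops$exclusive_b))
    tables$enrichment <- res$enrichment
    log_stage("enrich", n_top_a = length(res$tops$exclusive_a),
              n_top_b = length(res$tops$exclusive_b))
    out$enrichment <- res
  }

  ## outputs ---------------------------------------------------------------
  paths <- write_results(tables, config$out_dir)
  manifest$outputs <- lapply(seq_along(paths), function(i)
    list(table = names(paths)[i], path = unname(paths[i]),
         md5 = unname(tools::md5sum(paths[i]))))
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest[c("seed", "stages", "outputs")], mpath,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  out$panel <- panel
  invisible(out)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the arguments of [run_config()]; a `sim` block is passed
#' to [sim_config()] and a `qc` block to [qc_config()].
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a [run_config()] object.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$qc)) raw$qc <- do.call(qc_config, raw$qc)
  do.call(run_config, raw)
}
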