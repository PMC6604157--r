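#' Select the top decile of excess heterozygosity
#'
#' SNPs whose excess of heterozygosity F reaches the `k`-th largest value,
#' with `k = ceiling(q * n)` (the empirical order-statistic upper-tail
#' threshold). All SNPs tied at the threshold are included, so the set may
#' exceed `k`.
#'
#' @param f named numeric vector of per-SNP F values for one cohort (names
#'   are SNP ids).
#' @param q upper tail fraction (default 0.10).
#' @return character vector of SNP ids.
#' @export
select_top_decile <- function(f, q = 0.10) {
  if (!length(f)) stop("empty panel")
  k <- ceiling(q * length(f))
  thr <- sort(f, decreasing = TRUE)[k]
  names(f)[f >= thr]
}

#' Exclusive top-SNP sets and their genes
#'
#' Removes the SNPs shared by the two cohorts' top sets, then maps each
#' exclusive set to its distinct gene symbols (SNPs without a gene
#' annotation are dropped and counted).
#'
#' @param top_a,top_b character vectors of top SNP ids per cohort.
#' @param snp_to_gene named character vector mapping SNP id to gene symbol
#'   (NA or "" = unannotated).
#' @return list of class `top_snp_sets`: `shared`, `exclusive_a`,
#'   `exclusive_b`, `genes_a`, `genes_b`, `n_unannotated` (named, per
#'   cohort).
#' @export
exclusive_sets <- function(top_a, top_b, snp_to_gene) {
  shared <- intersect(top_a, top_b)
  ex_a <- setdiff(top_a, shared)
  ex_b <- setdiff(top_b, shared)
  genes_of <- function(ids) {
    gg <- snp_to_gene[ids]
    gg <- gg[!is.na(gg) & nzchar(gg)]
    unique(unname(gg))
  }
  drop_n <- function(ids) sum(is.na(snp_to_gene[ids]) |
                                !nzchar(snp_to_gene[ids]))
  structure(list(shared = shared, exclusive_a = ex_a, exclusive_b = ex_b,
                 genes_a = genes_of(ex_a), genes_b = genes_of(ex_b),
                 n_unannotated = c(a = drop_n(ex_a), b = drop_n(ex_b))),
            class = "top_snp_sets")
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set in the collection, intersects the set with the
#' background (sets with empty intersection are skipped), counts the overlap
#' `k` with the query, and reports the one-sided over-representation tail
#' `P(X >= k)` with `X ~ Hypergeom(N, K, n)` where `N` is the background
#' size, `K` the set size within the background and `n` the query size.
#' Benjamini-Hochberg q-values are computed within the collection; rows are
#' sorted by p.
#'
#' @param query_genes genes of interest (must be a subset of the background).
#' @param background_genes the gene universe.
#' @param collection named list of gene sets (see [read_gene_sets()]).
#' @param collection_name label carried into the output.
#' @return data.frame: `collection`, `set_name`, `k`, `set_size` (K),
#'   `query_size` (n), `background_size` (N), `p`, `q`.
#' @export
hypergeom_enrichment <- function(query_genes, background_genes, collection,
                                 collection_name = "collection") {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  if (!length(query_genes)) stop("empty query gene list")
  extra <- setdiff(query_genes, background_genes)
  if (length(extra))
    stop("query genes outside the background: ",
         paste(head(extra, 5), collapse = ", "))
  N <- length(background_genes); n <- length(query_genes)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], background_genes)
    if (!length(s)) return(NULL)
    K <- length(s)
    k <- length(intersect(query_genes, s))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(collection = collection_name, set_name = nm, k = k,
               set_size = K, query_size = n, background_size = N,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(collection = character(), set_name = character(),
                      k = integer(), set_size = integer(),
                      query_size = integer(), background_size = integer(),
                      p = numeric(), q = numeric()))
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Compare a numeric SNP score between two SNP sets
#'
#' Two-sided Mann-Whitney U test of a per-SNP score (for example a
#' user-supplied conservation or deleteriousness annotation) between two
#' SNP sets, or between one set and the rest of the panel.
#'
#' @param scores named numeric vector of per-SNP scores.
#' @param set_a SNP ids of the first set.
#' @param set_b SNP ids of the second set; if NULL, all scored SNPs outside
#'   `set_a` are used.
#' @param labels length-2 character for direction phrasing.
#' @return a [test_result()] row.
#' @export
score_set_comparison <- function(scores, set_a, set_b = NULL,
                                 labels = c("A", "rest")) {
  if (is.null(set_b)) set_b <- setdiff(names(scores), set_a)
  xa <- scores[set_a]; xb <- scores[set_b]
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (!length(xa) || !length(xb)) stop("a compared set is empty")
  if (length(unique(c(xa, xb))) == 1)
    return(test_result("mann_whitney", NA_real_, 1, "none",
                       note = "tie-degenerate"))
  wt <- suppressWarnings(wilcox.test(xa, xb))
  dir <- if (median(xa) > median(xb)) paste0(labels[1], "-higher")
         else if (median(xa) < median(xb)) paste0(labels[2], "-higher")
         else "none"
  test_result("mann_whitney", unname(wt$statistic), wt$p.value, dir)
}
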