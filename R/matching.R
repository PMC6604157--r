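#' Principal component analysis of a genotype panel
#'
#' PCA of mean-centred, per-SNP unit-variance dosages, computed from the
#' sample-by-sample Gram matrix (efficient when SNPs far outnumber samples,
#' and identical to the standard SVD route). Zero-variance SNPs are dropped.
#' Each component's sign is fixed so that its largest-magnitude SNP loading
#' is positive, making scores deterministic across linear-algebra backends.
#'
#' @param g a [cohort_genotypes] object.
#' @param k number of components to retain (must not exceed the rank).
#' @param panel optional SNP id subset.
#' @return list of class `pca_result`: `scores` (samples x k, row names are
#'   sample ids), `var_explained` (fraction per component, non-increasing),
#'   `k`.
#' @export
run_pca <- function(g, k = 6L, panel = NULL) {
  d <- g$dosage
  if (!is.null(panel)) d <- d[, panel, drop = FALSE]
  if (!ncol(d)) stop("empty panel")
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 samples")
  storage.mode(d) <- "double"
  mu <- colMeans(d)
  sdv <- sqrt(colMeans(d^2) - mu^2)
  ok <- sdv > 0
  x <- sweep(d[, ok, drop = FALSE], 2, mu[ok])
  x <- sweep(x, 2, sdv[ok], "/")
  gram <- tcrossprod(x)
  eg <- eigen(gram, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-9
  rank <- sum(pos)
  if (k > rank) stop("k = ", k, " exceeds the rank (", rank, ")")
  scores <- eg$vectors[, seq_len(k), drop = FALSE] *
    rep(sqrt(pmax(eg$values[seq_len(k)], 0)), each = n)
  # sign convention via the dominant SNP loading of each component
  for (j in seq_len(k)) {
    ld <- crossprod(x, eg$vectors[, j])
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(g$dosage)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 var_explained = eg$values[seq_len(k)] / sum(pmax(eg$values, 0)),
                 k = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples, k=%d, var explained: %s\n",
              nrow(x$scores), x$k,
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " ")))
  invisible(x)
}

#' Weighted PC-score distance between two samples
#'
#' Sum over the first `n_components` principal components of the absolute
#' score difference multiplied by that component's variance-explained
#' weight: `sum_j |a_j - b_j| * w_j`. An L2 variant squares the differences
#' instead.
#'
#' @param a,b score vectors covering at least `n_components` entries.
#' @param weights per-component weights (variance explained).
#' @param n_components number of leading components used (default 6).
#' @param metric "l1" (default) or "l2".
#' @return non-negative distance; zero iff the leading coordinates agree.
#' @export
match_distance <- function(a, b, weights, n_components = 6L,
                           metric = c("l1", "l2")) {
  metric <- match.arg(metric)
  if (length(a) < n_components || length(b) < n_components ||
      length(weights) < n_components)
    stop("vectors must cover at least n_components entries")
  j <- seq_len(n_components)
  d <- abs(a[j] - b[j])
  if (metric == "l2") d <- d^2
  sum(d * weights[j])
}

# dense nA x nB weighted distance matrix over leading components
distance_matrix <- function(sa, sb, weights, n_components, metric) {
  D <- matrix(0, nrow(sa), nrow(sb))
  for (j in seq_len(n_components)) {
    dj <- abs(outer(sa[, j], sb[, j], `-`))
    if (metric == "l2") dj <- dj^2
    D <- D + weights[j] * dj
  }
  D
}

#' Greedy PC-distance matching of two cohorts
#'
#' Sequentially pairs each cohort-A sample, visited in random order, with
#' the nearest still-unmatched cohort-B sample under [match_distance()].
#' The procedure is restarted `n_restarts` times with different visiting
#' orders and the pairing with the smallest total distance is returned, so
#' the total is non-increasing in the number of restarts.
#'
#' @param pca a [run_pca()] result covering both cohorts.
#' @param ids_a,ids_b sample ids of the two cohorts (`length(ids_b) >=
#'   length(ids_a)`).
#' @param n_restarts number of random visiting orders (default 10).
#' @param seed integer seed making the restarts reproducible.
#' @param n_components,metric see [match_distance()].
#' @return list of class `matched_pairs`: `pairs` (data.frame `id_a`,
#'   `id_b`, `distance`), `total_distance`, `n_restarts`.
#' @export
greedy_match <- function(pca, ids_a, ids_b, n_restarts = 10L, seed = NULL,
                         n_components = 6L, metric = c("l1", "l2")) {
  metric <- match.arg(metric)
  if (length(ids_a) > length(ids_b))
    stop("cohort A must not be larger than cohort B")
  if (pca$k < n_components) stop("PCA has fewer than n_components components")
  if (!is.null(seed)) set.seed(seed)
  sa <- pca$scores[ids_a, seq_len(n_components), drop = FALSE]
  sb <- pca$scores[ids_b, seq_len(n_components), drop = FALSE]
  D <- distance_matrix(sa, sb, pca$var_explained, n_components, metric)
  na <- length(ids_a)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    ord <- sample.int(na)
    free <- rep(TRUE, length(ids_b))
    mate <- integer(na)
    total <- 0
    for (i in ord) {
      row <- D[i, ]
      row[!free] <- Inf
      j <- which.min(row)  # ties: first (smallest B index), deterministic
      mate[i] <- j
      free[j] <- FALSE
      total <- total + row[[j]]
    }
    if (is.null(best) || total < best$total) best <- list(mate = mate, total = total)
  }
  pairs <- data.frame(id_a = ids_a, id_b = ids_b[best$mate],
                      distance = D[cbind(seq_len(na), best$mate)],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, total_distance = best$total,
                 n_restarts = n_restarts),
            class = "matched_pairs")
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(sprintf("<matched_pairs> %d pairs, total distance %.4g\n",
              nrow(x$pairs), x$total_distance))
  invisible(x)
}

#' Drop poorly matched pairs
#'
#' @param pairs a [greedy_match()] result.
#' @param max_distance retain pairs with distance at or below this. The
#'   appropriate cutoff depends on the score units of the data set at hand;
#'   no default is imposed.
#' @return a `matched_pairs` object with the retained pairs.
#' @export
filter_pairs <- function(pairs, max_distance) {
  keep <- pairs$pairs$distance <= max_distance
  structure(list(pairs = pairs$pairs[keep, , drop = FALSE],
                 total_distance = sum(pairs$pairs$distance[keep]),
                 n_restarts = pairs$n_restarts),
            class = "matched_pairs")
}

#' Genomic inflation factor
#'
#' `lambda_gc`: the median of per-SNP 1-df association chi-square statistics
#' divided by the median of the 1-df chi-square distribution (0.4549364).
#' Values near 1 indicate no systematic inflation from population structure.
#'
#' @param chi2_stats non-negative 1-df statistics, e.g. `allelic_test()$chisq`.
#' @return list: `lambda_gc`, `n_tests`.
#' @export
genomic_inflation <- function(chi2_stats) {
  if (!length(chi2_stats)) stop("no statistics supplied")
  if (any(chi2_stats < 0)) stop("chi-square statistics must be non-negative")
  list(lambda_gc = median(chi2_stats) / qchisq(0.5, df = 1),
       n_tests = length(chi2_stats))
}

#' Restrict a genotype object to a sample subset
#'
#' Convenience used after matching: keeps the listed samples (e.g. the
#' matched pairs) and re-derives the minor-allele orientation on the new
#' combined cohort.
#'
#' @param g a [cohort_genotypes] object.
#' @param sample_ids samples to keep.
#' @return a [cohort_genotypes] object.
#' @export
subset_samples <- function(g, sample_ids) {
  idx <- match(sample_ids, rownames(g$dosage))
  if (anyNA(idx)) stop("unknown sample id(s)")
  g2 <- cohort_genotypes(g$dosage[idx, , drop = FALSE],
                         droplevels(g$cohort[idx]), g$snps)
  recode_minor(g2)
}
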