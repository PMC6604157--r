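#' Read two-cohort genotypes
#'
#' Reads biallelic SNP hard calls from a GT-only VCF subset (via vcfR) or
#' from the package's TSV genotype dialect (one SNP per row; columns
#' `snp_id`, `chrom`, `pos`, `ref`, `alt`, then one dosage column per
#' sample counting ALT copies). Multiallelic or non-SNP records are
#' rejected and counted. Phase is ignored ("0/1" and "1|0" are the same
#' dosage). Dosages are recoded so that stored values count the
#' combined-cohort minor allele; at a frequency tie of exactly 0.5 the
#' lexicographically smaller allele string is designated minor.
#'
#' @param path input file.
#' @param dialect "vcf" or "tsv".
#' @param cohort_labels named character vector mapping every sample id to
#'   one of two cohort names.
#' @return list: `genotypes` (a [cohort_genotypes]), `n_rejected` (records
#'   dropped as multiallelic/non-SNP).
#' @export
read_genotypes <- function(path, dialect = c("vcf", "tsv"), cohort_labels) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    snp_ok <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
      nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
    n_rejected <- sum(!snp_ok)
    if (!any(snp_ok)) stop("no biallelic SNP records in ", path)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gt[snp_ok, , drop = FALSE]
    fix <- fix[snp_ok, , drop = FALSE]
    gt <- gsub("|", "/", gt, fixed = TRUE)
    code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    bad <- !(gt %in% c(names(code), "./.", NA))
    if (any(bad)) stop("unparseable genotype call(s): ",
                       paste(head(unique(gt[bad]), 3), collapse = ", "))
    dosage <- matrix(code[gt], nrow = nrow(gt), dimnames = dimnames(gt))
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    snps <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                       alt = fix[, "ALT"], minor_allele = fix[, "ALT"],
                       stringsAsFactors = FALSE)
    dosage <- t(dosage)
  } else {
    tab <- data.table::fread(path, sep = "\t", header = TRUE,
                             data.table = FALSE)
    need <- c("snp_id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tab)))
      stop("TSV genotype dialect needs columns: ", paste(need, collapse = ", "))
    snp_ok <- nchar(tab$ref) == 1 & nchar(tab$alt) == 1 &
      !grepl(",", tab$alt, fixed = TRUE)
    n_rejected <- sum(!snp_ok)
    tab <- tab[snp_ok, , drop = FALSE]
    if (!nrow(tab)) stop("no biallelic SNP records in ", path)
    sample_cols <- setdiff(names(tab), need)
    dosage <- t(as.matrix(tab[, sample_cols, drop = FALSE]))
    colnames(dosage) <- tab$snp_id
    snps <- data.frame(snp_id = tab$snp_id, chrom = as.character(tab$chrom),
                       pos = as.integer(tab$pos), ref = tab$ref,
                       alt = tab$alt, minor_allele = tab$alt,
                       stringsAsFactors = FALSE)
  }
  samples <- rownames(dosage)
  miss <- setdiff(samples, names(cohort_labels))
  if (length(miss))
    stop("samples without a cohort label: ", paste(head(miss, 5), collapse = ", "))
  colnames(dosage) <- snps$snp_id
  g <- cohort_genotypes(dosage, factor(cohort_labels[samples]), snps)
  list(genotypes = recode_minor(g), n_rejected = n_rejected)
}

#' Write two-cohort genotypes
#'
#' Writes the VCF subset (GT field only, genotypes phrased against the
#' stored `ref`/`alt` alleles) or the TSV genotype dialect read by
#' [read_genotypes()].
#'
#' @param g a [cohort_genotypes] object.
#' @param path output file.
#' @param dialect "vcf" or "tsv".
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  snps <- g$snps
  # dosage of the ALT allele, whatever the current minor orientation
  d_alt <- g$dosage
  flip <- snps$minor_allele != snps$alt
  if (any(flip)) d_alt[, flip] <- 2L - d_alt[, flip]
  if (dialect == "tsv") {
    tab <- data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
                      pos = snps$pos, ref = snps$ref, alt = snps$alt,
                      t(d_alt), check.names = FALSE,
                      stringsAsFactors = FALSE)
    data.table::fwrite(tab, path, sep = "\t", quote = FALSE, na = "NA")
  } else {
    gt_code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(d_alt), ncol(d_alt))
    ok <- !is.na(d_alt)
    gt[ok] <- gt_code[d_alt[ok] + 1L]
    lines <- c("##fileformat=VCFv4.2",
               "##source=hetspan",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d_alt)), collapse = "\t"))
    # per-record lines: fixed fields then one GT per sample
    body <- paste(snps$chrom, snps$pos, snps$snp_id, snps$ref, snps$alt,
                  ".", "PASS", ".", "GT",
                  apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated name, description, then
#' gene symbols. Duplicate set names and sets with no genes are errors.
#'
#' @param path GMT file.
#' @param collection_name label; defaults to the file name without extension.
#' @return named list of character vectors with attribute `collection`.
#' @export
read_gene_sets <- function(path,
                           collection_name = sub("\\.gmt$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(nms))
    stop("duplicate gene set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(seq_along(parts), function(i) {
    genes <- parts[[i]][-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("gene set '", nms[i], "' (line ", i, ") has no genes")
    unique(genes)
  })
  names(sets) <- nms
  attr(sets, "collection") <- collection_name
  sets
}

#' Write stage result tables
#'
#' Writes each table of a named list as `<name>.tsv` in `out_dir` (created
#' if needed), with a header row of documented column names. Empty tables
#' yield header-only files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory.
#' @return named character vector of file paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    data.table::fwrite(as.data.frame(tables[[nm]]), p, sep = "\t",
                       quote = FALSE, na = "NA")
    p
  }, character(1))
  invisible(paths)
}

#' Read a result table written by [write_results()]
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_result <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

#' Read an EHR table
#'
#' TSV with columns `sample_id`, `age`, `gender`, `conditions`
#' (semicolon-separated Charlson condition ids, empty for none) and
#' optionally `survival_10yr`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_ehr <- function(path) {
  ehr <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE,
                           colClasses = list(character = "conditions"))
  need <- c("sample_id", "age", "gender", "conditions")
  miss <- setdiff(need, names(ehr))
  if (length(miss)) stop("EHR table lacks columns: ",
                         paste(miss, collapse = ", "))
  ehr$conditions[is.na(ehr$conditions)] <- ""
  ehr
}
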