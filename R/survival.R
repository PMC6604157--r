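#' The Charlson condition catalogue
#'
#' Point values for the 16 clinical condition families entering the Charlson
#' comorbidity score, with severity variants (uncomplicated vs end-organ
#' diabetes, local vs metastatic solid tumor, mild vs moderate/severe liver
#' disease) as distinct identifiers. Only one variant per family may be
#' present in a record.
#'
#' @return named integer vector of point values.
#' @export
charlson_catalogue <- function() {
  c(myocardial_infarction = 1L, congestive_heart_failure = 1L,
    peripheral_vascular_disease = 1L, cerebrovascular_disease = 1L,
    dementia = 1L, copd = 1L, connective_tissue_disease = 1L,
    peptic_ulcer_disease = 1L,
    diabetes_uncomplicated = 1L, diabetes_end_organ = 2L,
    ckd_moderate_severe = 2L, hemiplegia = 2L, leukemia = 2L,
    malignant_lymphoma = 2L,
    solid_tumor = 2L, solid_tumor_metastatic = 6L,
    liver_mild = 1L, liver_moderate_severe = 3L,
    aids = 6L)
}

# severity families: at most one member per record
charlson_families <- list(
  diabetes = c("diabetes_uncomplicated", "diabetes_end_organ"),
  solid_tumor = c("solid_tumor", "solid_tumor_metastatic"),
  liver = c("liver_mild", "liver_moderate_severe"))

#' Charlson age points
#'
#' Ages at or below 40 score 0 points; closed decade bands 41-50, 51-60,
#' 61-70, 71-80 score 1-4. Fractional ages are floored to whole years before
#' banding. Scoring does not apply above age 80.
#'
#' @param age age in years (scalar).
#' @return integer points in 0..4.
#' @export
age_points <- function(age) {
  stopifnot(length(age) == 1, is.finite(age))
  age <- floor(age)
  if (age > 80) stop("Charlson scoring does not apply above age 80")
  if (age <= 40) return(0L)
  as.integer(ceiling((age - 40) / 10))
}

#' Charlson comorbidity points
#'
#' Sum of catalogue point values over a condition set. Unknown identifiers
#' and conflicting severity variants within one condition family are errors.
#'
#' @param conditions character vector of condition ids (may be empty).
#' @return integer total.
#' @export
comorbidity_points <- function(conditions) {
  if (!length(conditions)) return(0L)
  cat <- charlson_catalogue()
  unknown <- setdiff(conditions, names(cat))
  if (length(unknown))
    stop("unknown condition id(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(conditions)) stop("duplicated condition id")
  for (fam in charlson_families)
    if (sum(conditions %in% fam) > 1)
      stop("conflicting severity variants: ", paste(fam, collapse = " / "))
  sum(cat[conditions])
}

#' Charlson 10-year survival probability
#'
#' `Z = 0.983 ^ exp((A + C) * 0.9)` where `A` is the age score and `C` the
#' comorbidity score. `Z` lies in (0, 0.983] and is strictly decreasing in
#' `A + C`.
#'
#' For large `A + C` the probability underflows double precision; `log =
#' TRUE` returns `log(Z) = exp((A + C) * 0.9) * log(0.983)`, which is exact
#' over the whole score grid and preserves the strict ordering.
#'
#' @param A age points (vectorised).
#' @param C comorbidity points (vectorised).
#' @param log return the log survival probability.
#' @return numeric survival probabilities (or their logs).
#' @export
charlson_probability <- function(A, C, log = FALSE) {
  stopifnot(all(A >= 0), all(C >= 0))
  lz <- exp((A + C) * 0.9) * log(0.983)
  if (log) lz else exp(lz)
}

# parse "a;b;c" condition strings into per-record vectors
split_conditions <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(v)])
}

#' Charlson scores for an EHR table
#'
#' @param ehr data.frame with `sample_id`, `age`, `gender`, `conditions`
#'   (semicolon-separated ids).
#' @return data.frame `sample_id`, `age_points`, `comorbidity_points`,
#'   `survival_prob`.
#' @export
charlson_scores <- function(ehr) {
  A <- vapply(ehr$age, age_points, integer(1))
  C <- vapply(split_conditions(ehr$conditions), comorbidity_points, integer(1))
  data.frame(sample_id = ehr$sample_id, age_points = A,
             comorbidity_points = C,
             survival_prob = charlson_probability(A, C),
             stringsAsFactors = FALSE)
}

#' Regress 10-year survival probability on heterozygosity rate
#'
#' Ordinary least squares of the 10-year survival probability on
#' heterozygosity rate, age, comorbidity score, gender (female = 1; dropped
#' in per-gender fits) and the first five principal components:
#' `10ySP ~ HetRate + age + comorbidity + gender + PC1 + ... + PC5`.
#' Note the comorbidity score enters both the Charlson response and the
#' design matrix, as in the published model; the resulting collinearity with
#' the response is reported, not resolved.
#'
#' @param ehr EHR data.frame (`sample_id`, `age`, `gender`, `conditions`,
#'   optionally `survival_10yr`).
#' @param het named numeric vector of per-sample heterozygosity rates (names
#'   are sample ids), e.g. from [het_rate()].
#' @param pcs a [run_pca()] result with at least 5 components (its `scores`
#'   row names are sample ids), or NULL to omit PC covariates.
#' @param subset one of "all", "male", "female".
#' @param response "charlson" recomputes the Charlson probability from the
#'   EHR; "recorded" uses the `survival_10yr` column (e.g. a simulated
#'   outcome with known injected effect).
#' @return list of class `survival_fit`: `coefficients` (data.frame `term`,
#'   `estimate`, `se`, `p`), `n`, `subset`, `degenerate` (TRUE if the design
#'   was rank deficient; dropped columns in `dropped`), and the underlying
#'   `lm` fit.
#' @export
regress_survival <- function(ehr, het, pcs = NULL,
                             subset = c("all", "male", "female"),
                             response = c("charlson", "recorded")) {
  subset <- match.arg(subset)
  response <- match.arg(response)
  ehr <- ehr[ehr$age <= 80 & ehr$age > 40 &
               ehr$gender %in% c("male", "female"), , drop = FALSE]
  if (subset != "all") ehr <- ehr[ehr$gender == subset, , drop = FALSE]
  sc <- charlson_scores(ehr)
  y <- if (response == "charlson") sc$survival_prob else {
    if (is.null(ehr$survival_10yr)) stop("no recorded `survival_10yr` column")
    ehr$survival_10yr
  }
  df <- data.frame(y = y, HetRate = unname(het[ehr$sample_id]),
                   age = ehr$age, comorbidity = sc$comorbidity_points)
  if (subset == "all") df$gender <- as.integer(ehr$gender == "female")
  if (!is.null(pcs)) {
    sco <- pcs$scores[ehr$sample_id, 1:5, drop = FALSE]
    colnames(sco) <- paste0("PC", 1:5)
    df <- cbind(df, sco)
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < ncol(df) + 2)
    stop("too few eligible samples (", nrow(df), ") for the model")
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  dropped <- setdiff(names(coef(fit)), rownames(sm))
  na_coef <- names(coef(fit))[is.na(coef(fit))]
  degenerate <- length(na_coef) > 0
  co <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                   p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = co, n = nrow(df), subset = subset,
                 degenerate = degenerate,
                 dropped = union(dropped, na_coef), fit = fit),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> subset=%s n=%d%s\n", x$subset, x$n,
              if (x$degenerate) paste0(" [rank deficient: ",
                                       paste(x$dropped, collapse = ", "), "]")
              else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Compare heterozygosity between extreme survival groups
#'
#' Within an age band, two-sided Mann-Whitney U test of heterozygosity rates
#' between individuals with Charlson survival probability below `z_low` and
#' those above `z_high`, optionally per gender.
#'
#' @inheritParams regress_survival
#' @param age_band inclusive `c(low, high)` age range.
#' @param z_low,z_high survival-probability cutoffs defining the groups.
#' @return a `test_result` data.frame (see [test_result()]); if either group
#'   is empty, `p` is NA and `note` records the skip.
#' @export
extreme_group_comparison <- function(ehr, het, age_band = c(51, 60),
                                     z_low = 0.10, z_high = 0.90,
                                     subset = c("all", "male", "female")) {
  subset <- match.arg(subset)
  ehr <- ehr[ehr$age >= age_band[1] & ehr$age <= age_band[2], , drop = FALSE]
  if (subset != "all") ehr <- ehr[ehr$gender == subset, , drop = FALSE]
  if (!nrow(ehr))
    return(test_result("mann_whitney", NA_real_, NA_real_, "none",
                       note = "empty age band"))
  z <- charlson_scores(ehr)$survival_prob
  lo <- het[ehr$sample_id[z < z_low]]
  hi <- het[ehr$sample_id[z > z_high]]
  if (!length(lo) || !length(hi))
    return(test_result("mann_whitney", NA_real_, NA_real_, "none",
                       note = "empty extreme group"))
  wt <- suppressWarnings(wilcox.test(hi, lo))
  dir <- if (median(hi) > median(lo)) "high-survival-higher"
         else if (median(hi) < median(lo)) "low-survival-higher" else "none"
  test_result("mann_whitney", unname(wt$statistic), wt$p.value, dir)
}
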