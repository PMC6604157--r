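---
title: "Comparing genomic heterozygosity between matched cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing genomic heterozygosity between matched cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetspan)
```

## The scientific question

Heterozygosity–fitness correlations are widely documented across taxa: more
heterozygous individuals tend to be healthier. In humans, one way to probe
this is to compare a healthy-aged cohort against a general-population cohort
genotyped on a shared panel of biallelic autosomal SNPs. If heterozygotes
enjoy an advantage, the healthy-aged cohort should show an *excess of
heterozygosity* — more heterozygotes than Hardy–Weinberg equilibrium (HWE)
predicts from its allele frequencies — even when the allele frequencies
themselves are indistinguishable between the cohorts.

`hetspan` implements that comparison end to end: per-SNP heterozygosity
statistics, genotype-ratio association scans with an exact binomial
meta-test, PCA-based genetic matching with genomic-control diagnostics, a
permutation null for the individual heterozygosity rate, Charlson 10-year
survival modelling against EHR-like records, and top-decile gene-set
enrichment. Because the motivating cohort data are access-restricted, the
package ships a synthetic-data generator that reproduces the statistical
structure every stage assumes, so the whole pipeline is testable offline.

## Per-SNP statistics

For each SNP and cohort, with hard-call genotype counts
$(n_{\mathrm{hom\,major}}, n_\mathrm{het}, n_{\mathrm{hom\,minor}})$ and
$n$ individuals:

* minor-allele frequency $p = (2 n_{\mathrm{hom\,minor}} + n_\mathrm{het}) / 2n$,
  with the minor allele defined on the cohorts *combined* (ties at exactly
  0.5 go to the lexicographically smaller allele string, so orientation is
  deterministic);
* observed heterozygosity $\mathrm{HET_O} = n_\mathrm{het} / n$;
* expected heterozygosity $\mathrm{HET_E} = 2p(1-p)$;
* excess of heterozygosity $F = (\mathrm{HET_O} - \mathrm{HET_E}) / \mathrm{HET_E}$.

$F$ is zero at exact HWE, positive under heterozygote excess, and — unlike
$\mathrm{HET_O}$ — essentially decoupled from allele frequency, which is why
the cohort comparisons focus on it.

## Tests and their conventions

Several tests are exact and discrete, and their two-sided conventions
matter for reproducibility:

* **Fisher exact test (2×2)**: the two-sided p sums the probabilities of
  all tables with the observed margins whose conditional probability does
  not exceed the observed table's ("minlike", the convention of mainstream
  implementations). Used for the genotype-ratio scans (heterozygote vs
  minor-allele-homozygote counts across cohorts, and the het vs
  major-homozygote and allelic variants). Implemented in C++ because scans
  touch millions of tables; `stats::fisher.test` serves as the oracle in the
  test suite, never as the scan path.
* **Exact binomial meta-test**: at each nominal level the scan's
  significant SNPs are split by direction and the split is tested against
  Binomial(n, 1/2), two-sided by the same minimal-likelihood rule
  (`stats::binom.test`). This convention reproduces published worked
  examples of the meta-test to their printed two significant figures, which
  settled the open choice between exact and normal-approximate forms.
* **HWE exact test**: conditional on allele counts, the heterozygote-count
  distribution is enumerated and the two-sided p sums outcomes no more
  probable than the observed one. QC applies it to the combined cohorts by
  default (`hwe_scope = "per_cohort"` is available), matching the combined
  scope of the MAF filter.
* **Paired cohort comparisons** use the Wilcoxon signed-rank test on
  per-SNP differences (zero differences dropped; exact null for ≤ 25
  non-zero differences without ties, normal approximation with continuity
  correction otherwise).
* **Permutation p-values** use the add-one convention
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$, so an observation
  outside the whole null range reports the minimal achievable p rather
  than 0.

## QC and LD pruning

`qc_filter()` retains SNPs that, in order: share alleles across cohorts;
carry at least one minor allele in *each* cohort; have no missing
genotypes; are autosomal and outside a configurable excluded interval (the
MHC stand-in; 1-based inclusive coordinates); pass the HWE exact test at
p > 0.001; and have combined MAF above 1%. Each excluded SNP is attributed
to the first criterion it fails, making the exclusion report a reproducible
accounting. The filter is idempotent.

`ld_prune()` slides a 50-SNP window in 5-SNP steps over the
position-sorted panel and, within each window, repeatedly drops the
later-positioned SNP of the worst pair while any retained pair has squared
dosage correlation ≥ 0.5. Correlation is composite (dosage-level) r², the
appropriate quantity for unphased hard calls; ties break toward the larger
position, then the larger id, for determinism.

## Genetic matching and genomic control

Population structure inflates cohort-comparison statistics. `run_pca()`
computes PCA of per-SNP standardized dosages via the sample-level Gram
matrix (equivalent to the SVD route, and cheap when SNPs far outnumber
samples); each component's sign is pinned by its dominant loading so
results do not depend on the linear-algebra backend.

The matching distance between two individuals sums, over the first six
components, the absolute score difference weighted by that component's
variance-explained fraction. We read the published recipe's "eigenvalue
differences" as differences of per-individual *scores* (projections):
eigenvalues are per-component constants and would yield a degenerate
all-zero distance, so scores are the only per-individual quantity the
recipe can mean. Absolute rather than squared differences are used
(an L2 option exists behind `metric = "l2"`), and raw scores are weighted
by variance explained; a variance-normalized variant would change pair
sets only through the weighting scale.

`greedy_match()` visits the smaller cohort in random order, pairs each
sample with the nearest unmatched sample of the larger cohort, repeats for
`n_restarts = 10` random orders, and keeps the pairing with the smallest
total distance, which is therefore non-increasing in the number of
restarts. Greedy matching is the published procedure; the test suite
bounds it against a brute-force optimal assignment on small instances but
the optimum is deliberately not the default. A distance cutoff for
discarding poor pairs is supported but has no default: its scale is
data-set specific.

Matching efficacy is diagnosed with the genomic inflation factor
$\lambda_{gc}$ = median of per-SNP 1-df allelic $\chi^2$ statistics divided
by 0.4549364 (the 1-df $\chi^2$ median). The package's structured
simulations reproduce the qualitative pattern of substantial inflation
before matching collapsing to ≈ 1 after.

## Individual heterozygosity rate and its permutation null

The individual heterozygosity rate is the proportion of heterozygous sites
a sample carries on a fixed common-SNP panel (noncoding, combined
MAF > 0.1 by default; MAF > 0.25 as the robustness alternative). With a
shared panel and no missing calls, no standardisation is needed.

The null asks: if the two cohorts were exchangeable, how extreme would a
cohort's mean rate be? Pseudo-cohorts are formed by sampling, independently
per SNP column, `nA` of the combined `nA + nB` genotypes without
replacement. The recorded statistic — the pseudo-cohort's mean rate —
depends on a permuted column only through how many of its heterozygotes
land in the pseudo-cohort, which is exactly hypergeometric given the
column's heterozygote total. The implementation therefore draws one
hypergeometric variate per column per permutation: identical in law to
permuting full columns, and fast enough for the conventional 10,000
permutations. One-sided p-values are reported for both cohorts on both
sides, matching the directional phrasing such comparisons usually take.

## Charlson survival modelling

Eligibility follows the usual Charlson constraints: ages above 80 are not
scorable and are excluded, as are records with unknown gender. Age points
are 0 for ≤ 40 and 1–4 for the closed decade bands 41–50 through 71–80
(fractional ages floored, since the bands are stated in whole years). The
condition catalogue is frozen to a 16-family list with severity variants
(diabetes with end-organ damage, metastatic solid tumor, moderate/severe
liver disease) as distinct identifiers — published Charlson variants differ
in wording, and a fixed catalogue keeps scores stable. The 10-year
survival probability is

$$Z = 0.983^{\,e^{0.9\,(A + C)}}.$$

$Z$ underflows double precision for large $A + C$ (it is below 1e-300 by
$A + C = 8$), so `charlson_probability(..., log = TRUE)` evaluates
$\log Z = e^{0.9(A+C)} \log 0.983$ exactly; monotonicity checks are run on
that scale.

`regress_survival()` fits OLS of the survival probability on
heterozygosity rate, age, comorbidity score, gender (female = 1, pooled
model only) and the first five PCs, with classical t-test p-values. Note a
modelling quirk inherited from the published analysis: the comorbidity
score appears both inside the response (through $Z$) and as a predictor.
The fit reports that collinearity with the response rather than resolving
it. Rank-deficient designs are flagged with the offending columns named.

## The synthetic-data generator

`simulate_cohort_pair()` draws a shared panel of biallelic SNPs on a
single pseudo-autosome (1 kb spacing), with minor-allele frequencies
uniform on [0.01, 0.5] — flat coverage of all four MAF strata used in the
stratified analyses. Genotypes follow an inbreeding-style law: with
frequency $p$ and per-cohort coefficient $f$,
$P(\mathrm{het}) = 2p(1-p)(1-f)$ and the homozygote classes absorb
$p(1-p)f$ each, so $f < 0$ yields heterozygote excess with $E[F] \approx -f$.
$f$ may be a function of MAF and annotation class, which is how the tests
inject excess only into common SNPs of one cohort. Combinations where a
genotype probability would be negative are rejected.

Ancestry structure uses the Balding–Nichols law: subpopulation frequencies
are Beta-distributed around the ancestral frequency with spread set by
$F_{ST}$, and the two cohorts may mix subpopulations unequally. The
package's structured scenario (cohorts of 639 and 213, $F_{ST} = 0.01$,
65/35 versus 35/65 mixing) was sized from the standard inflation
approximation so that the unmatched comparison is clearly inflated while a
matched subset is not; it is fixed once, not tuned per run.

Annotations are synthetic but structurally faithful: genes tile the panel
in blocks of five SNPs; fractions of SNPs are labelled nonsynonymous,
disease- or trait-associated; fractions of genes are labelled
recessive/dominant. An optional masked interval stands in for the MHC so
the exclusion filter is exercised, and an optional block-copy mode
duplicates adjacent columns with noise purely to exercise the LD pruner —
it is not a realistic LD model, and no coalescent machinery is attempted.

Linked EHR records carry age (uniform in a configurable window inside
41–80), gender, and conditions drawn per record from configurable
prevalences. Two linkage knobs connect heterozygosity to health:
`het_link` tilts every condition's log-odds by the standardized
heterozygosity rate (a qualitative comorbidity pathway), and `het_beta`
adds a linear heterozygosity term (optionally per gender) plus Gaussian
noise to the *recorded* survival outcome. The second knob exists because a
purely categorical comorbidity pathway cannot encode an exact linear
slope, and OLS coverage recovery needs a known ground truth;
`regress_survival(response = "recorded")` targets that column, while the
default recomputes the Charlson probability as the real analysis does.

What passing tests on this generator do *not* show: robustness to real
LD beyond the toy block copies, to genotyping-platform batch effects, to
missingness (the generator emits complete calls), or to realistic
age-by-comorbidity dependence (conditions are age-independent by design).

## Problem sizes and numerical choices

The test suite exercises the study-scale design of two cohorts of 426 on
20,000-SNP panels, with replicate counts (50–200 per property) chosen for
stable Monte-Carlo estimates; the matching scenario uses 639 + 213 samples,
and survival recovery runs at n = 359 with 200 replicates. Exact-test
implementations are compared against exhaustive enumeration oracles on
more than a thousand small instances. Probability comparisons inside the
exact tests use a 1e-7 relative tolerance when collecting outcomes "as or
less probable" than the observed one, the same guard mainstream
implementations use against floating-point ties.

One calibration property is worth stating plainly: exact conditional tests
are conservative on discrete data. At combined MAF near 0.01 a cohort of
426 carries almost no minor-allele homozygotes, so many het-vs-hom-minor
tables are degenerate and the per-SNP rejection rate at nominal
$\alpha = 0.05$ over a uniform-MAF panel sits around 0.04 rather than
0.05. This is a property of the exact test itself, not a coding artefact;
the count-asymmetry meta-test, which only consumes directions of
already-significant SNPs, holds its size regardless.

## Known limitations

* The generator's per-SNP $f$ magnitudes are chosen for test power; the
  magnitudes in real cohorts are unknown.
* Recovery scenarios inject effects by the generator's (true) MAF while the
  analysis stratifies by observed combined MAF, so an effect confined to
  one MAF range bleeds slightly into the adjacent observed-MAF bin for
  SNPs near the boundary — visible as a mildly sub-uniform p distribution
  in that bin.
* Genotype ingestion covers a GT-only VCF subset and a TSV dialect; BGEN,
  PLINK binary, imputation dosages and indels are out of scope.
* Sample-level QC (call rate, relatedness, sex checks) is assumed done
  upstream.
* Enrichment is simple over-representation (hypergeometric with BH-FDR
  within each collection); ranked GSEA-style analysis is out of scope.
* The pipeline entry points are R functions (`run_pipeline()` with a
  YAML/JSON config); there is no shell executable.
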