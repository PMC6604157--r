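#include <Rcpp.h>
using namespace Rcpp;

// Two-sided Fisher exact p for a 2x2 table by the "minlike" convention:
// sum of probabilities of all tables (with the observed margins) whose
// conditional probability does not exceed that of the observed table,
// within a small relative tolerance (as fisher.test uses).
static double fet2x2_one(int a, int b, int c, int d) {
  const int r1 = a + b, c1 = a + c, n = a + b + c + d;
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return 1.0; // degenerate margin
  const int lo = std::max(0, r1 + c1 - n);
  const int hi = std::min(r1, c1);
  // log P(X = x) for the noncentral cell, hypergeometric with these margins
  const double lden = R::lchoose(n, r1);
  const double lobs = R::lchoose(c1, a) + R::lchoose(n - c1, r1 - a) - lden;
  const double cutoff = lobs + 1e-7;
  double p = 0.0;
  for (int x = lo; x <= hi; ++x) {
    double lp = R::lchoose(c1, x) + R::lchoose(n - c1, r1 - x) - lden;
    if (lp <= cutoff) p += std::exp(lp);
  }
  return std::min(p, 1.0);
}

// [[Rcpp::export(name = ".fet2x2_p")]]
NumericVector fet2x2_p(IntegerVector a, IntegerVector b,
                       IntegerVector c, IntegerVector d) {
  R_xlen_t m = a.size();
  if (b.size() != m || c.size() != m || d.size() != m)
    stop("count vectors must have equal length");
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    if (a[i] < 0 || b[i] < 0 || c[i] < 0 || d[i] < 0)
      stop("negative count in 2x2 table");
    out[i] = fet2x2_one(a[i], b[i], c[i], d[i]);
  }
  return out;
}

// Exact test of Hardy-Weinberg equilibrium: two-sided p from the
// conditional distribution of the heterozygote count given the minor
// allele count (Wigginton-style enumeration over same-parity counts).
static double hwe_one(int hom_min, int het, int hom_maj) {
  const int n = hom_min + het + hom_maj;
  const int n_minor = 2 * hom_min + het;          // minor allele count
  const int n1 = std::min(n_minor, 2 * n - n_minor);
  if (n1 == 0) return 1.0;                        // monomorphic: single outcome
  // heterozygote counts share the parity of the minor allele count
  const int h_lo = n1 % 2;
  const int h_hi = n1;                            // at most n1 hets
  const int nh = (h_hi - h_lo) / 2 + 1;
  std::vector<double> prob(nh);
  // unnormalised recurrence: P(h+2)/P(h) = [ (nA-h)(nB-h) ] / [ (h+2)(h+1+... ]
  // with nA = n1 minor, nB = 2n - n1 major alleles:
  // P(h) proportional to  n! / (n_mm! n_h! n_MM!) * 2^h  with
  // n_mm = (n1-h)/2, n_MM = (2n-n1-h)/2.
  int idx_mode = 0;
  double lmax = -1e300;
  for (int i = 0; i < nh; ++i) {
    int h = h_lo + 2 * i;
    int mm = (n1 - h) / 2;
    int MM = n - mm - h;
    double lp = R::lgammafn(n + 1.0) - R::lgammafn(mm + 1.0) -
                R::lgammafn(h + 1.0) - R::lgammafn(MM + 1.0) +
                h * M_LN2;
    prob[i] = lp;
    if (lp > lmax) { lmax = lp; idx_mode = i; }
  }
  (void)idx_mode;
  double tot = 0.0;
  for (int i = 0; i < nh; ++i) { prob[i] = std::exp(prob[i] - lmax); tot += prob[i]; }
  const int iobs = (het - h_lo) / 2;
  const double pobs = prob[iobs];
  double p = 0.0;
  for (int i = 0; i < nh; ++i)
    if (prob[i] <= pobs * (1.0 + 1e-7)) p += prob[i];
  return std::min(p / tot, 1.0);
}

// [[Rcpp::export(name = ".hwe_exact_p")]]
NumericVector hwe_exact_p(IntegerVector hom_min, IntegerVector het,
                          IntegerVector hom_maj) {
  R_xlen_t m = hom_min.size();
  if (het.size() != m || hom_maj.size() != m)
    stop("count vectors must have equal length");
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    if (hom_min[i] < 0 || het[i] < 0 || hom_maj[i] < 0)
      stop("negative genotype count");
    if (hom_min[i] + het[i] + hom_maj[i] == 0)
      stop("all-zero genotype counts");
    out[i] = hwe_one(hom_min[i], het[i], hom_maj[i]);
  }
  return out;
}

// Sample hard-call dosages for one homogeneous group: per-SNP cumulative
// genotype probabilities (P(hom major), P(hom major)+P(het)); returns an
// m x n matrix of minor-allele counts. Uses R's RNG, so draws are
// reproducible under set.seed().
// [[Rcpp::export(name = ".sample_dosage")]]
IntegerMatrix sample_dosage_cpp(NumericVector cum0, NumericVector cum1, int n) {
  const R_xlen_t m = cum0.size();
  if (cum1.size() != m) stop("probability vectors must have equal length");
  IntegerMatrix out(m, n);
  RNGScope scope;
  for (int j = 0; j < n; ++j) {
    int *col = &out(0, j);
    for (R_xlen_t i = 0; i < m; ++i) {
      double u = unif_rand();
      col[i] = (u > cum0[i]) + (u > cum1[i]);
    }
  }
  return out;
}

// Per-SNP genotype counts (hom-major/het/hom-minor) split by a two-level
// cohort factor, in one pass over the dosage matrix. NAs are skipped.
// [[Rcpp::export(name = ".count_dosage")]]
List count_dosage_cpp(IntegerMatrix dosage, IntegerVector cohort) {
  const int n = dosage.nrow(), m = dosage.ncol();
  if (cohort.size() != n) stop("cohort length must match samples");
  IntegerMatrix a(m, 3), b(m, 3);
  for (int j = 0; j < m; ++j) {
    const int *col = &dosage(0, j);
    int ca[3] = {0, 0, 0}, cb[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      int d = col[i];
      if (d == NA_INTEGER) continue;
      if (d < 0 || d > 2) stop("dosage outside 0..2");
      if (cohort[i] == 1) ++ca[d]; else ++cb[d];
    }
    for (int k = 0; k < 3; ++k) { a(j, k) = ca[k]; b(j, k) = cb[k]; }
  }
  return List::create(a, b);
}
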