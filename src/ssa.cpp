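#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Species column order shared with the R layer (see .gc_species in R/network.R):
// 0 CD40, 1 AKT, 2 FOXO1, 3 cRel, 4 RelA, 5 MYC, 6 AP4, 7 CXCR4, 8 CXCR5,
// 9 BLIMP1, 10 BclxL, 11 Casp3.
//
// Rate-vector order (see .rate_vector in R/network.R):
//  0 k_cd40   1 d_cd40   2 k_akt    3 d_akt    4 k_foxo   5 d_foxo
//  6 g_akt    7 K_akt    8 k_crel   9 d_crel  10 k_myc   11 d_myc
// 12 K_foxo  13 k_ap4   14 d_ap4   15 k_cxcr4 16 d_cxcr4 17 K_f2
// 18 k_cxcr5 19 d_cxcr5 20 k_blimp 21 d_blimp 22 k_bclxl 23 d_bclxl
// 24 d_rela  25 k_casp  26 d_casp  27 d_cxcr4_off (active downregulation
// once the cell-cycle commitment gate closes)  28 K_myc_ap4 (saturation of
// AP4 induction by MYC)

#define NSPEC 12
#define NREACT 24

// saturating occupancy x / (K + x), defined as 0 when the denominator is 0
static inline double hill(double x, double K) {
  double den = K + x;
  return den > 0.0 ? x / den : 0.0;
}

// Exact SSA (Gillespie direct method) over the B-cell network for every row
// of M, advancing each cell independently by `dt` time units with its signal
// inputs held constant. M is modified in place.
//' @noRd
// [[Rcpp::export(name = ".cpp_ssa_advance")]]
void cpp_ssa_advance(NumericMatrix M, NumericVector aff, NumericVector pmhc,
                     IntegerVector fdc, IntegerVector tfh,
                     IntegerVector cxcr4_gate, IntegerVector apo,
                     double dt, NumericVector r) {
  RNGScope scope;
  const int ncell = M.nrow();
  if (M.ncol() != NSPEC) stop("molecular state matrix must have 12 columns");
  double a[NREACT];
  // reaction -> (species, +1/-1)
  static const int rspec[NREACT]  = {0,0, 1,1, 2,2, 3,3, 4, 5,5, 6,6,
                                     7,7, 8,8, 9,9, 10,10, 11,11, 4};
  static const int rsign[NREACT]  = {1,-1, 1,-1, 1,-1, 1,-1, -1, 1,-1, 1,-1,
                                     1,-1, 1,-1, 1,-1, 1,-1, 1,-1, 1};
  // last slot (index 23) is a dummy zero-propensity RelA production so the
  // reaction table stays rectangular; RelA is switched on by rule in R.

  for (int i = 0; i < ncell; ++i) {
    double s[NSPEC];
    for (int j = 0; j < NSPEC; ++j) s[j] = M(i, j);
    double bcr = aff[i] / 10.0;
    if (bcr > 1.0) bcr = 1.0;
    if (bcr < 0.0) bcr = 0.0;
    double t = 0.0;
    for (;;) {
      a[0]  = r[0] * (tfh[i] ? pmhc[i] : 0.0);          // CD40 production
      a[1]  = r[1] * s[0];                               // CD40 decay
      a[2]  = r[2] * (fdc[i] ? bcr : 0.0);               // AKT production
      a[3]  = r[3] * s[1];                               // AKT decay
      a[4]  = r[4];                                      // FOXO1 production
      a[5]  = r[5] * s[2] * (1.0 + r[6] * hill(s[1], r[7])); // FOXO1 decay, AKT-boosted
      a[6]  = r[8] * s[0] / 100.0;                       // cRel production (CD40-driven)
      a[7]  = r[9] * s[3];                               // cRel decay
      a[8]  = r[24] * s[4];                              // RelA decay (rule-set level)
      a[9]  = r[10] * (s[3] / 100.0) * (1.0 - hill(s[2], r[12])); // MYC production: cRel AND low FOXO1
      a[10] = r[11] * s[5];                              // MYC decay
      a[11] = r[13] * hill(s[5], r[28]);                 // AP4 production (integrates MYC, saturable)
      a[12] = r[14] * s[6];                              // AP4 decay
      a[13] = r[15] * (cxcr4_gate[i] ? hill(s[2], r[17]) : 0.0); // CXCR4 production
      a[14] = (cxcr4_gate[i] ? r[16] : r[27]) * s[7];    // CXCR4 decay / active downregulation
      a[15] = r[18];                                     // CXCR5 production (constitutive)
      a[16] = r[19] * s[8];                              // CXCR5 decay
      a[17] = r[20] * s[4] / 100.0;                      // BLIMP1 production (RelA-driven)
      a[18] = r[21] * s[9];                              // BLIMP1 decay
      a[19] = r[22] * s[3] / 100.0;                      // BclxL production (cRel-driven)
      a[20] = r[23] * s[10];                             // BclxL decay
      a[21] = r[25] * (apo[i] ? 1.0 : 0.0);              // Casp3 production
      a[22] = r[26] * s[11];                             // Casp3 decay
      a[23] = 0.0;

      double a0 = 0.0;
      for (int j = 0; j < NREACT; ++j) {
        if (ISNAN(a[j]) || a[j] < 0.0)
          stop("negative or non-finite propensity in reaction %d", j + 1);
        a0 += a[j];
      }
      if (!(a0 > 0.0)) break;
      double tau = -std::log(unif_rand()) / a0;
      t += tau;
      if (t > dt) break;
      double u = unif_rand() * a0, cum = 0.0;
      int j = 0;
      for (; j < NREACT - 1; ++j) { cum += a[j]; if (u < cum) break; }
      s[rspec[j]] += rsign[j];
      if (s[rspec[j]] < 0.0) s[rspec[j]] = 0.0;
    }
    for (int j = 0; j < NSPEC; ++j) M(i, j) = s[j];
  }
}
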