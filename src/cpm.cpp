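#include <Rcpp.h>
#include <utility>
#include <set>
#include <vector>
using namespace Rcpp;

// Cell-type codes shared with the R layer:
// 0 = medium, 1 = B cell, 2 = CRC, 3 = FDC, 4 = Tfh.
// Per-id vectors (vol, tvol, typecode, lam12, lam13) are indexed by cell id,
// i.e. element id-1 describes cell id; id 0 is the medium and has no entry.

static inline int type_of(int id, const IntegerVector& typecode) {
  return id == 0 ? 0 : typecode[id - 1];
}

static inline bool is_stationary(int tc) { return tc >= 2; }

// Metropolis acceptance rule used by the sweep; exposed for direct testing.
static inline bool accept_move(double dH, double temp) {
  if (dH <= 0.0) return true;
  if (temp <= 0.0) return false;
  return unif_rand() < std::exp(-dH / temp);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_metropolis_trials")]]
int cpp_metropolis_trials(double dH, double temp, int n) {
  RNGScope scope;
  int acc = 0;
  for (int i = 0; i < n; ++i) if (accept_move(dH, temp)) ++acc;
  return acc;
}

// One Monte Carlo step: `nattempts` random pixel-copy attempts under the
// Hamiltonian H = sum_J contact + lambda_vol * sum (v - V_t)^2 with a
// chemotaxis bias -lam * (c(target) - c(source)) for the invading B cell.
// `lat` and `vol` are modified in place. Copy candidates come from the
// 8-neighbourhood; contact energy uses the 4-neighbourhood.
//' @noRd
// [[Rcpp::export(name = ".cpp_cpm_sweep")]]
List cpp_cpm_sweep(IntegerMatrix lat, IntegerVector vol, NumericVector tvol,
                   IntegerVector typecode,
                   NumericVector lam12, NumericVector lam13,
                   NumericMatrix f12, NumericMatrix f13,
                   NumericMatrix J, double temp, double lambda_vol,
                   int nattempts, double sat12 = 0.0, double sat13 = 0.0) {
  RNGScope scope;
  const int gx = lat.nrow(), gy = lat.ncol();
  static const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  static const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  static const int dx4[4] = {1, -1, 0, 0};
  static const int dy4[4] = {0, 0, 1, -1};
  long accepted = 0, lastpix_rejects = 0;

  for (int a = 0; a < nattempts; ++a) {
    int sx = (int)(unif_rand() * gx); if (sx == gx) sx = gx - 1;
    int sy = (int)(unif_rand() * gy); if (sy == gy) sy = gy - 1;
    int k = (int)(unif_rand() * 8); if (k == 8) k = 7;
    int tx = sx + dx8[k], ty = sy + dy8[k];
    if (tx < 0 || tx >= gx || ty < 0 || ty >= gy) continue;

    int s_id = lat(sx, sy), o_id = lat(tx, ty);
    if (s_id == o_id) continue;
    int ts = type_of(s_id, typecode), to = type_of(o_id, typecode);
    if (is_stationary(ts) || is_stationary(to)) continue;
    if (o_id != 0 && vol[o_id - 1] <= 1) { ++lastpix_rejects; continue; }

    // contact energy around the target pixel
    double dH = 0.0;
    for (int m = 0; m < 4; ++m) {
      int nx = tx + dx4[m], ny = ty + dy4[m];
      if (nx < 0 || nx >= gx || ny < 0 || ny >= gy) continue;
      int nid = lat(nx, ny);
      int tn = type_of(nid, typecode);
      if (nid != o_id) dH -= J(to, tn);
      if (nid != s_id) dH += J(ts, tn);
    }

    // volume constraint
    if (s_id != 0) {
      double d = vol[s_id - 1] - tvol[s_id - 1];
      dH += lambda_vol * ((d + 1.0) * (d + 1.0) - d * d);
    }
    if (o_id != 0) {
      double d = vol[o_id - 1] - tvol[o_id - 1];
      dH += lambda_vol * ((d - 1.0) * (d - 1.0) - d * d);
    }

    // chemotaxis of the invading B cell; optional saturable (log-sensing)
    // response dc / (K + c) flattens the bias across the field
    if (s_id != 0 && ts == 1) {
      double dc12 = f12(tx, ty) - f12(sx, sy);
      double dc13 = f13(tx, ty) - f13(sx, sy);
      if (sat12 > 0.0) dc12 /= (sat12 + f12(sx, sy));
      if (sat13 > 0.0) dc13 /= (sat13 + f13(sx, sy));
      dH -= lam12[s_id - 1] * dc12 + lam13[s_id - 1] * dc13;
    }

    if (accept_move(dH, temp)) {
      lat(tx, ty) = s_id;
      if (s_id != 0) ++vol[s_id - 1];
      if (o_id != 0) --vol[o_id - 1];
      ++accepted;
    }
  }
  return List::create(_["accepted"] = (double)accepted,
                      _["lastpixel_rejects"] = (double)lastpix_rejects);
}

// Full lattice scan: per-cell pixel counts and centroids, plus the set of
// distinct cell pairs sharing a 4-neighbourhood boundary.
//' @noRd
// [[Rcpp::export(name = ".cpp_lattice_scan")]]
List cpp_lattice_scan(IntegerMatrix lat, int maxid) {
  const int gx = lat.nrow(), gy = lat.ncol();
  NumericVector cx(maxid), cy(maxid);
  IntegerVector cnt(maxid);
  std::set<std::pair<int, int> > pairs;

  for (int y = 0; y < gy; ++y) {
    for (int x = 0; x < gx; ++x) {
      int id = lat(x, y);
      if (id > 0) {
        cx[id - 1] += x + 1;  // 1-based pixel coordinates on the R side
        cy[id - 1] += y + 1;
        ++cnt[id - 1];
      }
      // right and up neighbours cover each 4-neighbour pair once
      if (x + 1 < gx) {
        int b = lat(x + 1, y);
        if (id != b && id > 0 && b > 0)
          pairs.insert(std::make_pair(std::min(id, b), std::max(id, b)));
      }
      if (y + 1 < gy) {
        int b = lat(x, y + 1);
        if (id != b && id > 0 && b > 0)
          pairs.insert(std::make_pair(std::min(id, b), std::max(id, b)));
      }
    }
  }
  for (int i = 0; i < maxid; ++i) {
    if (cnt[i] > 0) { cx[i] /= cnt[i]; cy[i] /= cnt[i]; }
    else { cx[i] = NA_REAL; cy[i] = NA_REAL; }
  }
  int np = pairs.size();
  IntegerVector pa(np), pb(np);
  int i = 0;
  for (std::set<std::pair<int, int> >::iterator it = pairs.begin();
       it != pairs.end(); ++it, ++i) {
    pa[i] = it->first; pb[i] = it->second;
  }
  return List::create(_["count"] = cnt, _["cx"] = cx, _["cy"] = cy,
                      _["pair_a"] = pa, _["pair_b"] = pb);
}
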