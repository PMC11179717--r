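#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler secretion-diffusion-decay update with zero-flux (Neumann)
// boundaries:  c <- c + dt * (D * lap(c) - k * c + src).
// `conc` is modified in place; `src` holds the secretion rate per pixel.
//' @noRd
// [[Rcpp::export(name = ".cpp_diffuse_steps")]]
void cpp_diffuse_steps(NumericMatrix conc, NumericMatrix src,
                       double D, double k, double dt, int nsteps) {
  const int gx = conc.nrow(), gy = conc.ncol();
  NumericMatrix nxt(gx, gy);
  for (int step = 0; step < nsteps; ++step) {
    for (int y = 0; y < gy; ++y) {
      for (int x = 0; x < gx; ++x) {
        double c = conc(x, y);
        double w = (x > 0)      ? conc(x - 1, y) : c;  // zero-flux: mirror
        double e = (x < gx - 1) ? conc(x + 1, y) : c;
        double s = (y > 0)      ? conc(x, y - 1) : c;
        double n = (y < gy - 1) ? conc(x, y + 1) : c;
        double lap = w + e + s + n - 4.0 * c;
        double v = c + dt * (D * lap - k * c + src(x, y));
        nxt(x, y) = v > 0.0 ? v : 0.0;
      }
    }
    for (int y = 0; y < gy; ++y)
      for (int x = 0; x < gx; ++x) conc(x, y) = nxt(x, y);
  }
}
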