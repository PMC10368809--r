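#include <Rcpp.h>
using namespace Rcpp;

// Pairwise Gibbs energy seen by cell i at position (x, y):
//   E_i = -sum_{j != i, d_ij < range} strength(ph_i, ph_j)
// so positive strength rewards proximity (attraction) and negative strength
// penalises it (repulsion). Hard-core overlaps have infinite energy.
static double localEnergy(int i, double x, double y,
                          const NumericVector& px, const NumericVector& py,
                          const IntegerVector& phen, const NumericMatrix& S,
                          double range2, int n) {
  double e = 0.0;
  const int pi_ = phen[i];
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    const double dx = px[j] - x, dy = py[j] - y;
    if (dx * dx + dy * dy < range2) e -= S(pi_, phen[j]);
  }
  return e;
}

// Metropolis sweeps over cell positions under the pairwise Gibbs potential.
// pts: n x 2 positions (microns); phen: 0-based phenotype codes;
// S: K x K interaction strengths; candidates: m x 2 admissible (tissue)
// positions proposals are drawn from, jittered within +/- jitter/2.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".gibbsSweeps")]]
NumericMatrix gibbsSweeps(NumericMatrix pts, IntegerVector phen,
                          NumericMatrix S, double range, double hardcore,
                          int sweeps, NumericMatrix candidates,
                          double jitter) {
  const int n = pts.nrow(), m = candidates.nrow();
  NumericVector px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = pts(i, 0); py[i] = pts(i, 1); }
  const double range2 = range * range, hc2 = hardcore * hardcore;

  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      int idx = (int)(unif_rand() * m);
      if (idx >= m) idx = m - 1;
      const double nx = candidates(idx, 0) + (unif_rand() - 0.5) * jitter;
      const double ny = candidates(idx, 1) + (unif_rand() - 0.5) * jitter;
      bool ok = true;
      for (int j = 0; j < n && ok; ++j) {
        if (j == i) continue;
        const double dx = px[j] - nx, dy = py[j] - ny;
        if (dx * dx + dy * dy < hc2) ok = false;
      }
      if (!ok) continue;
      const double dE =
        localEnergy(i, nx, ny, px, py, phen, S, range2, n) -
        localEnergy(i, px[i], py[i], px, py, phen, S, range2, n);
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
        px[i] = nx; py[i] = ny;
      }
    }
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; }
  return out;
}
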