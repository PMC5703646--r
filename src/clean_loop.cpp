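#include <Rcpp.h>
using namespace Rcpp;

// Iterative CLEAN loop on one release frame.
//
// Repeatedly locates the global maximum pixel (ties broken towards the
// smallest row, then the smallest column), stops when it is <= threshold,
// otherwise subtracts a copy of the ACO centred there (edge-cropped) and
// increments that pixel's count.
//
// A per-column running maximum (value + smallest achieving row) makes each
// iteration O(W + patch) instead of O(H*W): after a subtraction only the
// columns whose stored maximum row falls inside the subtracted patch need a
// rescan, since values outside the patch are untouched and values inside
// only decrease.
// [[Rcpp::export]]
List clean_frame_cpp(NumericMatrix release, NumericMatrix aco,
                     double threshold, double max_iterations) {
  const int H = release.nrow(), W = release.ncol();
  const int ah = aco.nrow(), aw = aco.ncol();
  const int ra = (ah - 1) / 2, ca = (aw - 1) / 2;

  NumericMatrix res(clone(release));
  IntegerMatrix counts(H, W);
  std::vector<double> colmax(W);
  std::vector<int> colrow(W);

  for (int c = 0; c < W; ++c) {
    double m = res(0, c); int mr = 0;
    for (int r = 1; r < H; ++r)
      if (res(r, c) > m) { m = res(r, c); mr = r; }
    colmax[c] = m; colrow[c] = mr;
  }

  double iter = 0;
  bool converged = true;
  while (true) {
    // global maximum over column maxima, row-major tie-break
    int bc = 0, br = colrow[0];
    double bv = colmax[0];
    for (int c = 1; c < W; ++c) {
      double v = colmax[c];
      if (v > bv || (v == bv && colrow[c] < br)) {
        bv = v; br = colrow[c]; bc = c;
      }
    }
    if (!(bv > threshold)) break;  // also stops on NaN
    if (iter >= max_iterations) { converged = false; break; }
    ++iter;
    counts(br, bc) += 1;

    const int r0 = std::max(0, br - ra), r1 = std::min(H - 1, br + ra);
    const int c0 = std::max(0, bc - ca), c1 = std::min(W - 1, bc + ca);
    for (int c = c0; c <= c1; ++c) {
      for (int r = r0; r <= r1; ++r)
        res(r, c) -= aco(r - br + ra, c - bc + ca);
      if (colrow[c] >= r0 && colrow[c] <= r1) {
        double m = res(0, c); int mr = 0;
        for (int r = 1; r < H; ++r)
          if (res(r, c) > m) { m = res(r, c); mr = r; }
        colmax[c] = m; colrow[c] = mr;
      }
    }
  }

  return List::create(_["counts"] = counts, _["residual"] = res,
                      _["iterations"] = iter, _["converged"] = converged);
}

// Add count * ACO at every non-zero count position (the "rebuild" splat).
// [[Rcpp::export]]
NumericMatrix splat_counts_cpp(IntegerMatrix counts, NumericMatrix aco) {
  const int H = counts.nrow(), W = counts.ncol();
  const int ra = (aco.nrow() - 1) / 2, ca = (aco.ncol() - 1) / 2;
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      const int k = counts(r, c);
      if (k == 0) continue;
      const int r0 = std::max(0, r - ra), r1 = std::min(H - 1, r + ra);
      const int c0 = std::max(0, c - ca), c1 = std::min(W - 1, c + ca);
      for (int cc = c0; cc <= c1; ++cc)
        for (int rr = r0; rr <= r1; ++rr)
          out(rr, cc) += k * aco(rr - r + ra, cc - c + ca);
    }
  return out;
}
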