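#include <Rcpp.h>
using namespace Rcpp;

// Exact weighted decision-stump search.
//
// X:   n x p feature matrix.
// ord: n x p matrix of 0-based row indices sorting each column ascending
//      (precomputed once; X and the sample weights change roles, not order).
// y:   labels in {-1, +1}.
// w:   non-negative sample weights.
//
// Candidate thresholds are midpoints between consecutive distinct sorted
// values of each feature. A stump predicts `polarity` where x > threshold
// and `-polarity` otherwise. Returns the stump with minimal weighted error;
// ties resolve to the first feature, then the lowest threshold, then
// polarity +1, so the search is fully deterministic.
// [[Rcpp::export]]
List best_stump_cpp(NumericMatrix X, IntegerMatrix ord,
                    NumericVector y, NumericVector w) {
  const int n = X.nrow(), p = X.ncol();
  double w_pos = 0.0, w_neg = 0.0;
  for (int i = 0; i < n; ++i) {
    if (y[i] > 0) w_pos += w[i]; else w_neg += w[i];
  }
  double best_err = R_PosInf, best_thr = NA_REAL;
  int best_feat = -1, best_pol = 1;

  for (int j = 0; j < p; ++j) {
    // cum_pos/cum_neg: weight of +/- samples with x <= current threshold
    double cum_pos = 0.0, cum_neg = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      const int i = ord(k, j);
      if (y[i] > 0) cum_pos += w[i]; else cum_neg += w[i];
      const double xk = X(i, j), xk1 = X(ord(k + 1, j), j);
      if (xk1 <= xk) continue;               // not a value boundary
      const double thr = 0.5 * (xk + xk1);
      // polarity +1: predict +1 where x > thr
      const double err_pos = cum_pos + (w_neg - cum_neg);
      const double err_neg = (w_pos + w_neg) - err_pos;
      if (err_pos < best_err) {
        best_err = err_pos; best_feat = j; best_thr = thr; best_pol = 1;
      }
      if (err_neg < best_err) {
        best_err = err_neg; best_feat = j; best_thr = thr; best_pol = -1;
      }
    }
  }
  return List::create(_["feature_index"] = best_feat + 1,
                      _["threshold"] = best_thr,
                      _["polarity"] = best_pol,
                      _["error"] = best_err);
}

// 8-connectivity connected-component labeling (two-pass union-find).
// Components are numbered 1..K in raster-scan order (row-major, top-left
// first pixel), matching the usual blob-detection convention.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent;
  parent.reserve(256);
  // provisional labels, stored 1-based in lab; parent[] is 0-based
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c)) continue;
      int neigh[4], nn = 0;  // already-visited 8-neighbors
      if (r > 0) {
        if (c > 0 && lab(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1) - 1;
        if (lab(r - 1, c)) neigh[nn++] = lab(r - 1, c) - 1;
        if (c < W - 1 && lab(r - 1, c + 1)) neigh[nn++] = lab(r - 1, c + 1) - 1;
      }
      if (c > 0 && lab(r, c - 1)) neigh[nn++] = lab(r, c - 1) - 1;
      if (nn == 0) {
        parent.push_back((int)parent.size());
        lab(r, c) = (int)parent.size();
      } else {
        int root = uf_find(parent, neigh[0]);
        for (int k = 1; k < nn; ++k) {
          int r2 = uf_find(parent, neigh[k]);
          if (r2 < root) { parent[root] = r2; root = r2; }
          else parent[r2] = root;
        }
        lab(r, c) = root + 1;
      }
    }
  }
  // second pass: map roots to final labels in row-major first-pixel order
  std::vector<int> final_lab(parent.size(), 0);
  int next = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!lab(r, c)) continue;
      int root = uf_find(parent, lab(r, c) - 1);
      if (final_lab[root] == 0) final_lab[root] = ++next;
      lab(r, c) = final_lab[root];
    }
  }
  return lab;
}
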