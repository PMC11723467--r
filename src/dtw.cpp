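#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming alignment distance with absolute-difference local cost.
// C(i,j) = |a_i - b_j| + min(C(i-1,j), C(i,j-1), C(i-1,j-1)), returned value C(n,m).
static double dtw_pair(const double *a, int n, const double *b, int m,
                       std::vector<double> &row) {
  row.resize(m);
  double up, diag;
  for (int j = 0; j < m; ++j)
    row[j] = std::abs(a[0] - b[j]) + (j > 0 ? row[j - 1] : 0.0);
  for (int i = 1; i < n; ++i) {
    diag = row[0];
    row[0] += std::abs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      up = row[j];
      double best = diag < up ? diag : up;
      if (row[j - 1] < best) best = row[j - 1];
      row[j] = std::abs(a[i] - b[j]) + best;
      diag = up;
    }
  }
  return row[m - 1];
}

// [[Rcpp::export(name = ".dtw_distance_cpp")]]
double dtw_distance_cpp(NumericVector a, NumericVector b) {
  if (a.size() == 0 || b.size() == 0)
    stop("dtw_distance: empty input sequence");
  std::vector<double> row;
  return dtw_pair(a.begin(), a.size(), b.begin(), b.size(), row);
}

// Channel-weighted DTW distance of one segment against every bank entry.
// seg: ns x nc matrix; bank: numeric array with dim (ns, nc, ne) flattened
// column-major; weights: length nc. Returns length-ne vector of summed
// per-channel DTW distances.
// [[Rcpp::export(name = ".dtw_field_cpp")]]
NumericVector dtw_field_cpp(NumericMatrix seg, NumericVector bank,
                            IntegerVector bankdim, NumericVector weights) {
  int ns = bankdim[0], nc = bankdim[1], ne = bankdim[2];
  if (seg.nrow() != ns || seg.ncol() != nc)
    stop("segment dimensions do not match the prediction bank");
  if (weights.size() != nc) stop("one weight per channel required");
  NumericVector out(ne);
  std::vector<double> row;
  const double *bk = bank.begin();
  for (int e = 0; e < ne; ++e) {
    double d = 0.0;
    for (int c = 0; c < nc; ++c) {
      if (weights[c] == 0.0) continue;
      const double *bs = bk + (size_t)e * ns * nc + (size_t)c * ns;
      d += weights[c] * dtw_pair(&seg(0, c), ns, bs, ns, row);
    }
    out[e] = d;
  }
  return out;
}
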