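#include <Rcpp.h>
using namespace Rcpp;

// Dependent multi-dimensional DTW: local cost is the Euclidean norm across
// all feature dimensions at each frame pair; classic symmetric three-way
// step pattern (match/insert/delete, unit weights), no window constraint.
// Backtracking prefers the diagonal step on ties so identical inputs yield
// the main-diagonal warping path.

// [[Rcpp::export]]
List dtw_core(NumericMatrix A, NumericMatrix B, bool keep_cost) {
  const int n = A.nrow(), m = B.nrow(), J = A.ncol();
  if (n == 0 || m == 0) stop("empty input sequence");
  if (B.ncol() != J) stop("dimensionality mismatch");

  NumericMatrix local(n, m);
  for (int u = 0; u < n; ++u) {
    for (int v = 0; v < m; ++v) {
      double s = 0.0;
      for (int j = 0; j < J; ++j) {
        const double d = A(u, j) - B(v, j);
        s += d * d;
      }
      local(u, v) = std::sqrt(s);
    }
  }

  NumericMatrix D(n, m);
  D(0, 0) = local(0, 0);
  for (int u = 1; u < n; ++u) D(u, 0) = D(u - 1, 0) + local(u, 0);
  for (int v = 1; v < m; ++v) D(0, v) = D(0, v - 1) + local(0, v);
  for (int u = 1; u < n; ++u) {
    for (int v = 1; v < m; ++v) {
      double best = D(u - 1, v - 1);
      if (D(u - 1, v) < best) best = D(u - 1, v);
      if (D(u, v - 1) < best) best = D(u, v - 1);
      D(u, v) = local(u, v) + best;
    }
  }

  // Backtrack (diagonal preferred on ties).
  std::vector<int> pu, pv;
  int u = n - 1, v = m - 1;
  pu.push_back(u + 1); pv.push_back(v + 1);
  while (u > 0 || v > 0) {
    if (u == 0) {
      --v;
    } else if (v == 0) {
      --u;
    } else {
      const double diag = D(u - 1, v - 1), up = D(u - 1, v), left = D(u, v - 1);
      if (diag <= up && diag <= left) { --u; --v; }
      else if (up <= left) { --u; }
      else { --v; }
    }
    pu.push_back(u + 1); pv.push_back(v + 1);
  }
  const int L = static_cast<int>(pu.size());
  IntegerMatrix path(L, 2);
  for (int i = 0; i < L; ++i) {
    path(i, 0) = pu[L - 1 - i];
    path(i, 1) = pv[L - 1 - i];
  }

  return List::create(
    _["distance"] = D(n - 1, m - 1),
    _["path"] = path,
    _["cost"] = keep_cost ? SEXP(D) : R_NilValue,
    _["local"] = keep_cost ? SEXP(local) : R_NilValue
  );
}

// Row-major copy of an R matrix (frames contiguous within a row).
static std::vector<double> row_major(const NumericMatrix& M) {
  const int n = M.nrow(), J = M.ncol();
  std::vector<double> out(static_cast<size_t>(n) * J);
  for (int u = 0; u < n; ++u)
    for (int j = 0; j < J; ++j) out[static_cast<size_t>(u) * J + j] = M(u, j);
  return out;
}

// Distances from one probe feature matrix to a list of gallery feature
// matrices; avoids R-level loop overhead in the matching inner loop.
// [[Rcpp::export]]
NumericVector dtw_to_gallery(NumericMatrix probe, List gallery) {
  const int K = gallery.size();
  NumericVector out(K);
  const int n = probe.nrow(), J = probe.ncol();
  const std::vector<double> A = row_major(probe);
  for (int k = 0; k < K; ++k) {
    NumericMatrix Bm = gallery[k];
    if (Bm.ncol() != J) stop("dimensionality mismatch in gallery entry");
    const int m = Bm.nrow();
    const std::vector<double> B = row_major(Bm);
    std::vector<double> prev(m), cur(m);
    for (int u = 0; u < n; ++u) {
      const double* au = &A[static_cast<size_t>(u) * J];
      for (int v = 0; v < m; ++v) {
        const double* bv = &B[static_cast<size_t>(v) * J];
        double s = 0.0;
        for (int j = 0; j < J; ++j) {
          const double d = au[j] - bv[j];
          s += d * d;
        }
        const double lc = std::sqrt(s);
        if (u == 0 && v == 0) cur[v] = lc;
        else if (u == 0) cur[v] = cur[v - 1] + lc;
        else if (v == 0) cur[v] = prev[v] + lc;
        else {
          double best = prev[v - 1];
          if (prev[v] < best) best = prev[v];
          if (cur[v - 1] < best) best = cur[v - 1];
          cur[v] = lc + best;
        }
      }
      std::swap(prev, cur);
    }
    out[k] = prev[m - 1];
  }
  return out;
}
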