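#include <Rcpp.h>
using namespace Rcpp;

// Sum over rows of the minimum entry: the MEC contribution of a read set
// whose per-column mismatch counts are the rows of X.
// [[Rcpp::export(rng = false)]]
double rowMinSum(NumericMatrix X) {
  const int n = X.nrow(), k = X.ncol();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = X(i, 0);
    for (int p = 1; p < k; ++p) if (X(i, p) < m) m = X(i, p);
    acc += m;
  }
  return acc;
}

// For each permutation (row of `perms`, 1-based), the MEC contribution
// sum_i min_p ( A(i,p) + B(i, perm[p]) ).
// [[Rcpp::export(rng = false)]]
NumericVector rowMinSumPerm(NumericMatrix A, NumericMatrix B,
                            IntegerMatrix perms) {
  const int n = A.nrow(), k = A.ncol(), q = perms.nrow();
  NumericVector out(q);
  for (int c = 0; c < q; ++c) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = R_PosInf;
      for (int p = 0; p < k; ++p) {
        double v = A(i, p) + B(i, perms(c, p) - 1);
        if (v < m) m = v;
      }
      acc += m;
    }
    out[c] = acc;
  }
  return out;
}

// For each candidate allele assignment (row of `G`), the MEC-greedy score
// sum_i min_p ( base(i,p) + [a(i) != G(c,p)] ).
// [[Rcpp::export(rng = false)]]
NumericVector candScores(NumericMatrix base, IntegerVector a,
                         IntegerMatrix G) {
  const int n = base.nrow(), k = base.ncol(), q = G.nrow();
  NumericVector out(q);
  for (int c = 0; c < q; ++c) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = R_PosInf;
      for (int p = 0; p < k; ++p) {
        double v = base(i, p) + (a[i] != G(c, p) ? 1.0 : 0.0);
        if (v < m) m = v;
      }
      acc += m;
    }
    out[c] = acc;
  }
  return out;
}

// Best segment-relabeling move within one window. Pairs are ordered by
// boundary index; as the segment end advances one boundary at a time, each
// added pair updates only its own read's cached MEC contribution under every
// candidate permutation, so the sweep is linear in the window's pairs.
// Returns (delta, endBoundary, permIndex); permIndex = 0 if no improvement.
// [[Rcpp::export(rng = false)]]
NumericVector segWindowBest(NumericMatrix dt, IntegerVector pairBnd,
                            IntegerVector pairRead, IntegerMatrix mism,
                            IntegerMatrix perms) {
  const int T = dt.nrow(), k = dt.ncol(), np = pairBnd.size(),
            q = perms.nrow();
  std::vector<double> dm(static_cast<size_t>(T) * k, 0.0);
  std::vector<double> contrib(static_cast<size_t>(T) * q, 0.0);
  std::vector<char> seen(T, 0);
  double sumSnow = 0.0;
  std::vector<double> sumSalt(q, 0.0);
  double bestDelta = 0.0; int bestEnd = -1, bestPerm = 0;
  int i = 0;
  while (i < np) {
    const int b = pairBnd[i];
    for (; i < np && pairBnd[i] == b; ++i) {
      const int r = pairRead[i] - 1;
      if (!seen[r]) {
        seen[r] = 1;
        double m = dt(r, 0);
        for (int p = 1; p < k; ++p) if (dt(r, p) < m) m = dt(r, p);
        sumSnow += m;
        for (int c = 0; c < q; ++c) {
          contrib[r + static_cast<size_t>(T) * c] = m;
          sumSalt[c] += m;
        }
      }
      for (int p = 0; p < k; ++p)
        dm[r + static_cast<size_t>(T) * p] += mism(i, p);
      for (int c = 0; c < q; ++c) {
        double m = R_PosInf;
        for (int p = 0; p < k; ++p) {
          double v = dt(r, p) - dm[r + static_cast<size_t>(T) * p] +
                     dm[r + static_cast<size_t>(T) * (perms(c, p) - 1)];
          if (v < m) m = v;
        }
        sumSalt[c] += m - contrib[r + static_cast<size_t>(T) * c];
        contrib[r + static_cast<size_t>(T) * c] = m;
      }
    }
    for (int c = 0; c < q; ++c) {
      const double delta = sumSalt[c] - sumSnow;
      if (delta < bestDelta) { bestDelta = delta; bestEnd = b; bestPerm = c + 1; }
    }
  }
  return NumericVector::create(bestDelta, bestEnd, bestPerm);
}
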