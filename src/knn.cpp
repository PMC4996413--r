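#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Pooled cross-validated accuracy of the distance-weighted k-NN: for every
// fold, each held-out sample is classified by the remaining folds.
// Identical semantics to repeated knn_weighted_vote calls.
// [[Rcpp::export]]
double knn_cv_accuracy(NumericMatrix X, IntegerVector y, IntegerVector fold,
                       int k, int n_class) {
  const int n = X.nrow(), p = X.ncol();
  int correct = 0;
  std::vector<int> folds_u;
  for (int i = 0; i < n; ++i)
    if (std::find(folds_u.begin(), folds_u.end(), fold[i]) == folds_u.end())
      folds_u.push_back(fold[i]);
  std::sort(folds_u.begin(), folds_u.end());
  for (int f : folds_u) {
    std::vector<int> tr, te;
    for (int i = 0; i < n; ++i) (fold[i] == f ? te : tr).push_back(i);
    const int k_eff = std::min<int>(k, (int)tr.size());
    std::vector<double> d(tr.size());
    for (int q : te) {
      for (size_t i = 0; i < tr.size(); ++i) {
        long double s = 0.0;
        const int t = tr[i];
        for (int j = 0; j < p; ++j) {
          const double diff = X(q, j) - X(t, j);
          s += (long double)diff * diff;
        }
        d[i] = std::sqrt((double)s);
      }
      std::vector<int> ord(tr.size());
      for (size_t i = 0; i < tr.size(); ++i) ord[i] = (int)i;
      std::partial_sort(ord.begin(), ord.begin() + k_eff, ord.end(),
                        [&](int a, int b) {
                          if (d[a] != d[b]) return d[a] < d[b];
                          return a < b;
                        });
      std::vector<long double> votes(n_class, 0.0);
      std::vector<bool> seen(n_class, false);
      for (int r = 0; r < k_eff; ++r) {
        const int cl = y[tr[ord[r]]] - 1;
        votes[cl] += 1.0 / (d[ord[r]] + 1e-9);
        seen[cl] = true;
      }
      double best = -1.0;
      for (int c = 0; c < n_class; ++c)
        if (seen[c] && (double)votes[c] > best) best = (double)votes[c];
      int n_top = 0, top = -1;
      for (int c = 0; c < n_class; ++c)
        if (seen[c] && (double)votes[c] == best) { ++n_top; if (top < 0) top = c; }
      const int pred = (n_top > 1) ? y[tr[ord[0]]] : top + 1;
      if (pred == y[q]) ++correct;
    }
  }
  return (double)correct / n;
}

// Distance-weighted k-NN votes. Semantics match the R reference:
// Euclidean distance, weight 1/(d + 1e-9), class with the largest summed
// weight wins, vote ties resolved to the class of the single nearest
// neighbour. Labels are passed as integer codes 1..C; the weight sums per
// class accumulate in neighbour order (the same order the R split+sum
// produces), so results agree bit-for-bit.
// [[Rcpp::export]]
IntegerVector knn_weighted_vote(NumericMatrix train, IntegerVector labels,
                                NumericMatrix query, int k, int n_class) {
  const int n = train.nrow(), p = train.ncol(), m = query.nrow();
  if (k > n) stop("k exceeds the number of training samples");
  IntegerVector out(m);
  std::vector<double> d(n);
  std::vector<int> idx(n);
  for (int q = 0; q < m; ++q) {
    for (int i = 0; i < n; ++i) {
      long double s = 0.0;   // long-double accumulation, like R's sum()
      for (int j = 0; j < p; ++j) {
        const double diff = query(q, j) - train(i, j);
        s += (long double)diff * diff;
      }
      d[i] = std::sqrt((double)s);
      idx[i] = i;
    }
    // k smallest with ties broken by original index (matches order())
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                      [&](int a, int b) {
                        if (d[a] != d[b]) return d[a] < d[b];
                        return a < b;
                      });
    std::vector<long double> votes(n_class, 0.0);
    std::vector<bool> seen(n_class, false);
    for (int r = 0; r < k; ++r) {
      const int cl = labels[idx[r]] - 1;
      votes[cl] += 1.0 / (d[idx[r]] + 1e-9);
      seen[cl] = true;
    }
    double best = -1.0;
    for (int c = 0; c < n_class; ++c)
      if (seen[c] && (double)votes[c] > best) best = (double)votes[c];
    int n_top = 0, top = -1;
    for (int c = 0; c < n_class; ++c)
      if (seen[c] && (double)votes[c] == best) { ++n_top; if (top < 0) top = c; }
    out[q] = (n_top > 1) ? labels[idx[0]] : top + 1;
  }
  return out;
}
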