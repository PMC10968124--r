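#include <Rcpp.h>
using namespace Rcpp;

// Deterministic k-nearest-neighbour prediction.
//
// Observations are stored as columns (the caller passes transposed
// matrices) so the inner distance loop walks contiguous memory.
// Neighbours are the k training points with the smallest squared
// Euclidean distance, ordered lexicographically by (distance, training
// index) so distance ties resolve to the earlier point.  The vote is a
// plain majority; a vote tie resolves to the label of the nearest
// neighbour whose class is among the tied winners.  Labels are 1-based
// integer codes of a factor with nlev levels.

// [[Rcpp::export(name = ".knn_predict_codes")]]
IntegerVector knn_predict_codes(NumericMatrix train_xt, IntegerVector train_y,
                                NumericMatrix test_xt, int k, int nlev) {
  const int ntr = train_xt.ncol();
  const int nte = test_xt.ncol();
  const int d = train_xt.nrow();
  if (k < 1 || k >= ntr) stop("k must satisfy 1 <= k < ncol(train_xt)");
  if (train_y.size() != ntr) stop("train_y length mismatch");
  if (test_xt.nrow() != d) stop("row mismatch between train and test");
  const double *tr = REAL(train_xt);
  const double *te = REAL(test_xt);

  std::vector<double> bestd(k);
  std::vector<int> besti(k);
  std::vector<int> votes(nlev);
  IntegerVector out(nte);

  for (int i = 0; i < nte; ++i) {
    int filled = 0;
    const double *tei = te + (size_t)i * d;
    for (int j = 0; j < ntr; ++j) {
      const double *trj = tr + (size_t)j * d;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = tei[c] - trj[c];
        s += diff * diff;
      }
      if (filled < k) {
        int pos = filled++;
        while (pos > 0 && bestd[pos - 1] > s) {
          bestd[pos] = bestd[pos - 1];
          besti[pos] = besti[pos - 1];
          --pos;
        }
        bestd[pos] = s;
        besti[pos] = j;
      } else if (s < bestd[k - 1]) {
        int pos = k - 1;
        while (pos > 0 && bestd[pos - 1] > s) {
          bestd[pos] = bestd[pos - 1];
          besti[pos] = besti[pos - 1];
          --pos;
        }
        bestd[pos] = s;
        besti[pos] = j;
      }
    }
    std::fill(votes.begin(), votes.end(), 0);
    for (int j = 0; j < k; ++j) {
      const int lab = train_y[besti[j]] - 1;
      if (lab < 0 || lab >= nlev) stop("label code out of range");
      ++votes[lab];
    }
    int best = 0;
    for (int c = 1; c < nlev; ++c) {
      if (votes[c] > votes[best]) best = c;
    }
    int nwin = 0;
    for (int c = 0; c < nlev; ++c) {
      if (votes[c] == votes[best]) ++nwin;
    }
    if (nwin > 1) {
      for (int j = 0; j < k; ++j) {
        const int lab = train_y[besti[j]] - 1;
        if (votes[lab] == votes[best]) {
          best = lab;
          break;
        }
      }
    }
    out[i] = best + 1;
  }
  return out;
}
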