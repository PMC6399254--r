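#include <Rcpp.h>
using namespace Rcpp;

// Local alignment of two ordered label maps by dynamic programming over
// label pairs. A chain pairs query label i with reference label j; a step
// from (i',j') to (i,j) may skip at most K labels on either map and pays a
// sizing penalty comparing the spanned distances dq = q[i]-q[i'] and
// dr = r[j]-r[j']:
//
//   pen(dq, dr) = min( (dq-dr)^2 / (sf^2 + (sr*dr)^2), outlier_cap )
//
// Each paired label earns match_bonus; skipped query/reference labels cost
// cq/cr each. The chain may start and end anywhere (local alignment). The
// outlier cap bounds the sizing penalty so that a single interval
// harbouring a large indel does not sever an otherwise well-anchored
// alignment; the indel is then recovered from the interval distances.

// [[Rcpp::export]]
List dp_align_cpp(NumericVector q, NumericVector r,
                  double match_bonus, double cq, double cr,
                  double sf_pen, double sr_pen, int K,
                  double outlier_cap) {
  int nq = q.size(), nr = r.size();
  if (nq == 0 || nr == 0)
    return List::create(_["score"] = 0.0,
                        _["q_idx"] = IntegerVector(0),
                        _["r_idx"] = IntegerVector(0));
  NumericMatrix S(nq, nr);
  IntegerMatrix Pi(nq, nr), Pj(nq, nr);
  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j) {
      double sc = match_bonus;  // start a new chain at (i,j)
      int pi = -1, pj = -1;
      int i0 = i - K - 1; if (i0 < 0) i0 = 0;
      int j0 = j - K - 1; if (j0 < 0) j0 = 0;
      for (int ii = i0; ii < i; ++ii) {
        for (int jj = j0; jj < j; ++jj) {
          double dq = q[i] - q[ii];
          double dr = r[j] - r[jj];
          double denom = sf_pen * sf_pen + sr_pen * dr * sr_pen * dr;
          double pen = (dq - dr) * (dq - dr) / denom;
          if (pen > outlier_cap) pen = outlier_cap;
          double cand = S(ii, jj) + match_bonus - pen
            - cq * (i - ii - 1) - cr * (j - jj - 1);
          if (cand > sc) { sc = cand; pi = ii; pj = jj; }
        }
      }
      S(i, j) = sc;
      Pi(i, j) = pi;
      Pj(i, j) = pj;
      if (sc > best) { best = sc; bi = i; bj = j; }
    }
  }
  std::vector<int> qi, rj;
  if (bi >= 0) {
    int i = bi, j = bj;
    while (i >= 0) {
      qi.push_back(i + 1);
      rj.push_back(j + 1);
      int ni = Pi(i, j), nj = Pj(i, j);
      i = ni; j = nj;
    }
    std::reverse(qi.begin(), qi.end());
    std::reverse(rj.begin(), rj.end());
  }
  return List::create(_["score"] = best,
                      _["q_idx"] = wrap(qi),
                      _["r_idx"] = wrap(rj));
}

// Best scores of many queries against one reference (used for permutation
// calibration of the confidence null model): returns only the score.

// [[Rcpp::export]]
NumericVector dp_best_scores_cpp(List queries, NumericVector r,
                                 double match_bonus, double cq, double cr,
                                 double sf_pen, double sr_pen, int K,
                                 double outlier_cap) {
  int n = queries.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    NumericVector q = queries[k];
    List res = dp_align_cpp(q, r, match_bonus, cq, cr, sf_pen, sr_pen, K,
                            outlier_cap);
    out[k] = as<double>(res["score"]);
  }
  return out;
}
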