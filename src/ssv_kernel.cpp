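#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Full-precision single-segment ungapped Viterbi maximum.
// codes: 0-based symbols (length L), scores: K x 4 (model position x symbol).
// Recurrence: M(i,j) = max(0, M(i-1,j-1)) + scores(j, codes[i]), with
// predecessors outside the matrix contributing 0. Returns max over all cells.
// [[Rcpp::export]]
double ssv_max_score_cpp(IntegerVector codes, NumericMatrix scores) {
  const int L = codes.size();
  const int K = scores.nrow();
  std::vector<double> prev(K, 0.0), cur(K);
  double best = R_NegInf;
  for (int i = 0; i < L; ++i) {
    const int c = codes[i];
    for (int j = 0; j < K; ++j) {
      double pred = (i == 0 || j == 0) ? 0.0 : prev[j - 1];
      if (pred < 0.0) pred = 0.0;
      const double v = pred + scores(j, c);
      cur[j] = v;
      if (v > best) best = v;
    }
    prev.swap(cur);
  }
  return best;
}

// 8-bit threshold-hit recurrence, row-major order.
// Accumulator M in [0,255]; T = M(i-1,j-1) + P(j,c) at ordinary integer
// precision; T < 0 -> reset; T >= 256 -> hit + reset; else M = T.
// Returns a n_hits x 2 matrix of 0-based (i, j) pairs in encounter order.
// [[Rcpp::export]]
IntegerMatrix ssv_hits_rowmajor_cpp(IntegerVector codes, IntegerMatrix scores8) {
  const int L = codes.size();
  const int K = scores8.nrow();
  std::vector<int> prev(K, 0), cur(K);
  std::vector<int> hi, hj;
  for (int i = 0; i < L; ++i) {
    const int c = codes[i];
    for (int j = 0; j < K; ++j) {
      const int pred = (i == 0 || j == 0) ? 0 : prev[j - 1];
      const int t = pred + scores8(j, c);
      if (t < 0) {
        cur[j] = 0;
      } else if (t >= 256) {
        hi.push_back(i);
        hj.push_back(j);
        cur[j] = 0;
      } else {
        cur[j] = t;
      }
    }
    prev.swap(cur);
  }
  IntegerMatrix out(hi.size(), 2);
  for (size_t k = 0; k < hi.size(); ++k) {
    out(k, 0) = hi[k];
    out(k, 1) = hj[k];
  }
  return out;
}

// Same recurrence evaluated in segmented column order: the padded sequence is
// split into length-n segments; for each segment every model column is swept
// before moving to the next segment. The rightmost cell of each column is
// carried to the leftmost cell of the next segment through a score queue; the
// first segment seeds with zeros. Hit set is identical to row-major.
// [[Rcpp::export]]
IntegerMatrix ssv_hits_segmented_cpp(IntegerVector codes, IntegerMatrix scores8,
                                     int n) {
  const int L = codes.size();
  const int K = scores8.nrow();
  if (n < 1) stop("segment width n must be >= 1");
  if (L % n != 0) stop("padded length must be a multiple of the segment width");
  const int n_seg = L / n;
  std::vector<int> queue(K, 0), next_queue(K, 0);
  std::vector<int> col_prev(n, 0), col_cur(n, 0);
  std::vector<int> hi, hj;
  for (int s = 0; s < n_seg; ++s) {
    const int seg_start = s * n;
    std::fill(col_prev.begin(), col_prev.end(), 0);
    for (int j = 0; j < K; ++j) {
      for (int idx = 0; idx < n; ++idx) {
        int pred;
        if (idx == 0) {
          // leftmost cell: predecessor is the rightmost cell of the previous
          // segment at column j-1, delivered by the score queue
          pred = (s == 0 || j == 0) ? 0 : queue[j - 1];
        } else {
          pred = (j == 0) ? 0 : col_prev[idx - 1];
        }
        const int t = pred + scores8(j, codes[seg_start + idx]);
        int m;
        if (t < 0) {
          m = 0;
        } else if (t >= 256) {
          hi.push_back(seg_start + idx);
          hj.push_back(j);
          m = 0;
        } else {
          m = t;
        }
        col_cur[idx] = m;
      }
      next_queue[j] = col_cur[n - 1];
      col_prev.swap(col_cur);
    }
    queue.swap(next_queue);
  }
  IntegerMatrix out(hi.size(), 2);
  for (size_t k = 0; k < hi.size(); ++k) {
    out(k, 0) = hi[k];
    out(k, 1) = hj[k];
  }
  return out;
}

// Restricted single-diagonal recheck used by hit validation: rerun the 8-bit
// recurrence along the full diagonal through local cell (ip, jp), starting
// at the record boundary, and return every cell on that diagonal that
// crosses the threshold within this (sequence, model) pair.
// [[Rcpp::export]]
IntegerMatrix ssv_diag_hits_cpp(IntegerVector codes, IntegerMatrix scores8,
                                int ip, int jp) {
  const int L = codes.size();
  const int K = scores8.nrow();
  if (ip < 0 || ip >= L || jp < 0 || jp >= K)
    stop("cell outside the local matrix");
  const int off = ip - jp;
  int i = off > 0 ? off : 0;
  int j = i - off;
  int m = 0;
  std::vector<int> hi, hj;
  for (; i < L && j < K; ++i, ++j) {
    const int t = m + scores8(j, codes[i]);
    if (t < 0) {
      m = 0;
    } else if (t >= 256) {
      hi.push_back(i);
      hj.push_back(j);
      m = 0;
    } else {
      m = t;
    }
  }
  IntegerMatrix out(hi.size(), 2);
  for (size_t k = 0; k < hi.size(); ++k) {
    out(k, 0) = hi[k];
    out(k, 1) = hj[k];
  }
  return out;
}
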