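#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Op codes shared with the R side:
// 0 = match, 1 = mismatch, 2 = gap_in_query (consumes a query token),
// 3 = gap_in_ref (consumes a reference token).

// Smith-Waterman local alignment of token sequences.
// Tie-breaks: the best cell is the maximal-scoring cell with the smallest
// reference end index (then smallest query end index); traceback prefers
// diagonal (match/mismatch) over gap_in_ref over gap_in_query.
// [[Rcpp::export]]
List sw_align_cpp(CharacterVector query, CharacterVector reference,
                  double match, double mismatch, double gap) {
  const int n = query.size(), m = reference.size();
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  auto at = [&](int i, int j) -> double& { return H[i * (m + 1) + j]; };

  std::vector<std::string> q(n), r(m);
  for (int i = 0; i < n; ++i) q[i] = as<std::string>(query[i]);
  for (int j = 0; j < m; ++j) r[j] = as<std::string>(reference[j]);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      double v = at(i - 1, j - 1) + s;
      double up = at(i - 1, j) + gap;     // gap_in_query
      double left = at(i, j - 1) + gap;   // gap_in_ref
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0.0) v = 0.0;
      at(i, j) = v;
      // smaller j wins ties, then smaller i
      if (v > best || (v == best && v > 0.0 &&
                       (j < bj || (j == bj && i < bi)))) {
        if (v > 0.0) { best = v; bi = i; bj = j; }
      }
    }
  }

  std::vector<int> ops;
  int i = bi, j = bj;
  if (best > 0.0) {
    while (i > 0 && j > 0 && at(i, j) > 0.0) {
      double s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      if (at(i, j) == at(i - 1, j - 1) + s) {
        ops.push_back(q[i - 1] == r[j - 1] ? 0 : 1);
        --i; --j;
      } else if (at(i, j) == at(i, j - 1) + gap) {
        ops.push_back(3);
        --j;
      } else {
        ops.push_back(2);
        --i;
      }
    }
  }
  std::reverse(ops.begin(), ops.end());

  int q_start = best > 0.0 ? i : 0, q_end = best > 0.0 ? bi : 0;
  int r_start = best > 0.0 ? j : 0, r_end = best > 0.0 ? bj : 0;
  return List::create(
    _["score"] = best,
    _["q_start"] = q_start, _["q_end"] = q_end,   // 0-based half-open
    _["r_start"] = r_start, _["r_end"] = r_end,
    _["ops"] = IntegerVector(ops.begin(), ops.end()));
}

// Unit-cost Levenshtein alignment with operation counts.
// Traceback tie-break among equal-cost paths: prefer a matching diagonal
// (hit), then deletion (reference token dropped), then insertion
// (hypothesis token added), then a substitution diagonal. Hit-first keeps
// the decomposition faithful: a deletion/insertion pair straddling a
// matched word is reported as D+hit+I, not collapsed into two
// substitutions of the same total cost.
// [[Rcpp::export]]
IntegerVector edit_ops_cpp(CharacterVector reference, CharacterVector hypothesis) {
  const int n = reference.size(), m = hypothesis.size();
  std::vector<std::string> r(n), h(m);
  for (int i = 0; i < n; ++i) r[i] = as<std::string>(reference[i]);
  for (int j = 0; j < m; ++j) h[j] = as<std::string>(hypothesis[j]);

  std::vector<int> D((n + 1) * (m + 1));
  auto at = [&](int i, int j) -> int& { return D[i * (m + 1) + j]; };
  for (int i = 0; i <= n; ++i) at(i, 0) = i;
  for (int j = 0; j <= m; ++j) at(0, j) = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int diag = at(i - 1, j - 1) + (r[i - 1] == h[j - 1] ? 0 : 1);
      int del = at(i - 1, j) + 1;
      int ins = at(i, j - 1) + 1;
      int v = diag;
      if (del < v) v = del;
      if (ins < v) v = ins;
      at(i, j) = v;
    }
  }

  int hits = 0, subs = 0, ins = 0, del = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && r[i - 1] == h[j - 1] &&
        at(i, j) == at(i - 1, j - 1)) {
      ++hits;
      --i; --j;
    } else if (i > 0 && at(i, j) == at(i - 1, j) + 1) {
      ++del;
      --i;
    } else if (j > 0 && at(i, j) == at(i, j - 1) + 1) {
      ++ins;
      --j;
    } else {
      ++subs;
      --i; --j;
    }
  }
  return IntegerVector::create(
    _["hits"] = hits, _["substitutions"] = subs,
    _["insertions"] = ins, _["deletions"] = del);
}
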