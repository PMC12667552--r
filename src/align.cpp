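#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Global alignment under unit edit costs: match 0, substitution 1, gap 1.
// D is (n+1) x (m+1), row-major; returns the optimal cost.
static int nw_fill(const std::string& q, const std::string& t,
                   std::vector<int>& D) {
  const int n = (int)q.size(), m = (int)t.size();
  D.assign((size_t)(n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) D[j] = j;
  for (int i = 1; i <= n; ++i) {
    D[(size_t)i * (m + 1)] = i;
    for (int j = 1; j <= m; ++j) {
      int diag = D[(size_t)(i - 1) * (m + 1) + j - 1] + (q[i - 1] == t[j - 1] ? 0 : 1);
      int del  = D[(size_t)i * (m + 1) + j - 1] + 1;       // gap in read, consumes target
      int ins  = D[(size_t)(i - 1) * (m + 1) + j] + 1;     // gap in target, consumes read
      D[(size_t)i * (m + 1) + j] = std::min(diag, std::min(del, ins));
    }
  }
  return D[(size_t)n * (m + 1) + m];
}

// Optimal global alignment of a read payload against the synthesis target.
// Traceback runs from the end and, at cost ties, prefers the diagonal move
// (match/substitution), then the target-consuming gap (deletion), then the
// read-consuming gap (insertion). This fixed order makes counts reproducible
// and places co-optimal homopolymer deletions leftmost on the target.
// ops: M match, S substitution, D deletion, I insertion (read base absent
// from target; attached to the target position it follows, 0 = before all).
// [[Rcpp::export]]
List nw_align_cpp(std::string query, std::string target) {
  const int n = (int)query.size(), m = (int)target.size();
  std::vector<int> D;
  const int score = nw_fill(query, target, D);

  std::vector<std::string> op;
  std::vector<int> tpos, qpos;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int cur = D[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 &&
        cur == D[(size_t)(i - 1) * (m + 1) + j - 1] + (query[i - 1] == target[j - 1] ? 0 : 1)) {
      op.push_back(query[i - 1] == target[j - 1] ? "M" : "S");
      tpos.push_back(j);
      qpos.push_back(i);
      --i; --j;
    } else if (j > 0 && cur == D[(size_t)i * (m + 1) + j - 1] + 1) {
      op.push_back("D");
      tpos.push_back(j);
      qpos.push_back(NA_INTEGER);
      --j;
    } else {
      op.push_back("I");
      tpos.push_back(j);  // insertion follows target position j
      qpos.push_back(i);
      --i;
    }
  }
  std::reverse(op.begin(), op.end());
  std::reverse(tpos.begin(), tpos.end());
  std::reverse(qpos.begin(), qpos.end());

  return List::create(_["score"] = score,
                      _["op"] = wrap(op),
                      _["target_pos"] = wrap(tpos),
                      _["read_pos"] = wrap(qpos));
}

// Batch alignment costs for every query x target pair (shares nw_fill with
// the traceback aligner above).
// [[Rcpp::export]]
IntegerMatrix nw_cost_matrix_cpp(CharacterVector queries, CharacterVector targets) {
  const int nq = queries.size(), nt = targets.size();
  IntegerMatrix out(nq, nt);
  std::vector<int> D;
  for (int a = 0; a < nq; ++a) {
    const std::string q = as<std::string>(queries[a]);
    for (int b = 0; b < nt; ++b) {
      const std::string t = as<std::string>(targets[b]);
      out(a, b) = nw_fill(q, t, D);
    }
  }
  return out;
}

// Per-read error classification against one target, for a vector of payloads.
// Returns, per payload: counts of match/substitution/deletion/insertion and,
// per target position, the aligned outcome code
//   0 = match, 1 = substitution, 2 = deletion
// plus the read base observed at that position (target base for a match,
// the substituted base otherwise, '-' for a deletion), and the number of
// inserted bases attached after each target position 0..m.
// [[Rcpp::export]]
List classify_batch_cpp(CharacterVector payloads, std::string target) {
  const int np = payloads.size(), m = (int)target.size();
  IntegerVector n_match(np), n_sub(np), n_del(np), n_ins(np), scores(np);
  IntegerMatrix outcome(np, m);      // 0/1/2 per target position
  CharacterMatrix obs(np, m);        // observed base per target position
  IntegerMatrix ins_after(np, m + 1);  // column k = insertions after target pos k

  std::vector<int> D;
  for (int a = 0; a < np; ++a) {
    const std::string q = as<std::string>(payloads[a]);
    const int n = (int)q.size();
    scores[a] = nw_fill(q, target, D);
    int i = n, j = m;
    int nm = 0, ns = 0, nd = 0, ni = 0;
    while (i > 0 || j > 0) {
      const int cur = D[(size_t)i * (m + 1) + j];
      if (i > 0 && j > 0 &&
          cur == D[(size_t)(i - 1) * (m + 1) + j - 1] + (q[i - 1] == target[j - 1] ? 0 : 1)) {
        if (q[i - 1] == target[j - 1]) { outcome(a, j - 1) = 0; ++nm; }
        else                           { outcome(a, j - 1) = 1; ++ns; }
        obs(a, j - 1) = std::string(1, q[i - 1]);
        --i; --j;
      } else if (j > 0 && cur == D[(size_t)i * (m + 1) + j - 1] + 1) {
        outcome(a, j - 1) = 2;
        obs(a, j - 1) = "-";
        ++nd;
        --j;
      } else {
        ins_after(a, j) += 1;
        ++ni;
        --i;
      }
    }
    n_match[a] = nm; n_sub[a] = ns; n_del[a] = nd; n_ins[a] = ni;
  }
  return List::create(_["score"] = scores,
                      _["n_match"] = n_match, _["n_sub"] = n_sub,
                      _["n_del"] = n_del, _["n_ins"] = n_ins,
                      _["outcome"] = outcome, _["observed"] = obs,
                      _["ins_after"] = ins_after);
}
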