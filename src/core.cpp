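#include <Rcpp.h>
using namespace Rcpp;

// W: windows x k matrix of base codes 1..4 (admissible windows only).
// symlogp: 15 x 4 matrix of per-symbol, per-base weighted log probabilities
// (the lambda factor is already folded in by the caller).
// priorvec: per-window weighted prior log term (already includes 1 - lambda
// and the convex prior weights); zero-length means no priors.

// [[Rcpp::export]]
NumericVector window_scores_cpp(const IntegerMatrix& W,
                                const IntegerVector& sym,
                                const NumericMatrix& symlogp) {
  const int tw = W.nrow(), k = W.ncol();
  // long double accumulation so exact ties between windows holding the
  // same word survive reassociation (argmax ties then break identically
  // in every scoring path)
  std::vector<long double> acc(tw, 0.0L);
  for (int d = 0; d < k; ++d) {
    const int s = sym[d] - 1;
    for (int w = 0; w < tw; ++w) acc[w] += symlogp(s, W(w, d) - 1);
  }
  NumericVector out(tw);
  for (int w = 0; w < tw; ++w) out[w] = (double)acc[w];
  return out;
}

// Per-sequence argmax of `total` over the window rows [first, last] (1-based,
// inclusive). Rows are ordered by (sequence, start, strand '+' first), and
// only strictly greater values replace the running best, so ties resolve to
// the smallest start and then the forward strand.
// [[Rcpp::export]]
List annotate_best_cpp(const NumericVector& total,
                       const IntegerVector& first,
                       const IntegerVector& last) {
  const int n = first.size();
  IntegerVector idx(n);
  NumericVector val(n);
  long double bis = 0.0;
  for (int i = 0; i < n; ++i) {
    int best = first[i] - 1;
    double bv = total[best];
    for (int w = first[i]; w <= last[i] - 1; ++w) {
      if (total[w] > bv) { bv = total[w]; best = w; }
    }
    idx[i] = best + 1;
    val[i] = bv;
    bis += bv;
  }
  return List::create(_["idx"] = idx, _["value"] = val,
                      _["bis"] = (double)bis);
}

static double eval_candidate(const NumericVector& rest,
                             const IntegerMatrix& W, int d, int s,
                             const NumericMatrix& symlogp,
                             const IntegerVector& first,
                             const IntegerVector& last) {
  long double bis = 0.0;
  const int n = first.size();
  for (int i = 0; i < n; ++i) {
    double bv = R_NegInf;
    for (int w = first[i] - 1; w <= last[i] - 1; ++w) {
      double v = rest[w] + symlogp(s, W(w, d) - 1);
      if (v > bv) bv = v;
    }
    bis += bv;
  }
  return (double)bis;
}

// Greedy single-position IUPAC refinement. Positions are visited cyclically;
// the run stops once k consecutive positions yield no accepted substitution.
// Only strictly improving substitutions are accepted, and after an
// acceptance the remaining symbols of the inner loop are compared against
// the updated motif. max_degen < 0 means unlimited degenerate positions.
// [[Rcpp::export]]
List ggp_cpp(const IntegerVector& sym0,
             const IntegerMatrix& W,
             const NumericMatrix& symlogp,
             const NumericVector& priorvec,
             const IntegerVector& first,
             const IntegerVector& last,
             int max_degen) {
  const int tw = W.nrow(), k = W.ncol(), nsym = symlogp.nrow();
  IntegerVector sym = clone(sym0);

  // per-column contribution of the current motif to each window's score
  NumericMatrix percol(tw, k);
  for (int d = 0; d < k; ++d) {
    const int s = sym[d] - 1;
    for (int w = 0; w < tw; ++w) percol(w, d) = symlogp(s, W(w, d) - 1);
  }

  int deg = 0;
  for (int d = 0; d < k; ++d) if (sym[d] > 4) ++deg;

  NumericVector rest(tw);
  std::vector<int> mv_pos, mv_old, mv_new;
  std::vector<double> mv_before, mv_after;
  long evals = 0;

  // current BIS from a full pass
  double bis_cur;
  {
    NumericVector tot(tw);
    for (int w = 0; w < tw; ++w) {
      double v = priorvec.size() ? priorvec[w] : 0.0;
      for (int d = 0; d < k; ++d) v += percol(w, d);
      tot[w] = v;
    }
    List a = annotate_best_cpp(tot, first, last);
    bis_cur = a["bis"];
  }

  int t = 0, i = 0;
  while (t < k) {
    bool changed = false;
    // score of every window excluding position i's contribution
    for (int w = 0; w < tw; ++w) {
      double v = priorvec.size() ? priorvec[w] : 0.0;
      for (int d = 0; d < k; ++d) if (d != i) v += percol(w, d);
      rest[w] = v;
    }
    for (int a = 1; a <= nsym; ++a) {
      if (a == sym[i]) continue;  // identical motif cannot strictly improve
      if (a > 4 && max_degen >= 0) {
        int newdeg = deg - (sym[i] > 4 ? 1 : 0) + 1;
        if (newdeg > max_degen) continue;
      }
      ++evals;
      double cand = eval_candidate(rest, W, i, a - 1, symlogp, first, last);
      // strict improvement with a tiny margin: scores that are exact ties
      // in real arithmetic (e.g. symmetric IUPAC columns, or the same
      // objective rescaled by a positive affine map, as a uniform prior
      // does) must not be "accepted" through last-ulp rounding noise
      double tol = std::isfinite(bis_cur)
        ? 1e-9 + 1e-12 * std::fabs(bis_cur) : 0.0;
      if (cand > bis_cur + tol) {
        mv_pos.push_back(i);
        mv_old.push_back(sym[i]);
        mv_new.push_back(a);
        mv_before.push_back(bis_cur);
        mv_after.push_back(cand);
        deg += (a > 4 ? 1 : 0) - (sym[i] > 4 ? 1 : 0);
        sym[i] = a;
        for (int w = 0; w < tw; ++w) percol(w, i) = symlogp(a - 1, W(w, i) - 1);
        bis_cur = cand;
        t = 0;
        changed = true;
      }
    }
    if (!changed) ++t;
    i = (i + 1) % k;
  }

  return List::create(
    _["sym"] = sym,
    _["bis"] = bis_cur,
    _["move_pos"] = IntegerVector(mv_pos.begin(), mv_pos.end()),
    _["move_old"] = IntegerVector(mv_old.begin(), mv_old.end()),
    _["move_new"] = IntegerVector(mv_new.begin(), mv_new.end()),
    _["move_before"] = NumericVector(mv_before.begin(), mv_before.end()),
    _["move_after"] = NumericVector(mv_after.begin(), mv_after.end()),
    _["iterations"] = (double)evals);
}

// ---- seeder: depth-first extension over {A,C,G,T} -----------------------

struct DfsState {
  const IntegerMatrix* W;
  const IntegerVector* seq_of;
  int k, e, quorum;
  std::vector<int> words;     // flat, k codes per emitted word
  std::vector<int> supports;
};

static int distinct_seqs(const std::vector<int>& wins,
                         const IntegerVector& seq_of) {
  int cnt = 0, prev = -1;
  for (size_t j = 0; j < wins.size(); ++j) {
    int s = seq_of[wins[j]];
    if (s != prev) { ++cnt; prev = s; }
  }
  return cnt;
}

static void dfs_extend(DfsState& st, int depth, std::vector<int>& prefix,
                       const std::vector<int>& wins,
                       const std::vector<int>& dist) {
  const IntegerMatrix& W = *st.W;
  for (int a = 1; a <= 4; ++a) {
    std::vector<int> nw, nd;
    nw.reserve(wins.size());
    nd.reserve(wins.size());
    for (size_t j = 0; j < wins.size(); ++j) {
      int d2 = dist[j] + (W(wins[j], depth) != a ? 1 : 0);
      if (d2 <= st.e) { nw.push_back(wins[j]); nd.push_back(d2); }
    }
    int sup = distinct_seqs(nw, *st.seq_of);
    if (sup < st.quorum) continue;
    prefix.push_back(a);
    if (depth + 1 == st.k) {
      st.words.insert(st.words.end(), prefix.begin(), prefix.end());
      st.supports.push_back(sup);
    } else {
      dfs_extend(st, depth + 1, prefix, nw, nd);
    }
    prefix.pop_back();
  }
}

// Enumerate all width-k DNA words whose within-Hamming-distance-e support
// (number of distinct sequences with at least one matching window) meets the
// quorum. Prefix pruning uses prefix distance <= e, an admissible relaxation
// of the full-word distance, so no qualifying word is missed.
// [[Rcpp::export]]
List enumerate_words_cpp(const IntegerMatrix& W,
                         const IntegerVector& seq_of,
                         int k, int e, int quorum) {
  DfsState st;
  st.W = &W; st.seq_of = &seq_of; st.k = k; st.e = e; st.quorum = quorum;
  std::vector<int> wins(W.nrow()), dist(W.nrow(), 0), prefix;
  for (int w = 0; w < W.nrow(); ++w) wins[w] = w;
  if (W.nrow() > 0) dfs_extend(st, 0, prefix, wins, dist);
  const int nc = st.supports.size();
  IntegerMatrix words(nc, k);
  for (int r = 0; r < nc; ++r)
    for (int d = 0; d < k; ++d) words(r, d) = st.words[(size_t)r * k + d];
  return List::create(_["words"] = words,
                      _["support"] = IntegerVector(st.supports.begin(),
                                                   st.supports.end()));
}
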