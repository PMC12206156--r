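#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Banded pairwise alignment with linear gap costs (score maximized).
//
// The pattern `a` is always aligned end to end.  With free_b = true the
// alignment may start and end anywhere in the subject `b` (end gaps on the
// b side are free); with free_b = false both sequences are anchored.
//
// The band restricts diagonals d = j - i to [dlo, dhi], where i indexes a
// (rows) and j indexes b (columns).  Callers are responsible for choosing
// a band that provably contains the optimum (see the R-side widening loop)
// or, for the read aligner, a band wide enough for the seeded window.
//
// Returns score, and when traceback = TRUE a run-length CIGAR over
// {=, X, I, D} (I consumes a only, D consumes b only) plus the 1-based
// first/last consumed subject positions.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b,
                      int match, int mismatch, int gap,
                      int dlo, int dhi,
                      bool free_b, bool traceback) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n < 1 || m < 1) stop("empty sequence in alignment");
  if (dlo > dhi) stop("invalid band");
  // clamp band to what can exist at all
  if (dlo < -n) dlo = -n;
  if (dhi > m) dhi = m;
  const int W = dhi - dlo + 1;

  std::vector<int> prev((size_t) W, NEG), cur((size_t) W, NEG);
  std::vector<unsigned char> mv;
  if (traceback) mv.assign((size_t) (n + 1) * W, 0);
  // move codes: 0 invalid, 1 diag, 2 up (gap in b, op I), 3 left (gap in a,
  // op D), 4 alignment origin

  // row i = 0
  for (int c = 0; c < W; ++c) {
    int j = dlo + c;
    if (j < 0 || j > m) continue;
    if (j == 0) {
      prev[c] = 0;
      if (traceback) mv[c] = 4;
    } else if (free_b) {
      prev[c] = 0;
      if (traceback) mv[c] = 4;
    } else {
      prev[c] = j * gap;
      if (traceback) mv[c] = (dlo + c - 1 >= dlo) ? 3 : 0;
      if (traceback && mv[c] == 3 && prev[c] <= NEG / 2) mv[c] = 0;
    }
  }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[(size_t) i - 1];
    for (int c = 0; c < W; ++c) cur[c] = NEG;
    const size_t rowoff = traceback ? (size_t) i * W : 0;
    for (int c = 0; c < W; ++c) {
      int j = i + dlo + c;
      if (j < 0 || j > m) continue;
      int best = NEG; unsigned char bm = 0;
      if (j >= 1 && prev[c] > NEG / 2) {          // diag: (i-1, j-1), same c
        int s = prev[c] + (ai == b[(size_t) j - 1] ? match : mismatch);
        if (s > best) { best = s; bm = 1; }
      }
      if (c >= 1 && cur[c - 1] > NEG / 2) {       // left: (i, j-1)
        int s = cur[c - 1] + gap;
        if (s > best) { best = s; bm = 3; }
      }
      if (c + 1 < W && prev[c + 1] > NEG / 2) {   // up: (i-1, j)
        int s = prev[c + 1] + gap;
        if (s > best) { best = s; bm = 2; }
      }
      cur[c] = best;
      if (traceback) mv[rowoff + c] = bm;
    }
    std::swap(prev, cur);
  }
  // prev now holds row n

  int end_c = -1, best = NEG;
  if (free_b) {
    for (int c = 0; c < W; ++c) {                 // largest j among maxima
      int j = n + dlo + c;
      if (j < 0 || j > m) continue;
      if (prev[c] >= best && prev[c] > NEG / 2) { best = prev[c]; end_c = c; }
    }
  } else {
    int c = m - n - dlo;
    if (c < 0 || c >= W) stop("band does not reach the global end cell");
    end_c = c; best = prev[c];
  }
  if (end_c < 0 || best <= NEG / 2)
    stop("no alignment within the band");

  if (!traceback)
    return List::create(_["score"] = best);

  // traceback
  std::string ops;
  int i = n, c = end_c;
  int b_end = n + dlo + c;
  for (;;) {
    unsigned char m0 = mv[(size_t) i * W + c];
    if (m0 == 4) break;
    if (m0 == 0) stop("internal error: traceback fell out of the band");
    int j = i + dlo + c;
    if (m0 == 1) {
      ops.push_back(a[(size_t) i - 1] == b[(size_t) j - 1] ? '=' : 'X');
      --i;                       // d unchanged -> same c
    } else if (m0 == 2) {
      ops.push_back('I');
      --i; ++c;
    } else {
      ops.push_back('D');
      --c;
    }
  }
  int b_start = i + dlo + c + 1;  // first consumed subject base, 1-based

  // run-length encode (ops are reversed)
  std::vector<std::string> rops; std::vector<int> rlens;
  for (int k = (int) ops.size() - 1; k >= 0;) {
    char o = ops[(size_t) k]; int len = 0;
    while (k >= 0 && ops[(size_t) k] == o) { ++len; --k; }
    rops.push_back(std::string(1, o)); rlens.push_back(len);
  }
  return List::create(_["score"] = best,
                      _["ops"] = wrap(rops),
                      _["lens"] = wrap(rlens),
                      _["b_start"] = b_start,
                      _["b_end"] = b_end);
}

// Maximum-weight path DP over a DAG given in topological order.
// to_idx/from_idx/weight describe edges by 1-based node positions in the
// *topological* numbering; edges must satisfy topo[from] < topo[to].
// Returns DP values and the best predecessor (0 = none) chosen with the
// tie rule: higher score; then the predecessor whose best path carries
// fewer labeled nodes (parsimony — an equally supported bypass beats the
// longer walk through a spurious repeat copy, and cannot collapse
// zero-coverage stretches because nodes with predecessors must extend
// one); then backbone edge, smaller predecessor rank, non-N predecessor
// label, smaller predecessor index.

// [[Rcpp::export]]
List cpp_dag_dp(int n_nodes,
                IntegerVector from_idx, IntegerVector to_idx,
                IntegerVector weight, LogicalVector is_backbone,
                NumericVector rank_, LogicalVector label_is_n,
                LogicalVector is_labeled) {
  const int nE = from_idx.size();
  std::vector<double> dp((size_t) n_nodes, 0.0);
  std::vector<int> bp((size_t) n_nodes, 0);
  std::vector<int> bedge((size_t) n_nodes, -1);
  std::vector<int> plen((size_t) n_nodes, 0);  // labeled nodes on best path
  for (int i = 0; i < n_nodes; ++i) plen[(size_t) i] = is_labeled[i] ? 1 : 0;
  // edges are processed grouped by target in increasing target order;
  // callers pass them sorted by to_idx, so every predecessor is final
  // (and its plen known) before its successors are scored
  int last_u = -1;
  for (int e = 0; e <= nE; ++e) {
    int u = (e < nE) ? to_idx[e] - 1 : -2;
    if (u != last_u && last_u >= 0) {   // finalize plen of the previous u
      plen[(size_t) last_u] =
        plen[(size_t) (bp[(size_t) last_u] - 1)] +
        (is_labeled[last_u] ? 1 : 0);
    }
    if (e == nE) break;
    last_u = u;
    int v = from_idx[e] - 1;
    double cand = dp[(size_t) v] + weight[e];
    bool take = false;
    if (bp[(size_t) u] == 0 || cand > dp[(size_t) u]) {
      take = true;
    } else if (cand == dp[(size_t) u]) {
      int pe = bedge[(size_t) u];
      int pv = bp[(size_t) u] - 1;
      // 1. fewest labeled nodes (parsimony)
      if (plen[(size_t) v] != plen[(size_t) pv])
        take = plen[(size_t) v] < plen[(size_t) pv];
      // 2. prefer backbone edges
      else if (is_backbone[e] != is_backbone[pe]) take = is_backbone[e];
      // 3. smaller predecessor rank
      else if (rank_[v] != rank_[pv]) take = rank_[v] < rank_[pv];
      // 4. prefer non-N predecessor label
      else if (label_is_n[v] != label_is_n[pv]) take = !label_is_n[v];
      // 5. smaller predecessor index
      else take = v < pv;
    }
    if (take) {
      dp[(size_t) u] = cand;
      bp[(size_t) u] = v + 1;
      bedge[(size_t) u] = e;
    }
  }
  return List::create(_["dp"] = wrap(dp), _["best_pred"] = wrap(bp),
                      _["path_labels"] = wrap(plen));
}
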