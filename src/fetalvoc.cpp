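#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with L1 local cost and the symmetric step set
// {(1,0),(0,1),(1,1)}, both endpoints matched, no path-length
// normalization. Returns the minimal cumulative cost.
// [[Rcpp::export]]
double cpp_dtw_cost(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<double> prev(m), cur(m);
  prev[0] = std::abs(a[0] - b[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::abs(a[0] - b[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::abs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = best + std::abs(a[i] - b[j]);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Optimal warping path for the same DP; ties broken diagonal-first, then
// toward advancing the first sequence. Rows are 1-based (i, j) pairs from
// (1, 1) to (n, m).
// [[Rcpp::export]]
IntegerMatrix cpp_dtw_path(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  NumericMatrix D(n, m);
  D(0, 0) = std::abs(a[0] - b[0]);
  for (int j = 1; j < m; ++j) D(0, j) = D(0, j - 1) + std::abs(a[0] - b[j]);
  for (int i = 1; i < n; ++i) {
    D(i, 0) = D(i - 1, 0) + std::abs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(D(i - 1, j - 1), std::min(D(i - 1, j), D(i, j - 1)));
      D(i, j) = best + std::abs(a[i] - b[j]);
    }
  }
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double d = D(i - 1, j - 1), u = D(i - 1, j), l = D(i, j - 1);
      if (d <= u && d <= l) { --i; --j; }
      else if (u <= l) { --i; }
      else { --j; }
    }
    pi.push_back(i); pj.push_back(j);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k] + 1;
    path(k, 1) = pj[L - 1 - k] + 1;
  }
  return path;
}

// Greedy one-to-one pairing of orofacial and head movement units into the
// five co-occurrence states. Units of each kind are sorted by onset and
// non-overlapping within kind (frames, closed intervals). A later-onset
// unit overlaps an earlier one when its onset is >= 1 frame after the
// earlier onset and strictly before the earlier offset; equal onsets are
// synchronous. Each unit joins at most one pair; a unit overlapping
// several unused units of the other kind is paired with the first.
// States: 1 isolated orofacial, 2 isolated head, 3 orofacial leads,
// 4 head leads, 5 synchronous onset. Anchor = earlier onset of the pair.
// [[Rcpp::export]]
List cpp_pair_states(IntegerVector o_on, IntegerVector o_off,
                     IntegerVector h_on, IntegerVector h_off) {
  const int no = o_on.size(), nh = h_on.size();
  const int ntot = no + nh;
  // merged order by onset; kind 0 = orofacial, 1 = head
  std::vector<int> on(ntot), off(ntot), kind(ntot), ord(ntot);
  for (int i = 0; i < no; ++i) { on[i] = o_on[i]; off[i] = o_off[i]; kind[i] = 0; }
  for (int i = 0; i < nh; ++i) { on[no + i] = h_on[i]; off[no + i] = h_off[i]; kind[no + i] = 1; }
  for (int i = 0; i < ntot; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int x, int y) { return on[x] < on[y]; });
  std::vector<bool> used(ntot, false);
  std::vector<int> state, anchor;
  state.reserve(ntot); anchor.reserve(ntot);
  for (int k = 0; k < ntot; ++k) {
    int u = ord[k];
    if (used[u]) continue;
    int mate = -1;
    for (int k2 = k + 1; k2 < ntot; ++k2) {
      int v = ord[k2];
      if (on[v] > on[u] && on[v] >= off[u]) break;  // no later overlap possible
      if (used[v] || kind[v] == kind[u]) continue;
      if (on[v] == on[u] || (on[v] > on[u] && on[v] < off[u])) { mate = v; break; }
    }
    if (mate >= 0) {
      used[u] = used[mate] = true;
      int s = (on[mate] == on[u]) ? 5 : (kind[u] == 0 ? 3 : 4);
      state.push_back(s);
      anchor.push_back(on[u]);
    } else {
      used[u] = true;
      state.push_back(kind[u] == 0 ? 1 : 2);
      anchor.push_back(on[u]);
    }
  }
  return List::create(_["state"] = wrap(state), _["anchor"] = wrap(anchor));
}

// Count of overlapping orofacial-head pairs (states 3, 4, 5) under the
// same greedy pairing; fast path for the permutation null.
// [[Rcpp::export]]
int cpp_overlap_count(IntegerVector o_on, IntegerVector o_off,
                      IntegerVector h_on, IntegerVector h_off) {
  List res = cpp_pair_states(o_on, o_off, h_on, h_off);
  IntegerVector st = res["state"];
  int cnt = 0;
  for (int i = 0; i < st.size(); ++i) if (st[i] >= 3) ++cnt;
  return cnt;
}
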