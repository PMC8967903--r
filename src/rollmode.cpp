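#include <Rcpp.h>
using namespace Rcpp;

// Centered rolling mode over integer bin ids (0..n_bins-1) with edge truncation.
// Ties broken toward the smallest bin id so the baseline hugs the resting level.
// [[Rcpp::export]]
IntegerVector roll_mode_cpp(IntegerVector ids, int halfwidth, int n_bins) {
  int n = ids.size();
  IntegerVector out(n);
  std::vector<int> cnt(n_bins, 0);
  int best = -1, best_cnt = 0;

  auto add = [&](int id) {
    int c = ++cnt[id];
    if (c > best_cnt || (c == best_cnt && id < best)) { best = id; best_cnt = c; }
  };
  auto rescan = [&]() {
    best = -1; best_cnt = 0;
    for (int b = 0; b < n_bins; ++b)
      if (cnt[b] > best_cnt) { best = b; best_cnt = cnt[b]; }
  };

  // initial window [0, min(n, halfwidth+1))
  int hi = std::min(n, halfwidth + 1);
  for (int k = 0; k < hi; ++k) add(ids[k]);
  out[0] = best;
  for (int i = 1; i < n; ++i) {
    int add_k = i + halfwidth, rm_k = i - halfwidth - 1;
    if (add_k < n) add(ids[add_k]);
    if (rm_k >= 0) {
      int id = ids[rm_k];
      --cnt[id];
      if (id == best) { --best_cnt; rescan(); }
    }
    out[i] = best;
  }
  return out;
}
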