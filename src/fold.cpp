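#include <Rcpp.h>
#include <array>
#include <vector>
#include <string>

using namespace Rcpp;

// Base-pair scores for the built-in folding engine: GC=3, AU=2, GU=1,
// +1 bonus when a pair stacks directly inside another pair.
// Minimum hairpin loop of 3 unpaired bases.
static const int MINLOOP = 3;
static const int NEG = -1000000;

static inline int pair_score(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return NEG;
}

// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
List nussinov_fold_cpp(std::string seq) {
  const int n = (int) seq.size();
  if (n == 0) return List::create(_["dotbracket"] = "", _["score"] = 0);
  // M[i][j]: best score on [i, j]; P[i][j]: best score with (i, j) paired.
  std::vector<int> M((size_t) n * n, 0), P((size_t) n * n, NEG);
  auto idx = [n](int i, int j) { return (size_t) i * n + j; };

  for (int len = MINLOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int ps = pair_score(seq[i], seq[j]);
      if (ps > NEG) {
        int inner = M[idx(i + 1, j - 1)];
        int Pin = P[idx(i + 1, j - 1)];
        int best = inner;
        if (Pin > NEG && Pin + 1 > best) best = Pin + 1;  // stacked
        P[idx(i, j)] = ps + best;
      }
      int best = M[idx(i + 1, j)];  // i unpaired
      for (int k = i + MINLOOP + 1; k <= j; ++k) {
        int p = P[idx(i, k)];
        if (p == NEG) continue;
        int rest = (k + 1 <= j) ? M[idx(k + 1, j)] : 0;
        if (p + rest > best) best = p + rest;
      }
      M[idx(i, j)] = best;
    }
  }

  // Traceback (deterministic: unpaired-first for M, stacked-first for P).
  std::string db(n, '.');
  std::vector<std::array<int, 3>> stack;  // {i, j, mode} mode 0 = M, 1 = P
  stack.push_back({0, n - 1, 0});
  while (!stack.empty()) {
    auto st = stack.back();
    stack.pop_back();
    int i = st[0], j = st[1], mode = st[2];
    if (i >= j) continue;
    if (mode == 0) {
      if (j - i + 1 < MINLOOP + 2 || M[idx(i, j)] == 0) continue;
      if (M[idx(i, j)] == M[idx(i + 1, j)]) {
        stack.push_back({i + 1, j, 0});
        continue;
      }
      for (int k = i + MINLOOP + 1; k <= j; ++k) {
        int p = P[idx(i, k)];
        if (p == NEG) continue;
        int rest = (k + 1 <= j) ? M[idx(k + 1, j)] : 0;
        if (p + rest == M[idx(i, j)]) {
          stack.push_back({i, k, 1});
          if (k + 1 <= j) stack.push_back({k + 1, j, 0});
          break;
        }
      }
    } else {
      db[i] = '(';
      db[j] = ')';
      int ps = pair_score(seq[i], seq[j]);
      int Pin = P[idx(i + 1, j - 1)];
      if (Pin > NEG && ps + Pin + 1 == P[idx(i, j)]) {
        stack.push_back({i + 1, j - 1, 1});
      } else {
        stack.push_back({i + 1, j - 1, 0});
      }
    }
  }
  return List::create(_["dotbracket"] = db, _["score"] = M[idx(0, n - 1)]);
}

// Antisense-arm prescreen: does `window` contain a region, outside the mature
// interval, that pairs the mature (Watson-Crick or G:U) with at most
// `max_mm` unpaired mature bases, allowing at most one bulge of size
// <= max_bulge on either strand? Necessary condition for the hairpin
// criteria; cheap enough to screen thousands of windows before folding.
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export(name = ".star_arm_scan_cpp")]]
bool star_arm_scan_cpp(std::string window, int mature_start0, int mature_len,
                       int max_mm, int max_bulge) {
  const int n = (int) window.size();
  const int L = mature_len;
  if (mature_start0 < 0 || mature_start0 + L > n) return false;
  // mism[i][t]: mature position i (0-based, 5'->3') against window index t,
  // in antisense orientation: mature[i] pairs window[t - i] for ungapped
  // alignment anchored at t = (start of pairing of mature[0]).
  // Scan anchors t (window position pairing mature position 0), alignments
  // running downstream-to-upstream on the window.
  for (int t = L - 1; t < n; ++t) {
    // skip alignments whose window-side arm overlaps the mature itself
    int lo = t - L + 1 - max_bulge;  // smallest window index an alignment may touch
    int hi = t;
    if (!(hi < mature_start0 || lo > mature_start0 + L - 1)) continue;
    // one bulge of size s (0..max_bulge) on the window strand inserted after
    // mature position b, or on the mature strand (skipping mature bases).
    for (int s = 0; s <= max_bulge; ++s) {
      int maxb = (s == 0) ? 0 : L - 1;
      for (int b = 0; b <= maxb; ++b) {
        // window-strand bulge: mature[i] pairs window[t - i - (i > b ? s : 0)]
        int mm = 0;
        bool ok = true;
        for (int i = 0; i < L; ++i) {
          int w = t - i - (i > b ? s : 0);
          if (w < 0) { ok = false; break; }
          if (!can_pair(window[(size_t) i + mature_start0], window[(size_t) w])) ++mm;
          if (mm > max_mm) { ok = false; break; }
        }
        if (ok && mm <= max_mm) return true;
        if (s > 0) {
          // mature-strand bulge: mature bases b+1..b+s unpaired (count toward mm),
          // window advances without them.
          mm = s;
          ok = (mm <= max_mm);
          for (int i = 0; ok && i < L; ++i) {
            if (i > b && i <= b + s) continue;  // bulged-out mature base
            int w = t - i + (i > b + s ? s : 0);
            if (w < 0 || w >= n) { ok = false; break; }
            if (!can_pair(window[(size_t) i + mature_start0], window[(size_t) w])) ++mm;
            if (mm > max_mm) ok = false;
          }
          if (ok && mm <= max_mm) return true;
        }
      }
    }
  }
  return false;
}

// [[Rcpp::export(name = ".star_arm_scan_batch_cpp")]]
LogicalVector star_arm_scan_batch_cpp(CharacterVector windows,
                                      IntegerVector mature_start0,
                                      IntegerVector mature_len,
                                      int max_mm, int max_bulge) {
  const int n = windows.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = star_arm_scan_cpp(as<std::string>(windows[i]), mature_start0[i],
                               mature_len[i], max_mm, max_bulge);
  }
  return out;
}
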