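#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Levenshtein distance capped at `cap`: returns the exact distance when it
// is < cap, otherwise `cap`.  Banded DP (cells with |i-j| >= cap cannot lie
// on a path of cost < cap) with row-minimum early abandon; `prev`/`cur` are
// caller-provided scratch rows of length >= nb + 2 to avoid per-call
// allocation in the window scan.
static int lev_capped(const char *a, int na, const char *b, int nb, int cap,
                      int *prev, int *cur) {
  if (cap <= 0) return 0;
  int diff = na > nb ? na - nb : nb - na;
  if (diff >= cap) return cap;
  const int BIG = cap + 1;
  for (int j = 0; j <= nb; ++j) prev[j] = j < cap ? j : BIG;
  for (int i = 1; i <= na; ++i) {
    int jlo = i - cap + 1;
    if (jlo < 1) jlo = 1;
    int jhi = i + cap - 1;
    if (jhi > nb) jhi = nb;
    cur[jlo - 1] = (jlo == 1 && i < cap) ? i : BIG;
    if (jhi == i + cap - 1) prev[jhi] = BIG;  // beyond the previous row's band
    int rowmin = cur[jlo - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int v = sub < del ? sub : del;
      if (ins < v) v = ins;
      if (v > BIG) v = BIG;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin >= cap) return cap;
    std::swap(prev, cur);
  }
  return prev[nb] < cap ? prev[nb] : cap;
}

// Minimum Levenshtein distance between `suffix` and every length-`wlen`
// window of `seqs`, excluding windows of seqs[excl_seq[t]] (0-based) that
// overlap the half-open interval [excl_lo[t], excl_hi[t]).
// Returns -1 when no window is eligible (sentinel for +Inf).
// [[Rcpp::export]]
int cpp_min_lev_windows(std::string suffix, CharacterVector seqs, int wlen,
                        IntegerVector excl_seq, IntegerVector excl_lo,
                        IntegerVector excl_hi) {
  int best = INT_MAX;
  bool any = false;
  const char *a = suffix.c_str();
  int na = (int)suffix.size();
  int ne = excl_seq.size();
  std::vector<int> buf1(wlen + 2), buf2(wlen + 2);
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    int n = (int)seq.size();
    for (int j = 0; j + wlen <= n; ++j) {
      bool skip = false;
      for (int t = 0; t < ne; ++t) {
        if (excl_seq[t] == s && j < excl_hi[t] && j + wlen > excl_lo[t]) {
          skip = true;
          break;
        }
      }
      if (skip) continue;
      any = true;
      int cap = (best == INT_MAX) ? (na + wlen) : best;
      int d = lev_capped(a, na, seq.c_str() + j, wlen, cap,
                         buf1.data(), buf2.data());
      if (d < best) {
        best = d;
        if (best == 0) return 0;
      }
    }
  }
  return any ? best : -1;
}

// Batch form of the suffix screen for design_probes(): candidate i excludes
// only windows of seqs[src[i]] overlapping its own site [lo[i], hi[i]).
// src[i] may be -1 (no exclusion, e.g. target not among screened sequences).
// [[Rcpp::export]]
IntegerVector cpp_screen_batch(CharacterVector suffixes, IntegerVector src,
                               IntegerVector lo, IntegerVector hi,
                               CharacterVector seqs, int wlen) {
  int nc = suffixes.size();
  int ns = seqs.size();
  std::vector<std::string> ss(ns);
  for (int s = 0; s < ns; ++s) ss[s] = as<std::string>(seqs[s]);
  std::vector<int> buf1(wlen + 2), buf2(wlen + 2);
  IntegerVector out(nc);
  for (int i = 0; i < nc; ++i) {
    std::string suf = as<std::string>(suffixes[i]);
    const char *a = suf.c_str();
    int na = (int)suf.size();
    int best = INT_MAX;
    bool any = false;
    for (int s = 0; s < ns; ++s) {
      const std::string &seq = ss[s];
      int n = (int)seq.size();
      for (int j = 0; j + wlen <= n; ++j) {
        if (src[i] == s && j < hi[i] && j + wlen > lo[i]) continue;
        any = true;
        int cap = (best == INT_MAX) ? (na + wlen) : best;
        int d = lev_capped(a, na, seq.c_str() + j, wlen, cap,
                           buf1.data(), buf2.data());
        if (d < best) {
          best = d;
          if (best == 0) break;
        }
      }
      if (best == 0) break;
    }
    out[i] = any ? best : -1;
  }
  return out;
}

// 8-connected component labelling of a logical mask (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int cur = 0;
  std::vector<std::pair<int, int> > stack;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (mask(y, x) && lab(y, x) == 0) {
        ++cur;
        lab(y, x) = cur;
        stack.push_back(std::make_pair(y, x));
        while (!stack.empty()) {
          int cy = stack.back().first, cx = stack.back().second;
          stack.pop_back();
          for (int dy = -1; dy <= 1; ++dy) {
            for (int dx = -1; dx <= 1; ++dx) {
              int yy = cy + dy, xx = cx + dx;
              if (yy >= 0 && yy < ny && xx >= 0 && xx < nx && mask(yy, xx) &&
                  lab(yy, xx) == 0) {
                lab(yy, xx) = cur;
                stack.push_back(std::make_pair(yy, xx));
              }
            }
          }
        }
      }
    }
  }
  return lab;
}

// Strict local maxima of a (ny, nx, ns) scale-space cube above `thr`:
// a voxel is retained iff its value exceeds every in-bounds neighbour in the
// 3x3x3 neighbourhood.  Returns a k x 4 matrix: y, x, scale index (0-based),
// value.
// [[Rcpp::export]]
NumericMatrix cpp_local_max3(NumericVector cube, double thr) {
  IntegerVector dm = cube.attr("dim");
  int ny = dm[0], nx = dm[1], ns = dm[2];
  std::vector<double> ys, xs, ks, vs;
  for (int k = 0; k < ns; ++k) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        double v = cube[y + ny * (x + nx * k)];
        if (!(v > thr)) continue;
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; ++dk) {
          for (int dx = -1; dx <= 1 && ismax; ++dx) {
            for (int dy = -1; dy <= 1 && ismax; ++dy) {
              if (dy == 0 && dx == 0 && dk == 0) continue;
              int yy = y + dy, xx = x + dx, kk = k + dk;
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || kk < 0 ||
                  kk >= ns)
                continue;
              if (!(v > cube[yy + ny * (xx + nx * kk)])) ismax = false;
            }
          }
        }
        if (ismax) {
          ys.push_back((double)y);
          xs.push_back((double)x);
          ks.push_back((double)k);
          vs.push_back(v);
        }
      }
    }
  }
  int m = (int)ys.size();
  NumericMatrix out(m, 4);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = ys[i];
    out(i, 1) = xs[i];
    out(i, 2) = ks[i];
    out(i, 3) = vs[i];
  }
  colnames(out) = CharacterVector::create("y", "x", "scale_idx", "response");
  return out;
}
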