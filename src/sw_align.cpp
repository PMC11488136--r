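// Affine-gap local alignment of short fragments against every reference
// path, with traceback on the best hit. Bases are coded A=0,C=1,G=2,T=3,
// N=4; N scores as a mismatch against everything and is classified as an
// unresolved base. A gap of length L costs gap_open + L * gap_ext.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {

struct Scoring {
  double match, mismatch, gap_open, gap_ext;
};

inline double subscore(int a, int b, const Scoring& sc) {
  return (a == b && a < 4) ? sc.match : sc.mismatch;
}

// Score-only pass: O(n) memory. Integer kernel: scoring parameters are
// scaled by 4 and rounded, which is exact for the integer and
// quarter-integer scores used in practice.
double sw_score_only(const std::vector<int>& r, const std::vector<int>& s,
                     const Scoring& sc) {
  const int m = (int)r.size(), n = (int)s.size();
  const int NEG = -(1 << 28);
  const int ma = (int)std::lround(4.0 * sc.match);
  const int mi = (int)std::lround(4.0 * sc.mismatch);
  const int goe = (int)std::lround(4.0 * (sc.gap_open + sc.gap_ext));
  const int ge = (int)std::lround(4.0 * sc.gap_ext);
  std::vector<int> H(n + 1, 0), E(n + 1, NEG);
  int* Hp = H.data();
  int* Ep = E.data();
  int best = 0;
  int q[5];
  for (int i = 1; i <= m; ++i) {
    int diag = 0;            // H[i-1][j-1]
    int F = NEG;
    const int ri = r[i - 1];
    for (int b = 0; b < 5; ++b) q[b] = (b == ri && ri < 4) ? ma : mi;
    const int* sp = s.data();
    for (int j = 1; j <= n; ++j) {
      const int up = Hp[j];  // H[i-1][j]
      int e = Ep[j] - ge;
      const int eo = up - goe;
      e = eo > e ? eo : e;
      Ep[j] = e;
      int f = F - ge;
      const int fo = Hp[j - 1] - goe;
      f = fo > f ? fo : f;
      F = f;
      int h = diag + q[sp[j - 1]];
      h = e > h ? e : h;
      h = f > h ? f : h;
      h = h < 0 ? 0 : h;
      diag = up;
      Hp[j] = h;
      best = h > best ? h : best;
    }
  }
  return best / 4.0;
}

// Full pass with packed direction bytes for traceback.
// byte layout: bits 0-1 H-choice (0 stop, 1 diag, 2 E, 3 F),
// bit 2: E opened from H, bit 3: F opened from H.
double sw_traceback(const std::vector<int>& r, const std::vector<int>& s,
                    const Scoring& sc, int& bi, int& bj,
                    std::vector<unsigned char>& dir) {
  const int m = (int)r.size(), n = (int)s.size();
  dir.assign((size_t)(m + 1) * (n + 1), 0);
  std::vector<double> H(n + 1, 0.0), E(n + 1, R_NegInf);
  double best = 0.0;
  bi = bj = 0;
  for (int i = 1; i <= m; ++i) {
    double diag = 0.0;
    double F = R_NegInf;
    unsigned char* drow = &dir[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      const double up = H[j];
      unsigned char d = 0;
      double e = E[j] - sc.gap_ext;
      double eo = up - sc.gap_open - sc.gap_ext;
      if (eo >= e) { e = eo; d |= 4; }
      E[j] = e;
      double f = F - sc.gap_ext;
      double fo = H[j - 1] - sc.gap_open - sc.gap_ext;
      if (fo >= f) { f = fo; d |= 8; }
      F = f;
      double sc_d = diag + subscore(r[i - 1], s[j - 1], sc);
      double h = sc_d;
      unsigned char choice = 1;
      if (e > h) { h = e; choice = 2; }
      if (f > h) { h = f; choice = 3; }
      if (h <= 0.0) { h = 0.0; choice = 0; }
      d |= choice;
      drow[j] = d;
      diag = up;
      H[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  return best;
}

enum Event { MATCH = 0, MISMATCH = 1, INSERTION = 2, DELETION = 3,
             SOFTCLIP = 4, UNRESOLVED = 5 };

} // namespace

// [[Rcpp::export(name = ".align_reads_cpp")]]
List align_reads_cpp(List reads, List paths, double match, double mismatch,
                     double gap_open, double gap_ext, double min_score_frac) {
  Scoring sc{match, mismatch, gap_open, gap_ext};
  const int npath = paths.size();
  std::vector<std::vector<int>> P(npath);
  for (int p = 0; p < npath; ++p) {
    IntegerVector v = paths[p];
    P[p].assign(v.begin(), v.end());
  }
  const int nreads = reads.size();
  List out(nreads);
  std::vector<unsigned char> dir;
  for (int ri = 0; ri < nreads; ++ri) {
    IntegerVector rv = reads[ri];
    const int m = rv.size();
    std::vector<int> fwd(rv.begin(), rv.end());
    std::vector<int> rc(m);
    for (int i = 0; i < m; ++i) {
      int b = fwd[m - 1 - i];
      rc[i] = (b < 4) ? 3 - b : 4;
    }
    double best = R_NegInf;
    int best_path = -1, best_orient = 0;
    for (int p = 0; p < npath; ++p) {
      double sf = sw_score_only(fwd, P[p], sc);
      if (sf > best) { best = sf; best_path = p; best_orient = 1; }
      double sr = sw_score_only(rc, P[p], sc);
      if (sr > best) { best = sr; best_path = p; best_orient = -1; }
    }
    const double min_score = min_score_frac * m * match;
    if (best_path < 0 || best < min_score) {
      out[ri] = List::create(_["mapped"] = false);
      continue;
    }
    const std::vector<int>& rr = (best_orient == 1) ? fwd : rc;
    int bi, bj;
    sw_traceback(rr, P[best_path], sc, bi, bj, dir);
    // traceback: collect (read_pos, ref_pos, event) from end to start
    std::vector<int> ev_read, ev_ref, ev_code;
    const int n = (int)P[best_path].size();
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E, 2 = F
    while (i > 0 && j > 0) {
      unsigned char d = dir[(size_t)i * (n + 1) + j];
      if (state == 0) {
        int choice = d & 3;
        if (choice == 0) break;
        if (choice == 1) {
          int rb = rr[i - 1];
          int code = (rb == 4) ? UNRESOLVED
                               : (rb == P[best_path][j - 1] ? MATCH : MISMATCH);
          ev_read.push_back(i - 1);
          ev_ref.push_back(code == UNRESOLVED ? -1 : j - 1);
          ev_code.push_back(code);
          --i; --j;
        } else if (choice == 2) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) { // E: gap in reference, read base consumed
        int rb = rr[i - 1];
        ev_read.push_back(i - 1);
        ev_ref.push_back(-1);
        ev_code.push_back(rb == 4 ? UNRESOLVED : INSERTION);
        bool opened = (d & 4) != 0;
        --i;
        if (opened) state = 0;
      } else { // F: gap in read, reference base consumed
        ev_read.push_back(-1);
        ev_ref.push_back(j - 1);
        ev_code.push_back(DELETION);
        bool opened = (d & 8) != 0;
        --j;
        if (opened) state = 0;
      }
    }
    // alignment core read span in the aligned orientation
    int core_lo = m, core_hi = -1;
    for (size_t q = 0; q < ev_read.size(); ++q) {
      if (ev_read[q] >= 0) {
        if (ev_read[q] < core_lo) core_lo = ev_read[q];
        if (ev_read[q] > core_hi) core_hi = ev_read[q];
      }
    }
    std::vector<int> rows_read, rows_ref, rows_code;
    for (int q = 0; q < core_lo; ++q) {
      int rb = rr[q];
      rows_read.push_back(q);
      rows_ref.push_back(-1);
      rows_code.push_back(rb == 4 ? UNRESOLVED : SOFTCLIP);
    }
    for (size_t q = ev_read.size(); q-- > 0;) {
      rows_read.push_back(ev_read[q]);
      rows_ref.push_back(ev_ref[q]);
      rows_code.push_back(ev_code[q]);
    }
    for (int q = core_hi + 1; q < m; ++q) {
      int rb = rr[q];
      rows_read.push_back(q);
      rows_ref.push_back(-1);
      rows_code.push_back(rb == 4 ? UNRESOLVED : SOFTCLIP);
    }
    const int nr = (int)rows_read.size();
    IntegerMatrix evm(nr, 3);
    for (int q = 0; q < nr; ++q) {
      int rp = rows_read[q];
      // report positions on the original fragment strand
      if (rp >= 0 && best_orient == -1) rp = m - 1 - rp;
      evm(q, 0) = rp;
      evm(q, 1) = rows_ref[q];
      evm(q, 2) = rows_code[q];
    }
    out[ri] = List::create(
      _["mapped"] = true,
      _["path"] = best_path + 1,
      _["orient"] = best_orient,
      _["score"] = best,
      _["events"] = evm);
  }
  return out;
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(IntegerVector read, IntegerVector ref, double match,
                    double mismatch, double gap_open, double gap_ext) {
  Scoring sc{match, mismatch, gap_open, gap_ext};
  std::vector<int> r(read.begin(), read.end()), s(ref.begin(), ref.end());
  return sw_score_only(r, s, sc);
}
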