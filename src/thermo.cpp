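// Exhaustive ungapped antiparallel dimer window scan and hairpin stem/loop
// scan. Nearest-neighbor stack parameters are passed from R as flat
// 256-entry lookup tables indexed by ((a1*4+a2)*4+c1)*4+c2 where a1,a2 are
// the top dinucleotide 5'->3' and c1,c2 the bottom dinucleotide 3'->5'
// (base codes A=0,C=1,G=2,T=3); entries absent from the parameter set are
// NaN. Windows must start and end on Watson-Crick columns; a NaN stack
// (tandem mismatch or unparameterized pair) breaks a window.

#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int code4(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline bool is_wc(int a, int b) { return a + b == 3 && a >= 0; } // A/T=0/3, C/G=1/2

struct BestWindow {
  bool found = false;
  double dG = 0.0, dH = 0.0, dS = 0.0;
  int nstacks = 0, offset = 0, i = 0, j = 0;
  bool selfcomp = false;
};

// score all trimmed windows of one offset's column list
static void scan_offset(const std::vector<int>& top,
                        const std::vector<int>& bot,
                        int offset,
                        const NumericVector& st_dH, const NumericVector& st_dS,
                        double initAT_dH, double initAT_dS,
                        double initGC_dH, double initGC_dS,
                        double sym_dH, double sym_dS,
                        double tempK, double salt_ds, bool allow_selfcomp,
                        BestWindow& best) {
  const int m = (int)top.size();
  if (m < 2) return;
  std::vector<bool> wc(m);
  for (int t = 0; t < m; ++t) wc[t] = is_wc(top[t], bot[t]);
  // per-adjacent-pair stack terms
  std::vector<double> sdH(m - 1), sdS(m - 1);
  std::vector<bool> ok(m - 1);
  for (int t = 0; t < m - 1; ++t) {
    int idx = ((top[t] * 4 + top[t + 1]) * 4 + bot[t]) * 4 + bot[t + 1];
    double h = st_dH[idx];
    ok[t] = !ISNAN(h);
    sdH[t] = ok[t] ? h : 0.0;
    sdS[t] = ok[t] ? st_dS[idx] : 0.0;
  }
  // prefix sums over stacks
  std::vector<double> pH(m), pS(m);
  pH[0] = 0.0; pS[0] = 0.0;
  for (int t = 0; t < m - 1; ++t) {
    pH[t + 1] = pH[t] + sdH[t];
    pS[t + 1] = pS[t] + sdS[t];
  }
  auto init_dH = [&](int t) { return (top[t] == 0 || top[t] == 3) ? initAT_dH : initGC_dH; };
  auto init_dS = [&](int t) { return (top[t] == 0 || top[t] == 3) ? initAT_dS : initGC_dS; };
  // segments of consecutive defined stacks
  int seg_start = 0;
  while (seg_start < m - 1) {
    if (!ok[seg_start]) { ++seg_start; continue; }
    int seg_end = seg_start; // inclusive index into stacks
    while (seg_end + 1 < m - 1 && ok[seg_end + 1]) ++seg_end;
    // columns seg_start .. seg_end+1 are connected
    for (int i = seg_start; i <= seg_end; ++i) {
      if (!wc[i]) continue;
      for (int j = i + 1; j <= seg_end + 1; ++j) {
        if (!wc[j]) continue;
        int ns = j - i;
        double dH = pH[j] - pH[i] + init_dH(i) + init_dH(j);
        double dS = pS[j] - pS[i] + init_dS(i) + init_dS(j);
        bool sc = false;
        if (allow_selfcomp) {
          // self-complementary window duplex: top == reverse(bottom) and palindromic
          sc = true;
          for (int t = 0; t <= ns && sc; ++t) {
            if (top[i + t] != bot[j - t]) sc = false;            // top == rev(bottom)
            if (!is_wc(top[i + t], top[j - t])) sc = false;      // palindrome
          }
          if (sc) { dH += sym_dH; dS += sym_dS; }
        }
        double dS_corr = dS + ns * salt_ds;
        double dG = dH - tempK * dS_corr / 1000.0;
        if (dG < 0.0 && (!best.found || dG < best.dG)) {
          best.found = true;
          best.dG = dG; best.dH = dH; best.dS = dS;
          best.nstacks = ns; best.offset = offset; best.i = i; best.j = j;
          best.selfcomp = sc;
        }
      }
    }
    seg_start = seg_end + 1;
  }
}

// [[Rcpp::export(name = ".cpp_dimer_scan")]]
List cpp_dimer_scan(std::string s1, std::string s2,
                    NumericVector st_dH, NumericVector st_dS,
                    double initAT_dH, double initAT_dS,
                    double initGC_dH, double initGC_dS,
                    double sym_dH, double sym_dS,
                    double tempK, double salt_ds, bool allow_selfcomp) {
  const int L1 = (int)s1.size(), L2 = (int)s2.size();
  std::vector<int> a(L1), b2(L2);
  for (int i = 0; i < L1; ++i) a[i] = code4(s1[i]);
  // bottom strand laid out 3'->5' left-to-right = reverse of s2
  for (int i = 0; i < L2; ++i) b2[i] = code4(s2[L2 - 1 - i]);
  BestWindow best;
  for (int o = -(L2 - 1); o <= L1 - 1; ++o) {
    int lo = std::max(0, o), hi = std::min(L1 - 1, o + L2 - 1);
    if (hi - lo + 1 < 2) continue;
    std::vector<int> top(a.begin() + lo, a.begin() + hi + 1);
    std::vector<int> bot(hi - lo + 1);
    for (int t = 0; t <= hi - lo; ++t) bot[t] = b2[lo + t - o];
    scan_offset(top, bot, o, st_dH, st_dS, initAT_dH, initAT_dS,
                initGC_dH, initGC_dS, sym_dH, sym_dS,
                tempK, salt_ds, allow_selfcomp, best);
  }
  return List::create(_["found"] = best.found, _["dH"] = best.dH,
                      _["dS"] = best.dS, _["nstacks"] = best.nstacks,
                      _["offset"] = best.offset,
                      _["i"] = best.i + 1, _["j"] = best.j + 1,
                      _["selfcomp"] = best.selfcomp);
}

// [[Rcpp::export(name = ".cpp_hairpin_scan")]]
List cpp_hairpin_scan(std::string s, int min_stem, int min_loop,
                      NumericVector loop_dS, // indexed by loop size (1-based)
                      NumericVector st_dH, NumericVector st_dS,
                      double tempK, double salt_ds) {
  const int L = (int)s.size();
  std::vector<int> a(L);
  for (int i = 0; i < L; ++i) a[i] = code4(s[i]);
  bool found = false;
  double bdG = 0.0, bdH = 0.0, bdS = 0.0;
  int bi = 0, bstem = 0, bloop = 0;
  for (int i = 0; i < L; ++i) {
    for (int stem = min_stem; 2 * stem + min_loop + i <= L; ++stem) {
      for (int loop = min_loop; i + 2 * stem + loop <= L; ++loop) {
        if (loop >= loop_dS.size()) break;
        int j = i + stem + loop; // 3' arm start
        // 3' arm must be the reverse complement of the 5' arm
        bool okrc = true;
        for (int t = 0; t < stem && okrc; ++t) {
          if (!is_wc(a[i + t], a[j + stem - 1 - t])) okrc = false;
        }
        if (!okrc) continue;
        double dH = 0.0, dS = 0.0;
        for (int t = 0; t < stem - 1; ++t) {
          int a1 = a[i + t], a2 = a[i + t + 1];
          int c1 = 3 - a1, c2 = 3 - a2; // WC partners
          int idx = ((a1 * 4 + a2) * 4 + c1) * 4 + c2;
          dH += st_dH[idx];
          dS += st_dS[idx];
        }
        dS += loop_dS[loop - 1];
        double dS_corr = dS + (stem - 1) * salt_ds;
        double dG = dH - tempK * dS_corr / 1000.0;
        if (dG < 0.0 && (!found || dG < bdG)) {
          found = true; bdG = dG; bdH = dH; bdS = dS;
          bi = i; bstem = stem; bloop = loop;
        }
      }
    }
  }
  return List::create(_["found"] = found, _["dH"] = bdH, _["dS"] = bdS,
                      _["nstacks"] = bstem - 1, _["i"] = bi + 1,
                      _["stem"] = bstem, _["loop"] = bloop);
}
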