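#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive small-RNA : target-site duplex enumeration.
//
// The miRNA (integer-coded, 5'->3', A=0 C=1 G=2 T=3, N=4) is walked
// antiparallel along the transcript. A candidate alignment is defined by
// the transcript coordinate paired with miRNA position 1 (the site 3' end)
// and a bulge pattern: up to max_bulges unpaired nucleotides on either
// strand, never at the central (slicing) miRNA positions. Every
// (site end, pattern) pair whose Allen penalty stays within max_allen is
// reported; minimum-free-energy filtering and overlap reduction happen in
// R on the survivors.
//
// Pairing symbols: '|' Watson-Crick, 'o' G:U wobble, 'x' mismatch,
// '-' bulged miRNA nucleotide, '^' bulged target nucleotide (written
// before the symbol of the miRNA position whose slot it occupies).

static inline int pair_class(int m, int t) {
  // 0 = WC, 1 = GU, 2 = mismatch. DNA coding, so U==T (3).
  if (m > 3 || t > 3) return 2;
  if ((m == 0 && t == 3) || (m == 3 && t == 0) ||
      (m == 1 && t == 2) || (m == 2 && t == 1)) return 0;
  if ((m == 2 && t == 3) || (m == 3 && t == 2)) return 1;
  return 2;
}

struct Pattern {
  std::vector<int> mi_bulge;   // miRNA positions left unpaired (1-based)
  std::vector<int> t_slot;     // slots i: extra target nt before position i
};

static void build_patterns(int m, int max_bulges,
                           int central_lo, int central_hi,
                           std::vector<Pattern>& out) {
  out.push_back(Pattern());  // ungapped
  std::vector<int> bpos, slots;
  for (int i = 2; i <= m - 1; ++i)
    if (i < central_lo || i > central_hi) bpos.push_back(i);
  // slot i sits between pairings i-1 and i; slot central_hi would open
  // the helix between the slicing positions
  for (int i = 2; i <= m; ++i)
    if (i != central_hi) slots.push_back(i);
  if (max_bulges >= 1) {
    for (int b : bpos) { Pattern p; p.mi_bulge = {b}; out.push_back(p); }
    for (int s : slots) { Pattern p; p.t_slot = {s}; out.push_back(p); }
  }
  if (max_bulges >= 2) {
    for (size_t a = 0; a < bpos.size(); ++a)
      for (size_t b = a + 1; b < bpos.size(); ++b) {
        Pattern p; p.mi_bulge = {bpos[a], bpos[b]}; out.push_back(p);
      }
    for (size_t a = 0; a < slots.size(); ++a)
      for (size_t b = a; b < slots.size(); ++b) {  // a==b: 2-nt bulge
        Pattern p; p.t_slot = {slots[a], slots[b]}; out.push_back(p);
      }
    for (int b : bpos)
      for (int s : slots) {
        Pattern p; p.mi_bulge = {b}; p.t_slot = {s}; out.push_back(p);
      }
  }
}

// [[Rcpp::export(name = ".scan_duplexes_cpp")]]
DataFrame scan_duplexes_cpp(IntegerVector tx, IntegerVector mi,
                            double max_allen,
                            double mm_pen, double gu_pen, double bulge_pen,
                            int dbl_lo, int dbl_hi, double dbl_mult,
                            int max_bulges, int central_lo, int central_hi,
                            int cleave_pos_mi) {
  const int n = tx.size(), m = mi.size();
  std::vector<Pattern> pats;
  build_patterns(m, max_bulges, central_lo, central_hi, pats);

  std::vector<int> r_start, r_end, r_cleav;
  std::vector<double> r_allen;
  std::vector<std::string> r_pair;

  std::string sym;
  sym.reserve(m + max_bulges);
  for (const Pattern& pat : pats) {
    int t_extra = (int)pat.t_slot.size();
    int mi_b = (int)pat.mi_bulge.size();
    int span = m - mi_b + t_extra;          // target nts consumed
    for (int e = span - 1; e < n; ++e) {    // 0-based site end
      double pen = 0.0;
      int t = e;
      int cleav = -1;
      bool ok = true;
      sym.clear();
      for (int i = 1; i <= m; ++i) {
        double mult = (i >= dbl_lo && i <= dbl_hi) ? dbl_mult : 1.0;
        for (int s : pat.t_slot)
          if (s == i) {
            pen += bulge_pen * mult;
            sym.push_back('^');
            --t;
          }
        bool bulged = false;
        for (int b : pat.mi_bulge)
          if (b == i) { bulged = true; break; }
        if (bulged) {
          pen += bulge_pen * mult;
          sym.push_back('-');
        } else {
          int cls = pair_class(mi[i - 1], tx[t]);
          if (cls == 1) pen += gu_pen * mult;
          else if (cls == 2) pen += mm_pen * mult;
          sym.push_back(cls == 0 ? '|' : (cls == 1 ? 'o' : 'x'));
          if (i == cleave_pos_mi) cleav = t;
          --t;
        }
        if (pen > max_allen + 1e-9) { ok = false; break; }
      }
      if (!ok) continue;
      r_start.push_back(t + 2);        // 1-based site start
      r_end.push_back(e + 1);
      r_cleav.push_back(cleav + 1);
      r_allen.push_back(pen);
      r_pair.push_back(sym);
    }
  }
  return DataFrame::create(
    _["site_start"] = r_start, _["site_end"] = r_end,
    _["cleavage_pos"] = r_cleav, _["allen_score"] = r_allen,
    _["pairing"] = r_pair, _["stringsAsFactors"] = false);
}
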