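// Exhaustive enumeration of gapped alignments, used as an independent
// optimality reference for the dynamic-programming aligner. Exponential:
// only sensible for short sequences (lengths <= ~8).
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Ctx {
  const int *a, *b;
  int na, nb;
  const double *sub;
  int nrow;
  double open, ext;
};

// state: 0 = no open gap / match, 1 = gap in a (consuming b), 2 = gap in b
double best_from(const Ctx &c, int i, int j, int state) {
  if (i == c.na && j == c.nb) return 0.0;
  double best = R_NegInf;
  if (i < c.na && j < c.nb) {
    double s = c.sub[c.a[i] + c.nrow * c.b[j]] + best_from(c, i + 1, j + 1, 0);
    if (s > best) best = s;
  }
  if (j < c.nb) { // gap in a, aligns b[j] to '-'
    double pen = (state == 1) ? c.ext : (c.open + c.ext);
    double s = -pen + best_from(c, i, j + 1, 1);
    if (s > best) best = s;
  }
  if (i < c.na) { // gap in b
    double pen = (state == 2) ? c.ext : (c.open + c.ext);
    double s = -pen + best_from(c, i + 1, j, 2);
    if (s > best) best = s;
  }
  return best;
}

} // namespace

// [[Rcpp::export]]
double enumerate_align_score(IntegerVector a, IntegerVector b,
                             NumericMatrix submat, double gap_open,
                             double gap_extend, bool local) {
  Ctx c;
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  c.sub = submat.begin();
  c.nrow = submat.nrow();
  c.open = gap_open;
  c.ext = gap_extend;
  if (!local) {
    c.a = av.data(); c.b = bv.data();
    c.na = av.size(); c.nb = bv.size();
    return best_from(c, 0, 0, 0);
  }
  // local: maximize the global score over all substring pairs; the empty
  // alignment scores 0
  double best = 0.0;
  int na = av.size(), nb = bv.size();
  for (int i1 = 0; i1 < na; ++i1)
    for (int i2 = i1; i2 < na; ++i2)
      for (int j1 = 0; j1 < nb; ++j1)
        for (int j2 = j1; j2 < nb; ++j2) {
          c.a = av.data() + i1; c.na = i2 - i1 + 1;
          c.b = bv.data() + j1; c.nb = j2 - j1 + 1;
          double s = best_from(c, 0, 0, 0);
          if (s > best) best = s;
        }
  return best;
}
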