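#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Direct / inverted repeat-pair scanner. A pair is an i-bp arm at 0-based
// position p whose partner starts exactly j bases downstream: the partner is
// an identical copy (direct) or the reverse complement (inverted). Pairs are
// identified by their leftmost coordinate on the top strand, so the mirrored
// description of the same inverted pair is not double counted. Footprint =
// [p, p + 2i + j).

static inline char cbase(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

struct Seq {
  const std::string &s;
  int G;
  bool circular;
  Seq(const std::string &s_, bool circ) : s(s_), G((int) s_.size()),
                                          circular(circ) {}
  bool valid(long x) const {
    return circular || (x >= 0 && x < G);
  }
  char at(long x) const {
    long m = x % G;
    if (m < 0) m += G;
    return s[(size_t) m];
  }
};

static bool match_direct(const Seq &sq, long p, int i, int j) {
  long d = i + j;
  for (int k = 0; k < i; ++k)
    if (sq.at(p + k) != sq.at(p + d + k)) return false;
  return true;
}

static bool match_inverted(const Seq &sq, long p, int i, int j) {
  long c = 2 * p + 2 * i + j - 1;  // paired indices x and c - x
  for (int k = 0; k < i; ++k)
    if (sq.at(p + k) != cbase(sq.at(c - (p + k)))) return false;
  return true;
}

// Arm-maximality. Direct pairs live on a run of matches at fixed offset
// d = i + j: the pair is maximal when that run extends neither left nor
// right. Inverted pairs live on a palindrome at fixed centre: maximal when
// not extendable outward, nor inward (inward extension needs j >= 2 so the
// new arm base comes from the spacer).
static bool extendable_direct(const Seq &sq, long p, int i, int j) {
  long d = i + j;
  if (sq.valid(p - 1) && sq.valid(p - 1 + d) &&
      sq.at(p - 1) == sq.at(p - 1 + d)) return true;
  if (sq.valid(p + i + d) && sq.at(p + i) == sq.at(p + i + d)) return true;
  return false;
}

static bool extendable_inverted(const Seq &sq, long p, int i, int j) {
  if (sq.valid(p - 1) && sq.valid(p + 2 * i + j) &&
      sq.at(p - 1) == cbase(sq.at(p + 2 * i + j))) return true;
  if (j >= 2 && sq.at(p + i) == cbase(sq.at(p + i + j - 1))) return true;
  return false;
}

// [[Rcpp::export(name = ".scan_repeats_cpp")]]
DataFrame scan_repeats_cpp(std::string genome, bool inverted,
                           IntegerVector i_values, IntegerVector j_values,
                           bool circular, bool arm_maximal) {
  if (i_values.size() == 0 || j_values.size() == 0)
    stop("arm-length and spacer ranges must be non-empty");
  for (size_t k = 0; k < genome.size(); ++k) {
    char c = genome[k];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T')
      stop("genome sequence contains a character outside {A,C,G,T}");
  }
  Seq sq(genome, circular);
  int G = sq.G;
  std::vector<int> out_i, out_j, out_p;
  for (int a = 0; a < i_values.size(); ++a) {
    int i = i_values[a];
    if (i < 1) stop("arm length must be >= 1");
    for (int b = 0; b < j_values.size(); ++b) {
      int j = j_values[b];
      if (j < 0) stop("spacer must be >= 0");
      long span = 2L * i + j;
      if (span > G) continue;
      int nstart = circular ? G : G - (int) span + 1;
      for (int p = 0; p < nstart; ++p) {
        bool hit = inverted ? match_inverted(sq, p, i, j)
                            : match_direct(sq, p, i, j);
        if (!hit) continue;
        if (arm_maximal) {
          bool ext = inverted ? extendable_inverted(sq, p, i, j)
                              : extendable_direct(sq, p, i, j);
          if (ext) continue;
        }
        out_i.push_back(i);
        out_j.push_back(j);
        out_p.push_back(p);  // 0-based; R wrapper shifts
      }
    }
  }
  return DataFrame::create(_["i"] = out_i, _["j"] = out_j,
                           _["start"] = out_p);
}
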