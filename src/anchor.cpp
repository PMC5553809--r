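#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Exact-match k-mer index over both strands of a (possibly circular) genome.
// Strand collapse: a read and its reverse complement resolve to the same left
// coordinate, because the index stores only top-strand k-mers and queries are
// looked up both as-is and reverse-complemented.

typedef std::unordered_map<std::string, std::vector<int> > KmerMap;

struct ExactIndexData {
  int G;
  int L;
  bool circular;
  KmerMap map;
};

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (std::string::iterator it = r.begin(); it != r.end(); ++it)
    *it = comp_base(*it);
  return r;
}

static void check_alphabet(const std::string &s) {
  for (size_t k = 0; k < s.size(); ++k) {
    char c = s[k];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T')
      stop("genome sequence contains a character outside {A,C,G,T}");
  }
}

// [[Rcpp::export(name = ".build_index_cpp")]]
SEXP build_index_cpp(std::string genome, int read_length, bool circular) {
  int G = (int) genome.size();
  if (read_length < 1 || read_length > G)
    stop("read_length must be in [1, genome length]");
  check_alphabet(genome);
  ExactIndexData *idx = new ExactIndexData();
  idx->G = G;
  idx->L = read_length;
  idx->circular = circular;
  // Origin-spanning k-mers are included for circular genomes.
  std::string s2 = circular && read_length > 1
    ? genome + genome.substr(0, read_length - 1) : genome;
  int nstart = circular ? G : G - read_length + 1;
  idx->map.reserve((size_t) nstart);
  for (int p = 0; p < nstart; ++p)
    idx->map[s2.substr(p, read_length)].push_back(p);
  XPtr<ExactIndexData> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".index_info_cpp")]]
List index_info_cpp(SEXP xp) {
  XPtr<ExactIndexData> idx(xp);
  return List::create(_["G"] = idx->G, _["L"] = idx->L,
                      _["circular"] = idx->circular);
}

// [[Rcpp::export(name = ".index_is_null_cpp")]]
bool index_is_null_cpp(SEXP xp) {
  return R_ExternalPtrAddr(xp) == NULL;
}

static std::vector<int> lookup_hits(const ExactIndexData *idx,
                                    const std::string &kmer) {
  std::vector<int> hits;
  KmerMap::const_iterator it = idx->map.find(kmer);
  if (it != idx->map.end()) hits = it->second;
  std::string rc = revcomp(kmer);
  if (rc != kmer) {  // a self-complementary read is one molecule: count once
    KmerMap::const_iterator it2 = idx->map.find(rc);
    if (it2 != idx->map.end())
      hits.insert(hits.end(), it2->second.begin(), it2->second.end());
  }
  std::sort(hits.begin(), hits.end());
  hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
  return hits;
}

// Returns 0-based left coordinates; the R wrapper shifts to 1-based.
// [[Rcpp::export(name = ".lookup_kmer_cpp")]]
IntegerVector lookup_kmer_cpp(SEXP xp, std::string kmer) {
  XPtr<ExactIndexData> idx(xp);
  if ((int) kmer.size() != idx->L)
    stop("query length does not match the index read length");
  std::vector<int> hits = lookup_hits(idx, kmer);
  return wrap(hits);
}

// [[Rcpp::export(name = ".anchor_reads_cpp")]]
List anchor_reads_cpp(SEXP xp, CharacterVector reads, bool unique_only) {
  XPtr<ExactIndexData> idx(xp);
  NumericVector counts(idx->G);
  int n_anchored = 0, n_unanchored = 0, n_multi = 0;
  int n = reads.size();
  for (int r = 0; r < n; ++r) {
    std::string rd = as<std::string>(reads[r]);
    if ((int) rd.size() != idx->L)
      stop("read %d has length %d; index was built for %d-mers",
           r + 1, (int) rd.size(), idx->L);
    std::vector<int> hits = lookup_hits(idx, rd);
    size_t k = hits.size();
    if (k == 0) {
      ++n_unanchored;          // includes reads containing N: no exact match
    } else if (k == 1) {
      counts[hits[0]] += 1.0;
      ++n_anchored;
    } else {
      ++n_multi;
      if (!unique_only) {      // one increment at every matching locus
        for (size_t h = 0; h < k; ++h) counts[hits[h]] += 1.0;
        ++n_anchored;
      }
    }
  }
  return List::create(_["counts"] = counts,
                      _["n_anchored"] = n_anchored,
                      _["n_unanchored"] = n_unanchored,
                      _["n_multi"] = n_multi);
}
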