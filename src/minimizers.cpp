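#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

// Weighted minimizer selection. k-mers are 2-bit packed (k <= 31);
// canonical form is the lexicographic minimum of the k-mer and its reverse
// complement. Ordering is by (frequent?, splitmix64 hash, position):
// k-mers whose total occurrence count exceeds the weight threshold sort
// after all infrequent k-mers (Winnowmap-style down-weighting), so rare
// seeds win windows. The hash is the splitmix64 finalizer with the usual
// constants 0x9E3779B97F4A7C15 / 0xBF58476D1CE4E5B9 / 0x94D049BB133111EB.

namespace {

inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0; case 'C': case 'c': return 1;
  case 'G': case 'g': return 2; case 'T': case 't': return 3;
  default: return -1;
  }
}

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// all k-mer records of a sequence: canonical code, strand, validity
struct KmerScan {
  std::vector<uint64_t> canon;
  std::vector<uint8_t> strand;  // 1 if the sequence k-mer is the reverse
                                // complement of the canonical form
  std::vector<uint8_t> valid;
};

KmerScan scan_kmers(const std::string& s, int k) {
  KmerScan out;
  int n = (int)s.size();
  int m = n - k + 1;
  if (m <= 0) return out;
  out.canon.assign(m, 0); out.strand.assign(m, 0); out.valid.assign(m, 0);
  uint64_t fwd = 0, rev = 0;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;  // consecutive valid bases ending here
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    ++run;
    if (run >= k) {
      int pos = i - k + 1;
      if (fwd <= rev) { out.canon[pos] = fwd; out.strand[pos] = 0; }
      else { out.canon[pos] = rev; out.strand[pos] = 1; }
      out.valid[pos] = 1;
    }
  }
  return out;
}

std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  const char* abc = "ACGT";
  for (int i = k - 1; i >= 0; --i) { s[i] = abc[code & 3]; code >>= 2; }
  return s;
}

// windowed selection: every position attaining the window minimum is a
// minimizer occurrence (so runs of identical k-mers are all kept)
std::vector<int> select_minimizers(const KmerScan& ks, int w,
                                   const std::unordered_set<uint64_t>& frequent) {
  int m = (int)ks.canon.size();
  std::vector<int> sel;
  if (m <= 0) return sel;
  std::vector<std::pair<uint64_t, uint64_t>> key(m);
  for (int i = 0; i < m; ++i) {
    uint64_t freq = (ks.valid[i] && frequent.count(ks.canon[i])) ? 1 : 0;
    key[i] = {freq, ks.valid[i] ? splitmix64(ks.canon[i]) : ~0ULL};
  }
  std::vector<uint8_t> done(m, 0);
  int n_win = std::max(1, m - w + 1);
  for (int start = 0; start < n_win; ++start) {
    int end = std::min(start + w, m);
    int best = -1;
    for (int i = start; i < end; ++i) {
      if (!ks.valid[i]) continue;
      if (best < 0 || key[i] < key[best]) best = i;
    }
    if (best < 0) continue;
    for (int i = start; i < end; ++i)
      if (ks.valid[i] && key[i] == key[best] && !done[i]) {
        done[i] = 1; sel.push_back(i);
      }
  }
  return sel;
}

}  // namespace

// Build-side scan: counts all canonical k-mers across walks, derives the
// frequent set, then selects minimizers per walk.
// [[Rcpp::export(name = ".index_minimizers_cpp")]]
List index_minimizers_cpp(CharacterVector walk_seqs, int k, int w,
                          int weight_threshold) {
  std::vector<KmerScan> scans(walk_seqs.size());
  std::unordered_map<uint64_t, int> counts;
  for (int s = 0; s < walk_seqs.size(); ++s) {
    scans[s] = scan_kmers(as<std::string>(walk_seqs[s]), k);
    for (size_t i = 0; i < scans[s].canon.size(); ++i)
      if (scans[s].valid[i]) counts[scans[s].canon[i]]++;
  }
  std::unordered_set<uint64_t> frequent;
  for (auto& kv : counts)
    if (kv.second > weight_threshold) frequent.insert(kv.first);

  List per_walk(walk_seqs.size());
  for (int s = 0; s < walk_seqs.size(); ++s) {
    std::vector<int> sel = select_minimizers(scans[s], w, frequent);
    IntegerVector off(sel.size());
    IntegerVector strand(sel.size());
    CharacterVector kmer(sel.size());
    for (size_t i = 0; i < sel.size(); ++i) {
      off[i] = sel[i];
      strand[i] = scans[s].strand[sel[i]];
      kmer[i] = decode_kmer(scans[s].canon[sel[i]], k);
    }
    per_walk[s] = List::create(_["offset"] = off, _["strand"] = strand,
                               _["kmer"] = kmer);
  }
  CharacterVector freq_kmers(frequent.size());
  int i = 0;
  for (uint64_t c : frequent) freq_kmers[i++] = decode_kmer(c, k);
  return List::create(_["per_walk"] = per_walk, _["frequent"] = freq_kmers);
}

// Read-side scan with the same weighted order (frequent set from the index).
// [[Rcpp::export(name = ".read_minimizers_cpp")]]
List read_minimizers_cpp(std::string read, int k, int w,
                         CharacterVector frequent_kmers) {
  std::unordered_set<uint64_t> frequent;
  for (int i = 0; i < frequent_kmers.size(); ++i) {
    const std::string fk = as<std::string>(frequent_kmers[i]);
    KmerScan one = scan_kmers(fk, k);
    if (!one.valid.empty() && one.valid[0]) frequent.insert(one.canon[0]);
  }
  KmerScan ks = scan_kmers(read, k);
  std::vector<int> sel = select_minimizers(ks, w, frequent);
  IntegerVector off(sel.size());
  IntegerVector strand(sel.size());
  CharacterVector kmer(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) {
    off[i] = sel[i];
    strand[i] = ks.strand[sel[i]];
    kmer[i] = decode_kmer(ks.canon[sel[i]], k);
  }
  return List::create(_["offset"] = off, _["strand"] = strand, _["kmer"] = kmer);
}
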