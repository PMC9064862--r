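#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes; -1 for anything not ACGT (upper case expected)
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

// Apply sequencing errors: per-position Bernoulli substitutions first, then
// per-position insertions/deletions. Uses R's RNG so results are reproducible
// under set.seed().
// [[Rcpp::export]]
List cpp_mutate(std::string seq, double sub, double ins, double del) {
  const char bases[4] = {'A', 'C', 'G', 'T'};
  int n_sub = 0, n_ins = 0, n_del = 0;
  size_t n = seq.size();

  if (sub > 0) {
    for (size_t i = 0; i < n; ++i) {
      if (unif_rand() < sub) {
        char cur = seq[i];
        char nb = cur;
        while (nb == cur) nb = bases[(int)(unif_rand() * 4) & 3];
        seq[i] = nb;
        ++n_sub;
      }
    }
  }
  if (ins > 0 || del > 0) {
    std::string out;
    out.reserve(n + (size_t)(n * ins) + 16);
    for (size_t i = 0; i < n; ++i) {
      if (del > 0 && unif_rand() < del) { ++n_del; continue; }
      out.push_back(seq[i]);
      if (ins > 0 && unif_rand() < ins) {
        out.push_back(bases[(int)(unif_rand() * 4) & 3]);
        ++n_ins;
      }
    }
    seq.swap(out);
  }
  return List::create(_["seq"] = seq, _["n_sub"] = n_sub,
                      _["n_ins"] = n_ins, _["n_del"] = n_del);
}

struct Anchor { int q; int r; };  // 1-based start of k-mer in region (q) and read (r)

struct ChainHit {
  int region, read, strand;          // strand: 1 = plus, -1 = minus
  int n_anchors;
  double cov;                        // union of anchored region bases / region length
  int q_lo, q_hi, r_lo, r_hi;        // 1-based inclusive chain spans
  int chain_bases;
};

// Best colinear chain (minimap-style DP with a bounded predecessor window),
// then the union of anchored region bases along that chain.
static void chain_anchors(const std::vector<Anchor>& a, int k, int max_gap,
                          int& n_anchors, int& chain_bases,
                          std::vector<int>& chain_q,
                          int& q_lo, int& q_hi, int& r_lo, int& r_hi) {
  const int W = 50;
  int n = (int)a.size();
  std::vector<int> score(n), parent(n, -1);
  int best = 0;
  for (int i = 0; i < n; ++i) {
    score[i] = k;
    for (int j = i - 1; j >= 0 && j >= i - W; --j) {
      if (a[j].q >= a[i].q || a[j].r >= a[i].r) continue;
      if (a[i].q - (a[j].q + k) > max_gap) continue;
      if (a[i].r - (a[j].r + k) > max_gap) continue;
      int gain = std::min(k, std::min(a[i].q - a[j].q, a[i].r - a[j].r));
      if (score[j] + gain > score[i]) {
        score[i] = score[j] + gain;
        parent[i] = j;
      }
    }
    if (score[i] > score[best]) best = i;
  }
  // reconstruct
  std::vector<int> idx;
  for (int i = best; i >= 0; i = parent[i]) idx.push_back(i);
  n_anchors = (int)idx.size();
  q_lo = a[idx.back()].q; r_lo = a[idx.back()].r;
  q_hi = a[idx.front()].q + k - 1; r_hi = a[idx.front()].r + k - 1;
  // union of [q, q+k) over the chain (idx is reverse order, q decreasing)
  chain_bases = 0;
  chain_q.clear();
  int cur_lo = -1, cur_hi = -1;
  for (auto it = idx.rbegin(); it != idx.rend(); ++it) {
    int s = a[*it].q, e = a[*it].q + k - 1;
    if (cur_lo < 0) { cur_lo = s; cur_hi = e; }
    else if (s <= cur_hi + 1) { if (e > cur_hi) cur_hi = e; }
    else { chain_bases += cur_hi - cur_lo + 1; cur_lo = s; cur_hi = e; }
  }
  if (cur_lo >= 0) chain_bases += cur_hi - cur_lo + 1;
}

// Shared-k-mer anchoring of every read against every region, one pass per
// read (forward and reverse-complement), followed by per-(region,strand)
// chaining. Only chains with >= min_chain_bases anchored region bases are
// reported; everything else is an "absent" pair.
// [[Rcpp::export]]
DataFrame cpp_anchor_chains(CharacterVector regions, CharacterVector reads,
                            int k, int max_gap, int min_chain_bases) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // k-mer -> list of (region, pos) over all region forward strands
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  std::vector<int> region_len(regions.size());
  for (int r = 0; r < regions.size(); ++r) {
    std::string s = as<std::string>(regions[r]);
    region_len[r] = (int)s.size();
    uint64_t h = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[h].push_back({r, (int)(i - k + 2)}); // 1-based kmer start
    }
  }

  std::vector<ChainHit> hits;
  // per-(region,strand) anchor buffers, reused across reads
  int nr = (int)regions.size();
  std::vector<std::vector<Anchor>> buf(2 * nr);

  for (int rd = 0; rd < reads.size(); ++rd) {
    std::string s = as<std::string>(reads[rd]);
    for (auto& b : buf) b.clear();
    for (int strand = 0; strand < 2; ++strand) {
      std::string seq = s;
      if (strand == 1) {
        std::string rc(seq.rbegin(), seq.rend());
        for (auto& c : rc) c = comp_base(c);
        seq.swap(rc);
      }
      uint64_t h = 0; int run = 0;
      for (size_t i = 0; i < seq.size(); ++i) {
        int c = base_code(seq[i]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          auto it = index.find(h);
          if (it != index.end()) {
            int rpos = (int)(i - k + 2);
            for (auto& pr : it->second)
              buf[strand * nr + pr.first].push_back({pr.second, rpos});
          }
        }
      }
    }
    for (int r = 0; r < nr; ++r) {
      ChainHit best; best.chain_bases = -1;
      for (int strand = 0; strand < 2; ++strand) {
        auto& a = buf[strand * nr + r];
        if (a.empty()) continue;
        ChainHit h2; h2.region = r + 1; h2.read = rd + 1;
        h2.strand = strand == 0 ? 1 : -1;
        std::vector<int> cq;
        chain_anchors(a, k, max_gap, h2.n_anchors, h2.chain_bases, cq,
                      h2.q_lo, h2.q_hi, h2.r_lo, h2.r_hi);
        h2.cov = (double)h2.chain_bases / region_len[r];
        if (h2.chain_bases > best.chain_bases ||
            (h2.chain_bases == best.chain_bases && h2.strand == 1))
          best = h2;
      }
      if (best.chain_bases >= min_chain_bases) hits.push_back(best);
    }
    if (rd % 256 == 0) Rcpp::checkUserInterrupt();
  }

  int n = (int)hits.size();
  IntegerVector region(n), read(n), strand(n), n_anchors(n),
    q_lo(n), q_hi(n), r_lo(n), r_hi(n), chain_bases(n);
  NumericVector cov(n);
  for (int i = 0; i < n; ++i) {
    region[i] = hits[i].region; read[i] = hits[i].read;
    strand[i] = hits[i].strand; n_anchors[i] = hits[i].n_anchors;
    cov[i] = hits[i].cov; q_lo[i] = hits[i].q_lo; q_hi[i] = hits[i].q_hi;
    r_lo[i] = hits[i].r_lo; r_hi[i] = hits[i].r_hi;
    chain_bases[i] = hits[i].chain_bases;
  }
  return DataFrame::create(_["region"] = region, _["read"] = read,
                           _["strand"] = strand, _["n_anchors"] = n_anchors,
                           _["chain_cov"] = cov, _["q_lo"] = q_lo,
                           _["q_hi"] = q_hi, _["r_lo"] = r_lo,
                           _["r_hi"] = r_hi, _["chain_bases"] = chain_bases);
}

// Band-limited Smith-Waterman with traceback. The band is centred on the
// main diagonal and widened by the length difference, so a pre-positioned
// subject window keeps the optimum inside the band. Linear gap penalty.
// Returns the best local alignment's score, match count, column count and
// 1-based spans in pattern and subject.
// [[Rcpp::export]]
List cpp_banded_sw(std::string pattern, std::string subject, int band,
                   int match, int mismatch, int gap) {
  int m = (int)pattern.size(), n = (int)subject.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0, _["matches"] = 0, _["aln_len"] = 0,
                        _["p_start"] = 0, _["p_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);
  long w = (long)band + std::abs(n - m);
  if (w > n) w = n;
  long width = 2 * w + 1;
  // direction codes: 0 stop, 1 diag, 2 up (gap in subject), 3 left (gap in pattern)
  std::vector<uint8_t> dir((size_t)m * width, 0);
  std::vector<int> prev(width, 0), cur(width, 0);

  int best = 0, bi = 0, bo = 0;
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), 0);
    long olo = std::max(1L, i - w) - (i - w);   // offset of first valid j
    long ohi = std::min((long)n, i + w) - (i - w);
    for (long o = olo; o <= ohi; ++o) {
      long j = i - w + o;
      if (j < 1) continue;
      int sdiag = prev[o];                             // (i-1, j-1) -> prev row, same offset
      int sub = sdiag + (pattern[i - 1] == subject[j - 1] ? match : mismatch);
      int up = (o + 1 < width) ? prev[o + 1] - gap : INT32_MIN / 2;  // (i-1, j)
      int left = (o - 1 >= 0) ? cur[o - 1] - gap : INT32_MIN / 2;    // (i, j-1)
      int sc = 0; uint8_t d = 0;
      if (sub > sc) { sc = sub; d = 1; }
      if (up > sc) { sc = up; d = 2; }
      if (left > sc) { sc = left; d = 3; }
      cur[o] = sc;
      dir[(size_t)(i - 1) * width + o] = d;
      if (sc > best) { best = sc; bi = i; bo = (int)o; }
    }
    prev.swap(cur);
  }
  if (best == 0)
    return List::create(_["score"] = 0, _["matches"] = 0, _["aln_len"] = 0,
                        _["p_start"] = 0, _["p_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);
  // traceback
  int matches = 0, aln = 0;
  long i = bi, o = bo;
  long p_end = bi, s_end = bi - w + bo;
  long p_start = p_end, s_start = s_end;
  while (i >= 1) {
    uint8_t d = dir[(size_t)(i - 1) * width + o];
    if (d == 0) break;
    long j = i - w + o;
    if (d == 1) {
      ++aln;
      if (pattern[i - 1] == subject[j - 1]) ++matches;
      p_start = i; s_start = j;
      --i;            // o stays: (i-1, j-1) has same offset
    } else if (d == 2) {
      ++aln; p_start = i;
      --i; ++o;       // (i-1, j)
    } else {
      ++aln; s_start = j;
      --o;            // (i, j-1)
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["aln_len"] = aln, _["p_start"] = (int)p_start,
                      _["p_end"] = (int)p_end, _["s_start"] = (int)s_start,
                      _["s_end"] = (int)s_end);
}
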