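// Exact k-mer seeded read-to-CDS mapper with banded single-gap extension.
// Seeds are exact k-mers (default 25) over both strands of every CDS; each
// candidate (cds, strand, diagonal) is scored +1 match / -2 mismatch with at
// most one gap opening (-3 open, -1 per extension), and alignments below the
// identity threshold (matches / aligned read length) are discarded.  All CDS
// tied at the maximum score are returned, capped at max_ties; beyond the cap
// the read is discarded and tallied.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct SeedIndex {
  int k;
  std::vector<std::string> ids;
  std::vector<std::string> fwd;   // CDS sense strand
  std::vector<std::string> rev;   // reverse complement
  // key: 2-bit packed k-mer; value: packed (cds << 33) | (strand << 32) | pos
  std::unordered_map<uint64_t, std::vector<uint64_t>> seeds;
  size_t n_entries = 0;
};

static void index_strand(SeedIndex& idx, const std::string& s, uint64_t cds,
                         uint64_t strand) {
  const int k = idx.k;
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0;
  int run = 0;  // length of current valid-base run
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      int pos = i - k + 1;  // 0-based start on this strand's string
      idx.seeds[h].push_back((cds << 33) | (strand << 32) | (uint64_t)pos);
      ++idx.n_entries;
    }
  }
}

// [[Rcpp::export(name = ".build_index_cpp")]]
SEXP build_index_cpp(CharacterVector ids, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("word size k must be in 1..31");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  for (R_xlen_t i = 0; i < ids.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) {
      delete idx;
      stop("CDS '%s' shorter than word size %d", as<std::string>(ids[i]), k);
    }
    idx->ids.push_back(as<std::string>(ids[i]));
    idx->fwd.push_back(s);
    idx->rev.push_back(revcomp(s));
  }
  for (size_t c = 0; c < idx->fwd.size(); ++c) {
    index_strand(*idx, idx->fwd[c], c, 0);
    index_strand(*idx, idx->rev[c], c, 1);
  }
  XPtr<SeedIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export(name = ".index_stats_cpp")]]
List index_stats_cpp(SEXP xp_) {
  XPtr<SeedIndex> xp(xp_);
  return List::create(_["n_cds"] = (int)xp->ids.size(),
                      _["k"] = xp->k,
                      _["n_entries"] = (double)xp->n_entries);
}

// [[Rcpp::export(name = ".index_lookup_cpp")]]
DataFrame index_lookup_cpp(SEXP xp_, std::string kmer) {
  XPtr<SeedIndex> xp(xp_);
  if ((int)kmer.size() != xp->k) stop("query length must equal word size");
  uint64_t h = 0;
  for (char c : kmer) {
    int b = base2bits(c);
    if (b < 0) stop("query k-mer contains a non-ACGT base");
    h = (h << 2) | (uint64_t)b;
  }
  std::vector<std::string> cds;
  std::vector<std::string> strand;
  std::vector<int> pos;
  auto it = xp->seeds.find(h);
  if (it != xp->seeds.end()) {
    for (uint64_t e : it->second) {
      cds.push_back(xp->ids[e >> 33]);
      strand.push_back(((e >> 32) & 1) ? "-" : "+");
      pos.push_back((int)(e & 0xFFFFFFFFULL) + 1);  // 1-based
    }
  }
  return DataFrame::create(_["cds_id"] = cds, _["strand"] = strand,
                           _["pos"] = pos, _["stringsAsFactors"] = false);
}

struct MapParams {
  double min_identity;
  int max_gaps;      // 0 or 1 gap openings
  int max_gap_len;   // maximum gap extension length searched
  int max_ties;
  int match, mismatch, gap_open, gap_ext;
};

// prefix match counts of read vs target at diagonal d:
// P[i] = number of matching read positions in read[0..i) aligned to
// target[d..d+i); out-of-range target positions never match.
static void prefix_matches(const std::string& read, const std::string& tgt,
                           int d, std::vector<int>& P) {
  const int L = (int)read.size(), T = (int)tgt.size();
  P.assign(L + 1, 0);
  for (int i = 0; i < L; ++i) {
    int t = d + i;
    int m = (t >= 0 && t < T && read[i] == tgt[t] && base2bits(read[i]) >= 0)
      ? 1 : 0;
    P[i + 1] = P[i] + m;
  }
}

struct AlnResult {
  int score = INT32_MIN;
  double identity = 0.0;
};

// best scoring alignment of read against tgt anchored at diagonal d, allowing
// at most one gap (in read or in target) of length 1..max_gap_len; only
// configurations meeting the identity threshold are eligible.
static AlnResult align_at_diag(const std::string& read, const std::string& tgt,
                               int d, const MapParams& p,
                               std::unordered_map<int, std::vector<int>>& cache) {
  const int L = (int)read.size();
  AlnResult best;
  auto getP = [&](int e) -> const std::vector<int>& {
    auto it = cache.find(e);
    if (it != cache.end()) return it->second;
    auto& v = cache[e];
    prefix_matches(read, tgt, e, v);
    return v;
  };
  const std::vector<int>& Pd = getP(d);
  auto consider = [&](int matches, int aligned_len, int gap_cost) {
    if (aligned_len <= 0) return;
    double identity = (double)matches / (double)aligned_len;
    int score = p.match * matches
      - p.mismatch * (aligned_len - matches) - gap_cost;
    if (identity + 1e-12 < p.min_identity) return;
    if (score > best.score ||
        (score == best.score && identity > best.identity)) {
      best.score = score;
      best.identity = identity;
    }
  };
  consider(Pd[L], L, 0);
  if (p.max_gaps >= 1) {
    for (int g = 1; g <= p.max_gap_len; ++g) {
      int gap_cost = p.gap_open + (g - 1) * p.gap_ext;
      {  // gap in read: read bases i..i+g-1 unaligned, suffix on diagonal d-g
        const std::vector<int>& Ps = getP(d - g);
        int bestm = INT32_MIN;
        for (int i = 0; i + g <= L; ++i) {
          int m = Pd[i] + (Ps[L] - Ps[i + g]);
          if (m > bestm) bestm = m;
        }
        if (bestm > INT32_MIN) consider(bestm, L - g, gap_cost);
      }
      {  // gap in target: target skips g bases, suffix on diagonal d+g
        const std::vector<int>& Ps = getP(d + g);
        int bestm = INT32_MIN;
        for (int i = 0; i <= L; ++i) {
          int m = Pd[i] + (Ps[L] - Ps[i]);
          if (m > bestm) bestm = m;
        }
        if (bestm > INT32_MIN) consider(bestm, L, gap_cost);
      }
    }
  }
  return best;
}

// core mapping of one read; returns tied cds indices (deduplicated, sorted)
// or empty; sets tie_overflow when > max_ties CDS tie at the maximum score.
static std::vector<int> map_read_core(const SeedIndex& idx,
                                      const std::string& read,
                                      const MapParams& p,
                                      bool& tie_overflow) {
  tie_overflow = false;
  const int k = idx.k;
  const int L = (int)read.size();
  std::vector<int> out;
  if (L < k) return out;
  // candidate (cds, strand, diagonal) triples from exact k-mer hits
  std::unordered_set<uint64_t> cand;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t h = 0;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    int b = base2bits(read[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run < k) continue;
    auto it = idx.seeds.find(h);
    if (it == idx.seeds.end()) continue;
    int rp = i - k + 1;
    for (uint64_t e : it->second) {
      uint64_t cds = e >> 33;
      uint64_t strand = (e >> 32) & 1;
      int pos = (int)(e & 0xFFFFFFFFULL);
      int diag = pos - rp;
      // pack: (cds, strand, diag + 2^20) — diagonals here are small
      cand.insert((cds << 33) | (strand << 32) |
                  (uint64_t)(uint32_t)(diag + (1 << 20)));
    }
  }
  if (cand.empty()) return out;
  // best valid score per cds (over both strands and all candidate diagonals)
  std::unordered_map<int, AlnResult> per_cds;
  // per (cds, strand) prefix cache shared across that pair's diagonals
  std::vector<uint64_t> cands(cand.begin(), cand.end());
  std::sort(cands.begin(), cands.end());
  uint64_t cur_pair = ~0ULL;
  std::unordered_map<int, std::vector<int>> cache;
  for (uint64_t c : cands) {
    uint64_t pair = c >> 32;
    if (pair != cur_pair) { cache.clear(); cur_pair = pair; }
    int cds = (int)(c >> 33);
    int strand = (int)((c >> 32) & 1);
    int diag = (int)(uint32_t)(c & 0xFFFFFFFFULL) - (1 << 20);
    const std::string& tgt = strand ? idx.rev[cds] : idx.fwd[cds];
    AlnResult r = align_at_diag(read, tgt, diag, p, cache);
    if (r.score == INT32_MIN) continue;
    auto it = per_cds.find(cds);
    if (it == per_cds.end() || r.score > it->second.score) per_cds[cds] = r;
  }
  if (per_cds.empty()) return out;
  int best = INT32_MIN;
  for (auto& kv : per_cds) best = std::max(best, kv.second.score);
  for (auto& kv : per_cds) if (kv.second.score == best) out.push_back(kv.first);
  std::sort(out.begin(), out.end());
  if ((int)out.size() > p.max_ties) {
    tie_overflow = true;
    out.clear();
  }
  return out;
}

static MapParams params_from(double min_identity, int max_gaps,
                             int max_gap_len, int max_ties, int match,
                             int mismatch, int gap_open, int gap_ext) {
  MapParams p;
  p.min_identity = min_identity;
  p.max_gaps = max_gaps;
  p.max_gap_len = max_gap_len;
  p.max_ties = max_ties;
  p.match = match;
  p.mismatch = mismatch;
  p.gap_open = gap_open;
  p.gap_ext = gap_ext;
  return p;
}

// [[Rcpp::export(name = ".map_read_cpp")]]
List map_read_cpp(SEXP xp_, std::string read, double min_identity,
                  int max_gaps, int max_gap_len, int max_ties, int match,
                  int mismatch, int gap_open, int gap_ext) {
  XPtr<SeedIndex> xp(xp_);
  MapParams p = params_from(min_identity, max_gaps, max_gap_len, max_ties,
                            match, mismatch, gap_open, gap_ext);
  bool overflow = false;
  std::vector<int> hit = map_read_core(*xp, read, p, overflow);
  CharacterVector ids(hit.size());
  for (size_t i = 0; i < hit.size(); ++i) ids[i] = xp->ids[hit[i]];
  return List::create(_["cds_id"] = ids, _["tie_overflow"] = overflow);
}

// 5'/3' end-trim at quality < end_q; returns 0-based half-open [from, to)
static inline void trim_bounds(const char* q, int n, int end_q,
                               int& from, int& to) {
  from = 0;
  to = n;
  while (from < n && (q[from] - 33) < end_q) ++from;
  while (to > from && (q[to - 1] - 33) < end_q) --to;
}

// [[Rcpp::export(name = ".trim_bounds_cpp")]]
IntegerVector trim_bounds_cpp(std::string qual, int end_q) {
  int from, to;
  trim_bounds(qual.c_str(), (int)qual.size(), end_q, from, to);
  return IntegerVector::create(from + 1, to);  // 1-based inclusive bounds
}

// [[Rcpp::export(name = ".count_library_cpp")]]
List count_library_cpp(SEXP xp_, CharacterVector seqs, CharacterVector quals,
                       int end_q, int mean_q, int min_len, double min_identity,
                       int max_gaps, int max_gap_len, int max_ties, int match,
                       int mismatch, int gap_open, int gap_ext,
                       bool fractional) {
  XPtr<SeedIndex> xp(xp_);
  MapParams p = params_from(min_identity, max_gaps, max_gap_len, max_ties,
                            match, mismatch, gap_open, gap_ext);
  const int ncds = (int)xp->ids.size();
  std::vector<double> counts(ncds, 0.0);
  long long reads_in = seqs.size(), rejected = 0, unmapped = 0,
    distinct_mapped = 0, ties_discarded = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    const char* s = CHAR(STRING_ELT(seqs, i));
    int n = (int)LENGTH(STRING_ELT(quals, i));
    int from, to;
    trim_bounds(q, n, end_q, from, to);
    int len = to - from;
    if (len < min_len) { ++rejected; continue; }
    long sum = 0;
    for (int j = from; j < to; ++j) sum += q[j] - 33;
    if ((double)sum / len < (double)mean_q) { ++rejected; continue; }
    std::string read(s + from, s + to);
    bool overflow = false;
    std::vector<int> hit = map_read_core(*xp, read, p, overflow);
    if (hit.empty()) {
      ++unmapped;
      if (overflow) ++ties_discarded;
      continue;
    }
    ++distinct_mapped;
    double w = fractional ? 1.0 / (double)hit.size() : 1.0;
    for (int c : hit) counts[c] += w;
  }
  NumericVector cv(counts.begin(), counts.end());
  cv.attr("names") = CharacterVector(xp->ids.begin(), xp->ids.end());
  return List::create(_["counts"] = cv,
                      _["reads_in"] = (double)reads_in,
                      _["reads_rejected_qc"] = (double)rejected,
                      _["reads_unmapped"] = (double)unmapped,
                      _["distinct_mapped"] = (double)distinct_mapped,
                      _["ties_discarded"] = (double)ties_discarded);
}

// [[Rcpp::export(name = ".apply_substitutions_cpp")]]
CharacterVector apply_substitutions_cpp(CharacterVector seqs,
                                        IntegerVector read_idx,
                                        IntegerVector pos,
                                        CharacterVector base) {
  // read_idx and pos are 1-based; bases are single characters
  CharacterVector out = clone(seqs);
  for (R_xlen_t i = 0; i < read_idx.size(); ++i) {
    int r = read_idx[i] - 1;
    std::string s = as<std::string>(out[r]);
    s[pos[i] - 1] = CHAR(STRING_ELT(base, i))[0];
    out[r] = s;
  }
  return out;
}
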