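// Compiled kernels for crasskit: gapless profile-segment search,
// empirical null calibration, k-mer seeded genome comparison, spacer
// matching, k-mer LCA classification and read simulation.
//
// Conventions: sequence coordinates are 0-based half-open throughout;
// residue vectors index rows of a score matrix (last row is 'X'),
// -1 marks a residue that may not be crossed (a stop codon outside
// readthrough mode). All stochastic kernels take an explicit integer
// seed and use a private mt19937 so results are reproducible and do
// not disturb R's RNG stream.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <random>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Profile segment search
// ---------------------------------------------------------------------------

// One maximal high-scoring segment on a profile/sequence diagonal.
struct Segment {
  int start, end;    // residue positions, half-open
  int cstart, cend;  // profile columns, half-open
  double score;
};

// Kadane-style scan of one diagonal. Residues scoring matrix S is
// (n_alphabet x L), column-major access via S(res, col). Emits every
// maximal segment with score >= score_min.
static void scan_diagonal(const int* res, int n, const double* S, int nrow,
                          int L, int diag, double score_min,
                          std::vector<Segment>& out) {
  int col_lo = std::max(0, -diag);
  int col_hi = std::min(L, n - diag);
  if (col_hi <= col_lo) return;

  double cur = 0.0, best = 0.0;
  int seg_start = col_lo, best_end = col_lo;

  auto flush = [&](void) {
    if (best >= score_min && best_end > seg_start) {
      Segment s;
      s.cstart = seg_start; s.cend = best_end;
      s.start = seg_start + diag; s.end = best_end + diag;
      s.score = best;
      out.push_back(s);
    }
  };

  for (int col = col_lo; col < col_hi; ++col) {
    int r = res[col + diag];
    if (r < 0) {  // impassable residue: close out the running segment
      flush();
      cur = 0.0; best = 0.0; seg_start = col + 1; best_end = col + 1;
      continue;
    }
    cur += S[r + static_cast<size_t>(col) * nrow];
    if (cur <= 0.0) {
      flush();
      cur = 0.0; best = 0.0; seg_start = col + 1; best_end = col + 1;
    } else if (cur > best) {
      best = cur; best_end = col + 1;
    }
  }
  flush();
}

// [[Rcpp::export]]
DataFrame cpp_profile_scan(IntegerVector res, NumericMatrix S, double score_min) {
  const int n = res.size();
  const int L = S.ncol();
  std::vector<Segment> segs;
  for (int diag = -(L - 1); diag <= n - 1; ++diag)
    scan_diagonal(res.begin(), n, REAL(S), S.nrow(), L, diag, score_min, segs);
  const int m = segs.size();
  IntegerVector start(m), end(m), cstart(m), cend(m);
  NumericVector score(m);
  for (int i = 0; i < m; ++i) {
    start[i] = segs[i].start; end[i] = segs[i].end;
    cstart[i] = segs[i].cstart; cend[i] = segs[i].cend;
    score[i] = segs[i].score;
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["cstart"] = cstart, _["cend"] = cend,
                           _["score"] = score);
}

// Maximum segment score over all diagonals (helper for null calibration).
static double max_segment_score(const int* res, int n, const double* S,
                                int nrow, int L) {
  double global_best = 0.0;
  for (int diag = -(L - 1); diag <= n - 1; ++diag) {
    int col_lo = std::max(0, -diag);
    int col_hi = std::min(L, n - diag);
    double cur = 0.0;
    const int* rp = res + diag + col_lo;
    const double* Sp = S + static_cast<size_t>(col_lo) * nrow;
    // pool residues are all valid (>= 0), so the loop is branch-light
    for (int col = col_lo; col < col_hi; ++col, Sp += nrow) {
      cur = std::max(0.0, cur + Sp[*rp++]);
      global_best = std::max(global_best, cur);
    }
  }
  return global_best;
}

// Null distribution of the maximum segment score: each replicate is a
// random subsample (without replacement) of m residues from the pool,
// scanned against the profile. Pool should contain valid residues only.
// [[Rcpp::export]]
NumericVector cpp_null_max_scores(IntegerVector pool, NumericMatrix S,
                                  int n_null, int m, int seed) {
  const int n = pool.size();
  if (m > n) m = n;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<int> work(pool.begin(), pool.end());
  NumericVector out(n_null);
  for (int it = 0; it < n_null; ++it) {
    // partial Fisher-Yates: first m entries are a uniform random subset order
    for (int i = 0; i < m; ++i) {
      std::uniform_int_distribution<int> pick(i, n - 1);
      int j = pick(rng);
      std::swap(work[i], work[j]);
    }
    out[it] = max_segment_score(work.data(), m, REAL(S), S.nrow(), S.ncol());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Pairwise genome comparison: exact k-mer seeds on diagonals, run merging,
// ungapped X-drop extension, per-block identity.
// ---------------------------------------------------------------------------

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// [[Rcpp::export]]
DataFrame cpp_pairwise_blocks(std::string q, std::string s, int k,
                              int min_block_len, int max_gap) {
  const int nq = q.size(), ns = s.size();
  DataFrame empty = DataFrame::create(
      _["qstart"] = IntegerVector(0), _["qend"] = IntegerVector(0),
      _["sstart"] = IntegerVector(0), _["identity"] = NumericVector(0),
      _["score"] = IntegerVector(0), _["length"] = IntegerVector(0));
  if (nq < k || ns < k) return empty;

  // hash query k-mers
  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve(nq * 2);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < nq; ++i) {
    int b = base2bit(q[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | b) & mask;
    if (++run >= k) idx[h].push_back(i - k + 1);
  }

  // collect seed matches per diagonal (diag = spos - qpos)
  std::unordered_map<int, std::vector<int> > diag_hits;  // diag -> qpos list
  h = 0; run = 0;
  for (int i = 0; i < ns; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | b) & mask;
    if (++run >= k) {
      auto it = idx.find(h);
      if (it != idx.end()) {
        int spos = i - k + 1;
        for (int qpos : it->second) diag_hits[spos - qpos].push_back(qpos);
      }
    }
  }

  std::vector<int> qstart, qend, sstart, score, length;
  std::vector<double> identity;

  for (auto& kv : diag_hits) {
    int diag = kv.first;
    std::vector<int>& pos = kv.second;
    std::sort(pos.begin(), pos.end());
    size_t i0 = 0;
    while (i0 < pos.size()) {
      size_t i1 = i0;
      while (i1 + 1 < pos.size() && pos[i1 + 1] - pos[i1] <= max_gap) ++i1;
      int qlo = pos[i0], qhi = pos[i1] + k;  // half-open on query

      // ungapped X-drop extension (match +1, mismatch -3, drop 12)
      const int XDROP = 12;
      int cur = 0, best = 0, best_ext = 0;
      for (int e = 1; qlo - e >= 0 && qlo - e + diag >= 0; ++e) {
        cur += (q[qlo - e] == s[qlo - e + diag]) ? 1 : -3;
        if (cur > best) { best = cur; best_ext = e; }
        if (cur < best - XDROP) break;
      }
      qlo -= best_ext;
      cur = 0; best = 0; best_ext = 0;
      for (int e = 0; qhi + e < nq && qhi + e + diag < ns; ++e) {
        cur += (q[qhi + e] == s[qhi + e + diag]) ? 1 : -3;
        if (cur > best) { best = cur; best_ext = e + 1; }
        if (cur < best - XDROP) break;
      }
      qhi += best_ext;

      int len = qhi - qlo, match = 0;
      for (int p = qlo; p < qhi; ++p)
        if (q[p] == s[p + diag]) ++match;
      if (len >= min_block_len) {
        qstart.push_back(qlo); qend.push_back(qhi);
        sstart.push_back(qlo + diag);
        identity.push_back(100.0 * match / len);
        score.push_back(2 * match - len);  // match - mismatch
        length.push_back(len);
      }
      i0 = i1 + 1;
    }
  }
  return DataFrame::create(_["qstart"] = wrap(qstart), _["qend"] = wrap(qend),
                           _["sstart"] = wrap(sstart),
                           _["identity"] = wrap(identity),
                           _["score"] = wrap(score),
                           _["length"] = wrap(length));
}

// ---------------------------------------------------------------------------
// CRISPR spacer matching: exact seed k-mers anchor full-length ungapped
// placements; the best placement (most matched positions) is returned.
// ---------------------------------------------------------------------------

static void spacer_scan_strand(const std::string& sp, const std::string& g,
                               int seed_len, int& best_matches, int& best_pos) {
  const int L = sp.size(), n = g.size();
  if (n < L) return;
  std::unordered_map<uint64_t, std::vector<int> > seeds;
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < L; ++i) {
    int b = base2bit(sp[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | b) & mask;
    if (++run >= seed_len) seeds[h].push_back(i - seed_len + 1);
  }
  std::unordered_map<int, bool> tried;
  h = 0; run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(g[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | b) & mask;
    if (++run >= seed_len) {
      auto it = seeds.find(h);
      if (it == seeds.end()) continue;
      int gpos = i - seed_len + 1;
      for (int off : it->second) {
        int start = gpos - off;
        if (start < 0 || start + L > n) continue;
        if (tried.count(start)) continue;
        tried[start] = true;
        int match = 0;
        for (int p = 0; p < L; ++p)
          if (sp[p] == g[start + p]) ++match;
        if (match > best_matches || (match == best_matches && (best_pos < 0 || start < best_pos))) {
          best_matches = match; best_pos = start;
        }
      }
    }
  }
}

static std::string revcomp_str(const std::string& x) {
  std::string r(x.rbegin(), x.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
List cpp_spacer_best_match(std::string spacer, std::string genome, int seed_len) {
  int bm_f = -1, bp_f = -1, bm_r = -1, bp_r = -1;
  spacer_scan_strand(spacer, genome, seed_len, bm_f, bp_f);
  std::string rc = revcomp_str(spacer);
  spacer_scan_strand(rc, genome, seed_len, bm_r, bp_r);
  if (bm_f < 0 && bm_r < 0)
    return List::create(_["matches"] = NA_INTEGER, _["start"] = NA_INTEGER,
                        _["strand"] = NA_STRING);
  if (bm_f >= bm_r)
    return List::create(_["matches"] = bm_f, _["start"] = bp_f,
                        _["strand"] = "+");
  return List::create(_["matches"] = bm_r, _["start"] = bp_r,
                      _["strand"] = "-");
}

// ---------------------------------------------------------------------------
// k-mer LCA index and read classification
// ---------------------------------------------------------------------------

struct KmerIndex {
  std::unordered_map<uint64_t, int> map;  // canonical k-mer -> node id (1-based)
  int k;
};

static inline uint64_t revcomp_kmer(uint64_t h, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (h & 3));
    h >>= 2;
  }
  return r;
}

// LCA of two 1-based nodes given parent array (parent[root-1] == 0).
static int lca_nodes(int a, int b, const std::vector<int>& parent,
                     const std::vector<int>& depth) {
  while (a != b) {
    if (depth[a - 1] >= depth[b - 1]) a = parent[a - 1];
    else b = parent[b - 1];
  }
  return a;
}

static std::vector<int> node_depths(const std::vector<int>& parent) {
  const int n = parent.size();
  std::vector<int> depth(n, -1);
  for (int i = 0; i < n; ++i) {
    if (depth[i] >= 0) continue;
    // walk up, then fill
    std::vector<int> chain;
    int v = i + 1;
    while (v != 0 && depth[v - 1] < 0) { chain.push_back(v); v = parent[v - 1]; }
    int d = (v == 0) ? -1 : depth[v - 1];
    for (auto it = chain.rbegin(); it != chain.rend(); ++it)
      depth[*it - 1] = ++d;
  }
  return depth;
}

// [[Rcpp::export]]
SEXP cpp_build_kmer_index(CharacterVector seqs, IntegerVector leaf_nodes,
                          IntegerVector parents, int k) {
  std::vector<int> parent(parents.begin(), parents.end());
  std::vector<int> depth = node_depths(parent);
  KmerIndex* ki = new KmerIndex();
  ki->k = k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int gi = 0; gi < seqs.size(); ++gi) {
    std::string s = as<std::string>(seqs[gi]);
    int node = leaf_nodes[gi];
    uint64_t h = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | b) & mask;
      if (++run >= k) {
        uint64_t rc = revcomp_kmer(h, k);
        uint64_t canon = (h < rc) ? h : rc;
        auto it = ki->map.find(canon);
        if (it == ki->map.end()) ki->map[canon] = node;
        else if (it->second != node)
          it->second = lca_nodes(it->second, node, parent, depth);
      }
    }
  }
  XPtr<KmerIndex> xp(ki, true);
  return xp;
}

// [[Rcpp::export]]
int cpp_index_size(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  return static_cast<int>(xp->map.size());
}

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP xp_, CharacterVector kmers) {
  XPtr<KmerIndex> xp(xp_);
  const int k = xp->k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  IntegerVector out(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t h = 0; bool ok = (static_cast<int>(s.size()) == k);
    if (ok) for (char c : s) { int b = base2bit(c); if (b < 0) { ok = false; break; } h = ((h << 2) | b) & mask; }
    if (!ok) { out[i] = NA_INTEGER; continue; }
    uint64_t rc = revcomp_kmer(h, k);
    uint64_t canon = (h < rc) ? h : rc;
    auto it = xp->map.find(canon);
    out[i] = (it == xp->map.end()) ? 0 : it->second;
  }
  return out;
}

// Classify reads: votes from database k-mers score every root-to-leaf
// path; the read is assigned to the leaf of the unique max-weight path, or,
// when several paths tie, to the last common ancestor of the tied leaves
// (the shallower, conservative node). 0 = unclassified.
// [[Rcpp::export]]
IntegerVector cpp_classify_reads(SEXP xp_, CharacterVector reads,
                                 IntegerVector parents) {
  XPtr<KmerIndex> xp(xp_);
  const int k = xp->k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<int> parent(parents.begin(), parents.end());
  std::vector<int> depth = node_depths(parent);
  const int n_nodes = parent.size();
  std::vector<bool> has_child(n_nodes, false);
  for (int p : parent) if (p != 0) has_child[p - 1] = true;
  std::vector<int> leaves;
  for (int v = 1; v <= n_nodes; ++v)
    if (!has_child[v - 1]) leaves.push_back(v);

  IntegerVector out(reads.size());
  std::unordered_map<int, int> votes;
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string s = as<std::string>(reads[ri]);
    votes.clear();
    uint64_t h = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | b) & mask;
      if (++run >= k) {
        uint64_t rc = revcomp_kmer(h, k);
        uint64_t canon = (h < rc) ? h : rc;
        auto it = xp->map.find(canon);
        if (it != xp->map.end()) ++votes[it->second];
      }
    }
    if (votes.empty()) { out[ri] = 0; continue; }
    int best_w = 0, assign = 0;
    for (int leaf : leaves) {
      int w = 0, v = leaf;
      while (v != 0) {
        auto f = votes.find(v);
        if (f != votes.end()) w += f->second;
        v = parent[v - 1];
      }
      if (w == 0) continue;
      if (w > best_w) { best_w = w; assign = leaf; }
      else if (w == best_w && assign != 0)
        assign = lca_nodes(assign, leaf, parent, depth);
    }
    out[ri] = assign;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Read simulation: substring extraction from (pre-doubled) genomes plus
// per-base substitution errors.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_sample_reads(CharacterVector genomes, IntegerVector origin,
                                 IntegerVector start, int read_len,
                                 double error_rate, int seed) {
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> pick3(0, 2);
  static const char* BASES = "ACGT";
  const int n = origin.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string g = as<std::string>(genomes[origin[i] - 1]);
    std::string r = g.substr(start[i], read_len);
    if (error_rate > 0.0) {
      for (int p = 0; p < read_len; ++p) {
        if (unif(rng) < error_rate) {
          int b = base2bit(r[p]);
          if (b < 0) continue;
          int nb = pick3(rng);
          if (nb >= b) ++nb;
          r[p] = BASES[nb];
        }
      }
    }
    out[i] = r;
  }
  return out;
}
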