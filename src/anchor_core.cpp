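// Seed-and-chain anchoring core.
//
// Exact k-mer seeds on both strands, collinear banded DP chaining with a
// maximum join distance, identity estimated as matched-seed span over
// chained span. Deterministic; the only heuristics are the per-k-mer
// occurrence cap (drops seeds from high-copy repeats) and the predecessor
// band of the chaining DP.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <string>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_char(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_char(s[i]);
  return out;
}

// collect valid k-mers (2-bit rolling encoding); windows with non-ACGT skipped
static void collect_kmers(const std::string& s, int k,
                          std::vector<uint64_t>& vals, std::vector<int>& poss) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t val = 0;
  int run = 0;
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint64_t)c) & mask;
    if (++run >= k) { vals.push_back(val); poss.push_back(i - k + 1); }
  }
}

typedef std::unordered_map<uint64_t, std::vector<int>> KmerIndex;

static KmerIndex build_index(const std::string& target, int k) {
  std::vector<uint64_t> vals;
  std::vector<int> poss;
  vals.reserve(target.size());
  poss.reserve(target.size());
  collect_kmers(target, k, vals, poss);
  KmerIndex idx;
  idx.reserve(vals.size() * 2);
  for (size_t i = 0; i < vals.size(); ++i) idx[vals[i]].push_back(poss[i]);
  return idx;
}

struct Seed { int q, t; };

// banded DP chaining: maximize the number of collinear seeds subject to a
// maximum join distance on both query and target (so chains never jump
// between distant loci, which would hide duplications). Predecessors are
// searched among the previous `band` seeds, the usual desk-scale shortcut.
static std::vector<int> dp_chain(const std::vector<Seed>& seeds, int max_join,
                                 int band) {
  const int n = (int)seeds.size();
  std::vector<int> chain;
  if (n == 0) return chain;
  std::vector<int> dp(n, 1), parent(n, -1);
  int best = 0;
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - band);
    for (int j = i - 1; j >= lo; --j) {
      if (seeds[j].q >= seeds[i].q || seeds[j].t >= seeds[i].t) continue;
      if (seeds[i].q - seeds[j].q > max_join) break;  // q-sorted: older only larger
      if (seeds[i].t - seeds[j].t > max_join) continue;
      if (dp[j] + 1 > dp[i]) { dp[i] = dp[j] + 1; parent[i] = j; }
    }
    if (dp[i] > dp[best]) best = i;
  }
  for (int i = best; i >= 0; i = parent[i]) chain.push_back(i);
  std::reverse(chain.begin(), chain.end());
  return chain;
}

// union length of [p, p+k) intervals over an ascending position vector
static long cover_len(const std::vector<int>& pos, int k) {
  long covered = 0;
  int cur_start = -1, cur_end = -1;
  for (int p : pos) {
    if (cur_start < 0) { cur_start = p; cur_end = p + k; continue; }
    if (p <= cur_end) { if (p + k > cur_end) cur_end = p + k; }
    else { covered += cur_end - cur_start; cur_start = p; cur_end = p + k; }
  }
  if (cur_start >= 0) covered += cur_end - cur_start;
  return covered;
}

struct ChainStats {
  int qstart, qend, tstart, tend, n_seeds;
  double identity, coverage;
};

static bool chain_stats(const std::vector<Seed>& seeds,
                        const std::vector<int>& chain, int k, int q_valid,
                        ChainStats& out) {
  if (chain.empty()) return false;
  std::vector<int> qpos, tpos;
  qpos.reserve(chain.size());
  tpos.reserve(chain.size());
  for (int i : chain) { qpos.push_back(seeds[i].q); tpos.push_back(seeds[i].t); }
  std::sort(qpos.begin(), qpos.end());
  std::sort(tpos.begin(), tpos.end());
  long qcov = cover_len(qpos, k);
  long tcov = cover_len(tpos, k);
  long tspan = (long)tpos.back() + k - tpos.front();
  out.qstart = qpos.front();
  out.qend = qpos.back() + k - 1;
  out.tstart = tpos.front();
  out.tend = tpos.back() + k - 1;
  out.n_seeds = (int)chain.size();
  out.identity = tspan > 0 ? (double)tcov / (double)tspan : 0.0;
  out.coverage = q_valid > 0 ? (double)qcov / (double)q_valid : 0.0;
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_anchor_hits(CharacterVector queries, std::string target, int k,
                          int max_occ, int max_chains, int max_join,
                          int band) {
  if (k < 2 || k > 32) stop("k must be between 2 and 32");
  KmerIndex idx = build_index(target, k);

  std::vector<int> o_query, o_tstart, o_tend, o_qstart, o_qend, o_nseeds, o_rank;
  std::vector<std::string> o_strand;
  std::vector<double> o_identity, o_coverage;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    const int qlen = (int)q.size();
    if (qlen < k) stop("query %d is shorter than k = %d", qi + 1, k);
    int q_valid = 0;
    for (char c : q) if (base_code(c) >= 0) ++q_valid;

    for (int si = 0; si < 2; ++si) {
      const bool fwd = (si == 0);
      std::string qs = fwd ? q : revcomp(q);
      std::vector<uint64_t> vals;
      std::vector<int> poss;
      collect_kmers(qs, k, vals, poss);

      std::vector<Seed> seeds;
      for (size_t i = 0; i < vals.size(); ++i) {
        KmerIndex::const_iterator it = idx.find(vals[i]);
        if (it == idx.end()) continue;
        const std::vector<int>& tp = it->second;
        if ((int)tp.size() > max_occ) continue;
        // q ascending from collect_kmers; t ascending within each q
        for (size_t j = 0; j < tp.size(); ++j)
          seeds.push_back({poss[i], tp[j]});
      }

      std::vector<char> alive(seeds.size(), 1);
      for (int rank = 1; rank <= max_chains; ++rank) {
        std::vector<Seed> sub;
        std::vector<int> sub_map;
        for (size_t i = 0; i < seeds.size(); ++i)
          if (alive[i]) { sub.push_back(seeds[i]); sub_map.push_back((int)i); }
        if (sub.empty()) break;
        std::vector<int> chain = dp_chain(sub, max_join, band);
        ChainStats st;
        if (!chain_stats(sub, chain, k, q_valid, st)) break;

        int qstart = st.qstart, qend = st.qend;
        if (!fwd) {  // report query interval on the original orientation
          int s2 = qlen - 1 - qend, e2 = qlen - 1 - qstart;
          qstart = s2; qend = e2;
        }
        o_query.push_back(qi + 1);
        o_strand.push_back(fwd ? "+" : "-");
        o_tstart.push_back(st.tstart + 1);
        o_tend.push_back(st.tend + 1);
        o_qstart.push_back(qstart + 1);
        o_qend.push_back(qend + 1);
        o_nseeds.push_back(st.n_seeds);
        o_identity.push_back(st.identity);
        o_coverage.push_back(st.coverage);
        o_rank.push_back(rank);

        // mask the chained target span before searching for a further chain
        for (size_t i = 0; i < seeds.size(); ++i)
          if (alive[i] && seeds[i].t >= st.tstart && seeds[i].t <= st.tend)
            alive[i] = 0;
      }
    }
  }

  return DataFrame::create(
      _["query"] = o_query, _["strand"] = o_strand,
      _["tstart"] = o_tstart, _["tend"] = o_tend,
      _["qstart"] = o_qstart, _["qend"] = o_qend,
      _["n_seeds"] = o_nseeds, _["identity"] = o_identity,
      _["coverage"] = o_coverage, _["rank"] = o_rank,
      _["stringsAsFactors"] = false);
}

// Exact ungapped sliding scan: best placement of query on target by Hamming
// distance. Non-ACGT positions (on either side) count as mismatches. Returns
// the best and the best well-separated runner-up placement.
// [[Rcpp::export]]
List cpp_hamming_scan(std::string query, std::string target, int min_sep) {
  const int m = (int)query.size(), n = (int)target.size();
  if (m == 0 || n < m)
    return List::create(_["offset"] = NA_INTEGER, _["mismatches"] = NA_INTEGER,
                        _["identity"] = NA_REAL,
                        _["second_offset"] = NA_INTEGER,
                        _["second_identity"] = NA_REAL);
  std::vector<int> mism(n - m + 1, 0);
  for (int o = 0; o <= n - m; ++o) {
    int d = 0;
    for (int i = 0; i < m; ++i) {
      char a = query[i], b = target[o + i];
      int ca = base_code(a), cb = base_code(b);
      if (ca < 0 || cb < 0 || ca != cb) ++d;
    }
    mism[o] = d;
  }
  int best = 0;
  for (int o = 1; o <= n - m; ++o) if (mism[o] < mism[best]) best = o;
  int second = -1;
  for (int o = 0; o <= n - m; ++o) {
    if (std::abs(o - best) <= min_sep) continue;
    if (second < 0 || mism[o] < mism[second]) second = o;
  }
  return List::create(
      _["offset"] = best + 1, _["mismatches"] = mism[best],
      _["identity"] = 1.0 - (double)mism[best] / (double)m,
      _["second_offset"] = second < 0 ? NA_INTEGER : second + 1,
      _["second_identity"] =
          second < 0 ? NA_REAL : 1.0 - (double)mism[second] / (double)m);
}
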