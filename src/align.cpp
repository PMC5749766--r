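// Needleman-Wunsch machinery shared by pairwise identity, greedy clustering
// and progressive profile alignment.
//
// Scoring contract (fixed package-wide): BLOSUM62, affine gaps in the BLAST
// convention — a gap of length L costs open + ext*L (the first gap residue
// pays open + ext).  To make identity/coverage path-independent, the DP
// optimises the triple (score, #identical pairs, #aligned residue pairs)
// lexicographically; the reported counts are therefore uniquely defined and
// comparable bit-exactly against an independent oracle.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_set>
#include <cstdint>
#include <cmath>
#include <limits>
#include <algorithm>
using namespace Rcpp;

namespace {

// The DP value (score, #identical, #aligned) is packed into one int64 so
// lexicographic maximisation becomes plain integer max: score in the high
// bits (arithmetic shift handles negatives), then identical count, then
// aligned count, each in a 21-bit field that can never borrow (both counts
// are nonnegative and bounded by sequence length << 2^21).
typedef int64_t pk;
const pk NEGP = std::numeric_limits<int64_t>::min() / 4;

inline pk pk_make(int64_t s, int64_t id, int64_t al) {
  return (s << 42) + (id << 21) + al;
}
inline int64_t pk_score(pk v) { return v >> 42; }
inline int64_t pk_id(pk v) { return (v >> 21) & ((1 << 21) - 1); }
inline int64_t pk_al(pk v) { return v & ((1 << 21) - 1); }
inline pk pk_max3(pk a, pk b, pk c) {
  return std::max(a, std::max(b, c));
}

// map characters to row indices of the scoring matrix
std::vector<int> encode(const std::string& seq, const std::string& alphabet,
                        const char* what) {
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)alphabet[i]] = (int)i;
  std::vector<int> out(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    int v = lut[(unsigned char)seq[i]];
    if (v < 0)
      stop("%s: residue '%c' not in alphabet '%s'", what, seq[i],
           alphabet.c_str());
    out[i] = v;
  }
  return out;
}

struct NWResult {
  double score;
  int nid;
  int nal;
};

// integer scoring matrix in flat row-major layout for speed
struct IntMatrix {
  std::vector<int64_t> v;
  int n;
  explicit IntMatrix(const NumericMatrix& sm) : v(sm.nrow() * sm.ncol()),
                                                n(sm.ncol()) {
    for (int i = 0; i < sm.nrow(); ++i)
      for (int j = 0; j < sm.ncol(); ++j)
        v[i * n + j] = (int64_t)std::llround(sm(i, j));
  }
  int64_t at(int i, int j) const { return v[i * n + j]; }
};

// global affine-gap NW over encoded sequences; rolling rows, no traceback
NWResult nw_core(const std::vector<int>& a, const std::vector<int>& b,
                 const IntMatrix& sm, int64_t open, int64_t ext) {
  const int n = (int)a.size(), m = (int)b.size();
  const pk go = pk_make(open + ext, 0, 0);  // gap opening (BLAST: open+ext)
  const pk ge = pk_make(ext, 0, 0);
  std::vector<pk> M0(m + 1), E0(m + 1), F0(m + 1);
  std::vector<pk> M1(m + 1), E1(m + 1), F1(m + 1);

  M0[0] = 0;
  E0[0] = NEGP;
  F0[0] = NEGP;
  for (int j = 1; j <= m; ++j) {
    M0[j] = NEGP;
    E0[j] = NEGP;
    F0[j] = pk_make(-(open + ext * j), 0, 0);  // leading gap in a
  }
  for (int i = 1; i <= n; ++i) {
    M1[0] = NEGP;
    F1[0] = NEGP;
    E1[0] = pk_make(-(open + ext * i), 0, 0);  // leading gap in b
    const int ai = a[i - 1];
    const int64_t* srow = &sm.v[ai * sm.n];
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1];
      const pk step = pk_make(srow[bj], ai == bj ? 1 : 0, 1);
      pk d = pk_max3(M0[j - 1], E0[j - 1], F0[j - 1]);
      M1[j] = (d <= NEGP / 2) ? NEGP : d + step;
      // E: a_i against a gap (gap in b)
      E1[j] = pk_max3(M0[j] - go, E0[j] - ge, F0[j] - go);
      // F: b_j against a gap (gap in a)
      F1[j] = pk_max3(M1[j - 1] - go, F1[j - 1] - ge, E1[j - 1] - go);
    }
    std::swap(M0, M1);
    std::swap(E0, E1);
    std::swap(F0, F1);
  }
  pk best = pk_max3(M0[m], E0[m], F0[m]);
  return {(double)pk_score(best), (int)pk_id(best), (int)pk_al(best)};
}

// rolling-hash k-mer codes (alphabet <= 32 => 5 bits per residue, k <= 12)
void kmer_codes(const std::vector<int>& s, int k,
                std::unordered_set<uint64_t>& out) {
  if ((int)s.size() < k) return;
  uint64_t code = 0;
  const uint64_t mask = (k * 5 >= 64) ? ~0ULL : ((1ULL << (k * 5)) - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    code = ((code << 5) | (uint64_t)s[i]) & mask;
    if ((int)i >= k - 1) out.insert(code);
  }
}

// lower bound on shared k-mer positions implied by identity >= c over the
// shorter sequence: t identical columns split into runs by at most
// (n + m - 2t + 1) breaks, each run of length r contributes r - k + 1
// intact shared k-mers
long kmer_lower_bound(int n_long, int m_short, int k, double c) {
  long t = (long)std::ceil(c * m_short - 1e-9);
  return t - (long)(k - 1) * (long)(n_long + m_short - 2 * t + 1);
}

bool prefilter_core(const std::vector<int>& a, const std::vector<int>& b,
                    int k, double c) {
  const std::vector<int>& s = (a.size() <= b.size()) ? a : b;
  const std::vector<int>& l = (a.size() <= b.size()) ? b : a;
  const int m = (int)s.size(), n = (int)l.size();
  if (m < k) return true;
  long bound = kmer_lower_bound(n, m, k, c);
  if (bound <= 0) return true;  // bound vacuous: must not exclude
  std::unordered_set<uint64_t> lk;
  kmer_codes(l, k, lk);
  long count = 0;
  uint64_t code = 0;
  const uint64_t mask = (k * 5 >= 64) ? ~0ULL : ((1ULL << (k * 5)) - 1);
  for (int i = 0; i < m; ++i) {
    code = ((code << 5) | (uint64_t)s[i]) & mask;
    if (i >= k - 1 && lk.count(code)) ++count;
  }
  return count >= bound;
}

}  // namespace

// [[Rcpp::export(name = ".nw_stats_cpp")]]
NumericVector nw_stats_cpp(std::string a, std::string b, NumericMatrix sm,
                           std::string alphabet, double open, double ext) {
  if (a.empty() || b.empty()) stop("empty sequence");
  std::vector<int> ea = encode(a, alphabet, "seq_a");
  std::vector<int> eb = encode(b, alphabet, "seq_b");
  IntMatrix ism(sm);
  NWResult r = nw_core(ea, eb, ism, (int64_t)std::llround(open),
                       (int64_t)std::llround(ext));
  const double shorter = (double)std::min(a.size(), b.size());
  return NumericVector::create(_["identity"] = r.nid / shorter,
                               _["coverage"] = r.nal / shorter,
                               _["score"] = r.score,
                               _["n_identical"] = (double)r.nid,
                               _["n_aligned"] = (double)r.nal);
}

// [[Rcpp::export(name = ".kmer_prefilter_cpp")]]
bool kmer_prefilter_cpp(std::string a, std::string b, std::string alphabet,
                        int k, double c) {
  std::vector<int> ea = encode(a, alphabet, "seq_a");
  std::vector<int> eb = encode(b, alphabet, "seq_b");
  return prefilter_core(ea, eb, k, c);
}

// Greedy incremental clustering over sequences pre-sorted by decreasing
// length (ties broken upstream).  Returns 1-based cluster ids plus the
// identity/coverage of each member to its representative.
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
List greedy_cluster_cpp(CharacterVector seqs, NumericMatrix sm,
                        std::string alphabet, double open, double ext,
                        double c, double a, int k) {
  const int n = seqs.size();
  std::vector<std::vector<int> > enc(n);
  for (int i = 0; i < n; ++i)
    enc[i] = encode(as<std::string>(seqs[i]), alphabet, "record");
  IntMatrix ism(sm);
  const int64_t iopen = (int64_t)std::llround(open);
  const int64_t iext = (int64_t)std::llround(ext);

  IntegerVector assign(n);
  NumericVector identity(n), coverage(n);
  std::vector<int> reps;  // record index of each cluster representative

  for (int i = 0; i < n; ++i) {
    int best = -1;
    double best_id = -1.0, best_cov = 0.0;
    for (size_t r = 0; r < reps.size(); ++r) {
      const std::vector<int>& rep = enc[reps[r]];
      if (!prefilter_core(rep, enc[i], k, c)) continue;
      NWResult w = nw_core(rep, enc[i], ism, iopen, iext);
      const double shorter =
          (double)std::min(rep.size(), enc[i].size());
      const double id = w.nid / shorter, cov = w.nal / shorter;
      // strict '>' keeps the lowest cluster index on ties
      if (id + 1e-12 >= c && cov + 1e-12 >= a && id > best_id) {
        best = (int)r;
        best_id = id;
        best_cov = cov;
      }
    }
    if (best < 0) {
      reps.push_back(i);
      assign[i] = (int)reps.size();
      identity[i] = 1.0;
      coverage[i] = 1.0;
    } else {
      assign[i] = best + 1;
      identity[i] = best_id;
      coverage[i] = best_cov;
    }
    if (i % 64 == 0) checkUserInterrupt();
  }
  LogicalVector is_rep(n, false);
  for (size_t r = 0; r < reps.size(); ++r) is_rep[reps[r]] = true;
  return List::create(_["cluster"] = assign, _["identity"] = identity,
                      _["coverage"] = coverage, _["is_representative"] = is_rep,
                      _["n_clusters"] = (int)reps.size());
}

// Profile-profile global alignment for the progressive aligner.  Profiles
// are integer matrices (rows = sequences, cols = alignment columns), codes
// 0..(A-1) for residues and A for the gap symbol.  Column-column score is
// the mean substitution score over residue-residue pairs (gap pairs
// contribute 0).  Returns, per output column, the source column in each
// profile (NA = new gap column).  Ties: diagonal > gap-in-B > gap-in-A.
// [[Rcpp::export(name = ".profile_nw_cpp")]]
List profile_nw_cpp(IntegerMatrix pa, IntegerMatrix pb, NumericMatrix sm,
                    double open, double ext) {
  const int n = pa.ncol(), m = pb.ncol();
  const int ra = pa.nrow(), rb = pb.nrow();
  const int A = sm.nrow();  // gap code == A

  // precompute residue counts per column
  std::vector<std::vector<int> > ca(n, std::vector<int>(A, 0)),
      cb(m, std::vector<int>(A, 0));
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < ra; ++i)
      if (pa(i, j) < A) ca[j][pa(i, j)]++;
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < rb; ++i)
      if (pb(i, j) < A) cb[j][pb(i, j)]++;

  auto colscore = [&](int ja, int jb) {
    double s = 0.0;
    for (int x = 0; x < A; ++x) {
      if (!ca[ja][x]) continue;
      for (int y = 0; y < A; ++y)
        if (cb[jb][y]) s += ca[ja][x] * (double)cb[jb][y] * sm(x, y);
    }
    return s / ((double)ra * (double)rb);
  };

  // Gotoh with traceback; state 0 = M, 1 = E (consume A col), 2 = F (B col)
  const double NEG = -1e18;
  std::vector<double> M((n + 1) * (m + 1), NEG), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tbM((n + 1) * (m + 1)),
      tbE((n + 1) * (m + 1)), tbF((n + 1) * (m + 1));
  auto ix = [&](int i, int j) { return i * (m + 1) + j; };

  M[ix(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    E[ix(i, 0)] = -(open + ext * i);
    tbE[ix(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    F[ix(0, j)] = -(open + ext * j);
    tbF[ix(0, j)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = colscore(i - 1, j - 1);
      // M from best predecessor at (i-1, j-1); tie: M > E > F
      double bm = M[ix(i - 1, j - 1)];
      unsigned char tm = 0;
      if (E[ix(i - 1, j - 1)] > bm) { bm = E[ix(i - 1, j - 1)]; tm = 1; }
      if (F[ix(i - 1, j - 1)] > bm) { bm = F[ix(i - 1, j - 1)]; tm = 2; }
      M[ix(i, j)] = (bm <= NEG / 2) ? NEG : bm + s;
      tbM[ix(i, j)] = tm;
      // E: consume column of A against gap
      double e = M[ix(i - 1, j)] - open - ext;
      unsigned char te = 0;
      if (E[ix(i - 1, j)] - ext > e) { e = E[ix(i - 1, j)] - ext; te = 1; }
      if (F[ix(i - 1, j)] - open - ext > e) {
        e = F[ix(i - 1, j)] - open - ext; te = 2;
      }
      E[ix(i, j)] = e;
      tbE[ix(i, j)] = te;
      // F: consume column of B against gap
      double f = M[ix(i, j - 1)] - open - ext;
      unsigned char tf = 0;
      if (F[ix(i, j - 1)] - ext > f) { f = F[ix(i, j - 1)] - ext; tf = 2; }
      if (E[ix(i, j - 1)] - open - ext > f) {
        f = E[ix(i, j - 1)] - open - ext; tf = 1;
      }
      F[ix(i, j)] = f;
      tbF[ix(i, j)] = tf;
    }
  }
  // pick final state; tie: M > E > F
  int state = 0;
  double bv = M[ix(n, m)];
  if (E[ix(n, m)] > bv) { bv = E[ix(n, m)]; state = 1; }
  if (F[ix(n, m)] > bv) { bv = F[ix(n, m)]; state = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char t = tbM[ix(i, j)];
      ai.push_back(i);
      bi.push_back(j);
      --i; --j;
      state = t;
    } else if (state == 1) {
      unsigned char t = tbE[ix(i, j)];
      ai.push_back(i);
      bi.push_back(NA_INTEGER);
      --i;
      state = t;
    } else {
      unsigned char t = tbF[ix(i, j)];
      ai.push_back(NA_INTEGER);
      bi.push_back(j);
      --j;
      state = t;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a_col"] = wrap(ai), _["b_col"] = wrap(bi),
                      _["score"] = bv);
}
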