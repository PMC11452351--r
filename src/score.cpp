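// Core haplotype-homozygosity machinery: local clusters by Hamming
// distance, EHH partition walks, trapezoidal iHH integration, and the
// SNP-count (nSL-style) walk.  All routines are deterministic.
#include <Rcpp.h>
#include <map>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// Refining partition of a haplotype set walking away from a core site.
struct Partition {
  std::vector<int> grp;   // group id per member
  std::vector<int> newid, cnt;  // reusable scratch (no per-marker malloc)
  int ngroups;
  explicit Partition(int k) : grp(k, 0), ngroups(1) {
    newid.reserve(2 * k + 2);
    cnt.reserve(k + 1);
  }
  // refine by allele at column `col` for rows `rows` of A; return EHH
  double refine(const IntegerMatrix& A, const std::vector<int>& rows, int col) {
    const int k = (int)rows.size();
    newid.assign(2 * ngroups, -1);
    int nxt = 0;
    for (int u = 0; u < k; ++u) {
      int key = grp[u] * 2 + A(rows[u], col);
      if (newid[key] < 0) newid[key] = nxt++;
      grp[u] = newid[key];
    }
    ngroups = nxt;
    cnt.assign(ngroups, 0);
    for (int u = 0; u < k; ++u) cnt[grp[u]]++;
    double num = 0.0;
    for (int g = 0; g < ngroups; ++g) num += (double)cnt[g] * (cnt[g] - 1.0);
    return num / ((double)k * (k - 1.0));
  }
};

// Trapezoidal integral of the EHH curve for `rows`, both directions from
// x0, stopping per side at L markers, the window edge, or when EHH falls
// below `cutoff` (the trapezoid reaching the sub-cutoff marker is
// included, then extension stops).
double ihh_walk(const IntegerMatrix& A, const std::vector<int>& rows,
                int x0, int lo, int hi, const NumericVector& gpos,
                double cutoff, int L) {
  if ((int)rows.size() < 2) return NA_REAL;
  double ihh = 0.0;
  // downstream; the identity stretch includes the core site itself, so
  // members carrying the opposite core allele split from the start
  // (no effect on single-class sets)
  {
    Partition part((int)rows.size());
    double prev = part.refine(A, rows, x0);
    int last = std::min(hi, x0 + L);
    for (int i = x0 + 1; i <= last; ++i) {
      double cur = part.refine(A, rows, i);
      ihh += 0.5 * (prev + cur) * (gpos[i] - gpos[i - 1]);
      prev = cur;
      if (cur < cutoff || cur <= 0.0) break;
    }
  }
  // upstream
  {
    Partition part((int)rows.size());
    double prev = part.refine(A, rows, x0);
    int first = std::max(lo, x0 - L);
    for (int i = x0 - 1; i >= first; --i) {
      double cur = part.refine(A, rows, i);
      ihh += 0.5 * (prev + cur) * (gpos[i + 1] - gpos[i]);
      prev = cur;
      if (cur < cutoff || cur <= 0.0) break;
    }
  }
  return ihh;
}

// Rectangle sum of EHH over marker counts (unit inter-marker weight),
// capped at `cap` markers per side: mean pairwise shared-stretch length
// is 1 + sum_down + sum_up.
double nsl_walk(const IntegerMatrix& A, const std::vector<int>& rows,
                int x0, int lo, int hi, int cap) {
  if ((int)rows.size() < 2) return NA_REAL;
  double total = 1.0;
  for (int dir = 0; dir < 2; ++dir) {
    Partition part((int)rows.size());
    if (dir == 0) {
      int last = std::min(hi, x0 + cap);
      for (int i = x0 + 1; i <= last; ++i) {
        double cur = part.refine(A, rows, i);
        total += cur;
        if (cur <= 0.0) break;
      }
    } else {
      int first = std::max(lo, x0 - cap);
      for (int i = x0 - 1; i >= first; --i) {
        double cur = part.refine(A, rows, i);
        total += cur;
        if (cur <= 0.0) break;
      }
    }
  }
  return total;
}

// Bit-pack rows over columns [lo, hi] and return pairwise Hamming
// distances within the set (condensed, row-major upper triangle).
void hamming_within(const IntegerMatrix& A, const std::vector<int>& rows,
                    int lo, int hi, std::vector<int>& dist) {
  const int k = (int)rows.size();
  const int w = hi - lo + 1;
  const int nw = (w + 63) / 64;
  std::vector<uint64_t> bits((size_t)k * nw, 0ULL);
  for (int u = 0; u < k; ++u) {
    uint64_t* b = &bits[(size_t)u * nw];
    for (int c = lo; c <= hi; ++c)
      if (A(rows[u], c)) b[(c - lo) >> 6] |= (1ULL << ((c - lo) & 63));
  }
  dist.assign((size_t)k * k, 0);
  for (int u = 0; u < k; ++u) {
    const uint64_t* bu = &bits[(size_t)u * nw];
    for (int v = u + 1; v < k; ++v) {
      const uint64_t* bv = &bits[(size_t)v * nw];
      int d = 0;
      for (int q = 0; q < nw; ++q) {
#if defined(__GNUC__) || defined(__clang__)
        d += __builtin_popcountll(bu[q] ^ bv[q]);
#else
        uint64_t x = bu[q] ^ bv[q];
        while (x) { x &= x - 1; ++d; }
#endif
      }
      dist[(size_t)u * k + v] = d;
      dist[(size_t)v * k + u] = d;
    }
  }
}

// Cluster diameter rule s = min(max(ceil(r*nc), 8), nc).
int cluster_s(double r, int nc, int s_floor) {
  int s = (int)std::ceil(r * nc);
  if (s < s_floor) s = s_floor;
  if (s > nc) s = nc;
  return s;
}

// Nearest-neighbour cluster of focal `f` (index within `rows`):
// focal + s class members minimising (Hamming distance, haplotype index).
std::vector<int> nn_cluster(const std::vector<int>& rows,
                            const std::vector<int>& dist, int f, int s) {
  const int k = (int)rows.size();
  if (s >= k) return rows;  // whole class
  std::vector<int> ord;
  ord.reserve(k - 1);
  for (int v = 0; v < k; ++v)
    if (v != f) ord.push_back(v);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    int da = dist[(size_t)f * k + a], db = dist[(size_t)f * k + b];
    if (da != db) return da < db;
    return rows[a] < rows[b];
  });
  std::vector<int> mem;
  mem.reserve(s + 1);
  mem.push_back(rows[f]);
  for (int q = 0; q < s && q < (int)ord.size(); ++q)
    mem.push_back(rows[ord[q]]);
  return mem;
}

}  // namespace

// Per-site scoring backbone: for each requested site return class sizes,
// whole-class iHH and cluster-averaged iHHL for both alleles.
// `pool_all`: nearest-neighbour candidates come from the full sample
// rather than the focal's allele class; the identity stretch then starts
// at the core site itself, so opposite-core members split immediately.
// [[Rcpp::export]]
List cpp_score_sites(IntegerMatrix alleles, NumericVector gpos,
                     IntegerVector sites, double r, int L,
                     double ehh_cutoff, int min_class, int s_floor,
                     bool pool_all) {
  const int n = alleles.nrow(), m = alleles.ncol();
  const int ns = sites.size();
  NumericVector freq1(ns), ihhl1(ns), ihhl0(ns), ihh1(ns), ihh0(ns);
  IntegerVector n1(ns), n0(ns), scl1(ns), scl0(ns);
  LogicalVector edge(ns);
  CharacterVector status(ns);

  for (int t = 0; t < ns; ++t) {
    const int x0 = sites[t];
    if (x0 < 0 || x0 >= m) stop("site index out of range");
    std::vector<int> c1, c0;
    for (int j = 0; j < n; ++j) (alleles(j, x0) ? c1 : c0).push_back(j);
    n1[t] = (int)c1.size();
    n0[t] = (int)c0.size();
    freq1[t] = (double)c1.size() / n;
    ihhl1[t] = ihhl0[t] = ihh1[t] = ihh0[t] = NA_REAL;
    scl1[t] = scl0[t] = NA_INTEGER;
    const int lo = std::max(0, x0 - L), hi = std::min(m - 1, x0 + L);
    edge[t] = (x0 - L < 0) || (x0 + L > m - 1);
    if ((int)c1.size() < min_class || (int)c0.size() < min_class) {
      status[t] = "class_too_small";
      continue;
    }
    std::vector<int> allrows, dist_all;
    if (pool_all) {
      allrows.resize(n);
      for (int j = 0; j < n; ++j) allrows[j] = j;
      hamming_within(alleles, allrows, lo, hi, dist_all);
    }
    bool ok = true;
    for (int cls = 0; cls < 2; ++cls) {
      const std::vector<int>& rows = cls ? c1 : c0;
      const int k = (int)rows.size();
      const int s = cluster_s(r, k, s_floor);
      double ihh_class = ihh_walk(alleles, rows, x0, lo, hi, gpos,
                                  ehh_cutoff, L);
      double ihhl;
      if (s >= k && !pool_all) {
        ihhl = ihh_class;  // cluster is the whole class for every focal
      } else {
        std::vector<int> dist;
        if (!pool_all) hamming_within(alleles, rows, lo, hi, dist);
        // focals in the same haplotype family often share an identical
        // cluster; cache walks by member set
        std::map<std::vector<int>, double> cache;
        double acc = 0.0;
        for (int f = 0; f < k; ++f) {
          std::vector<int> mem = pool_all
              ? nn_cluster(allrows, dist_all, rows[f], s)
              : nn_cluster(rows, dist, f, s);
          std::vector<int> key(mem);
          std::sort(key.begin(), key.end());
          auto it = cache.find(key);
          double v;
          if (it != cache.end()) {
            v = it->second;
          } else {
            v = ihh_walk(alleles, mem, x0, lo, hi, gpos, ehh_cutoff, L);
            cache.emplace(std::move(key), v);
          }
          acc += v;
        }
        ihhl = acc / k;
      }
      if (cls) { ihh1[t] = ihh_class; ihhl1[t] = ihhl; scl1[t] = s; }
      else     { ihh0[t] = ihh_class; ihhl0[t] = ihhl; scl0[t] = s; }
      if (!(ihh_class > 0.0) || !(ihhl > 0.0)) ok = false;
    }
    status[t] = ok ? "ok" : "zero_ihh";
  }
  return List::create(
      _["site"] = sites, _["freq1"] = freq1, _["n1"] = n1, _["n0"] = n0,
      _["s1"] = scl1, _["s0"] = scl0,
      _["iHHL1"] = ihhl1, _["iHHL0"] = ihhl0,
      _["iHH1"] = ihh1, _["iHH0"] = ihh0,
      _["edge"] = edge, _["status"] = status);
}

// Mean pairwise shared-stretch lengths (in SNP counts, capped per side)
// for both allele classes at each requested site.
// [[Rcpp::export]]
List cpp_nsl_sites(IntegerMatrix alleles, IntegerVector sites, int cap,
                   int min_class) {
  const int n = alleles.nrow(), m = alleles.ncol();
  const int ns = sites.size();
  NumericVector freq1(ns), sl1(ns), sl0(ns);
  IntegerVector n1(ns), n0(ns);
  CharacterVector status(ns);
  for (int t = 0; t < ns; ++t) {
    const int x0 = sites[t];
    if (x0 < 0 || x0 >= m) stop("site index out of range");
    std::vector<int> c1, c0;
    for (int j = 0; j < n; ++j) (alleles(j, x0) ? c1 : c0).push_back(j);
    n1[t] = (int)c1.size();
    n0[t] = (int)c0.size();
    freq1[t] = (double)c1.size() / n;
    sl1[t] = sl0[t] = NA_REAL;
    if ((int)c1.size() < min_class || (int)c0.size() < min_class) {
      status[t] = "class_too_small";
      continue;
    }
    sl1[t] = nsl_walk(alleles, c1, x0, 0, m - 1, cap);
    sl0[t] = nsl_walk(alleles, c0, x0, 0, m - 1, cap);
    status[t] = "ok";
  }
  return List::create(_["site"] = sites, _["freq1"] = freq1,
                      _["n1"] = n1, _["n0"] = n0,
                      _["SL1"] = sl1, _["SL0"] = sl0,
                      _["status"] = status);
}

// iHH of one haplotype set with the production stopping rules (exported
// for the fine-grained accessors and oracle comparisons).
// [[Rcpp::export]]
double cpp_ihh_cluster(IntegerMatrix alleles, NumericVector gpos,
                       IntegerVector rows0, int x0, int L, double cutoff) {
  const int m = alleles.ncol();
  if (x0 < 0 || x0 >= m) stop("site index out of range");
  std::vector<int> rows(rows0.begin(), rows0.end());
  const int lo = std::max(0, x0 - L), hi = std::min(m - 1, x0 + L);
  return ihh_walk(alleles, rows, x0, lo, hi, gpos, cutoff, L);
}

// EHH curve of one haplotype set from the core outward (exported for the
// cluster/EHH accessors and the brute-force oracle comparisons).
// Returns EHH at each marker from x0+1..right and x0-1..left (no early
// stopping), NA outside the scan range.
// [[Rcpp::export]]
NumericVector cpp_ehh_curve(IntegerMatrix alleles, IntegerVector rows0,
                            int x0, int left, int right) {
  const int m = alleles.ncol();
  if (x0 < 0 || x0 >= m || left < 0 || right >= m || left > x0 || right < x0)
    stop("invalid curve range");
  if (rows0.size() < 2) stop("degenerate set: need >= 2 haplotypes");
  std::vector<int> rows(rows0.begin(), rows0.end());
  NumericVector out(right - left + 1, NA_REAL);
  out[x0 - left] = 1.0;
  {
    Partition part((int)rows.size());
    for (int i = x0 + 1; i <= right; ++i)
      out[i - left] = part.refine(alleles, rows, i);
  }
  {
    Partition part((int)rows.size());
    for (int i = x0 - 1; i >= left; --i)
      out[i - left] = part.refine(alleles, rows, i);
  }
  return out;
}

// Pairwise Hamming distances of `rows` over columns [lo, hi] (dense
// matrix; used by localCluster and tests).
// [[Rcpp::export]]
IntegerMatrix cpp_hamming(IntegerMatrix alleles, IntegerVector rows0,
                          int lo, int hi) {
  std::vector<int> rows(rows0.begin(), rows0.end());
  std::vector<int> dist;
  hamming_within(alleles, rows, lo, hi, dist);
  const int k = (int)rows.size();
  IntegerMatrix out(k, k);
  for (int u = 0; u < k; ++u)
    for (int v = 0; v < k; ++v) out(u, v) = dist[(size_t)u * k + v];
  return out;
}
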