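// Rescaled forward Wright-Fisher sweep engine on full haplotypes.
//
// The beneficial allele's per-generation carrier counts are supplied as a
// pre-simulated trajectory, so transmission is conditioned: carrier
// offspring draw their core-donating parent uniformly from carriers, the
// rest from non-carriers, and selection enters only through the
// trajectory.  Recombination donates non-core segments from a uniformly
// chosen second parent; new neutral mutations follow the infinite-sites
// model.  Founder lineages are tracked as onset-ancestor labels of the
// core locus.  Uses R's RNG throughout (deterministic under set.seed).
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Hap {
  std::vector<int> sites;  // derived-site ids, sorted by genomic position
  bool carrier = false;
  int label = -1;          // founder label of the core locus, -1 if none
};

inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

}  // namespace

// [[Rcpp::export]]
List cpp_forward_sweep(IntegerMatrix base, NumericVector pos,
                       LogicalVector carrier0, IntegerVector traj,
                       IntegerVector origins, double rec_per_gen,
                       double mut_per_gen, double L_bp, double core_pos,
                       int n_sample) {
  const int N2 = base.nrow();          // population size in haplotypes (2N)
  const int S0 = base.ncol();
  const int T = traj.size();
  if (origins.size() != T) stop("traj/origins length mismatch");
  if (n_sample > N2) stop("sample larger than population");

  std::vector<double> site_pos(pos.begin(), pos.end());
  auto pos_less = [&site_pos](int a, int b) {
    if (site_pos[a] != site_pos[b]) return site_pos[a] < site_pos[b];
    return a < b;
  };

  std::vector<Hap> pop(N2), nxt(N2);
  int next_label = 0;
  for (int j = 0; j < N2; ++j) {
    for (int c = 0; c < S0; ++c)
      if (base(j, c)) pop[j].sites.push_back(c);
    if (carrier0[j]) {
      pop[j].carrier = true;
      pop[j].label = next_label++;
    }
  }

  std::vector<int> car, non, brk_par;
  std::vector<double> brks;
  for (int t = 0; t < T; ++t) {
    car.clear();
    non.clear();
    for (int j = 0; j < N2; ++j) (pop[j].carrier ? car : non).push_back(j);
    const int k_trans = traj[t] - origins[t];
    if (k_trans < 0 || k_trans > N2)
      stop("inconsistent trajectory at generation %d", t + 1);
    if (k_trans > 0 && car.empty())
      stop("trajectory demands carriers but none remain (generation %d)",
           t + 1);
    if (k_trans < N2 && non.empty())
      stop("trajectory demands non-carriers but none remain (generation %d)",
           t + 1);
    for (int j = 0; j < N2; ++j) {
      const bool as_carrier = j < k_trans;
      const std::vector<int>& pool = as_carrier ? car : non;
      const Hap& p1 = pop[pool[runif_int((int)pool.size())]];
      Hap& off = nxt[j];
      off.carrier = as_carrier;
      off.label = as_carrier ? p1.label : -1;
      const int ncross = (int)R::rpois(rec_per_gen);
      if (ncross == 0) {
        off.sites = p1.sites;
      } else {
        brks.clear();
        for (int q = 0; q < ncross; ++q) brks.push_back(unif_rand() * L_bp);
        std::sort(brks.begin(), brks.end());
        brks.push_back(L_bp + 1.0);
        // parity of the segment containing the core decides which
        // segments stay with the core-donating parent; with time
        // rescaling one step stands for Q meioses, so each foreign
        // segment draws its own donor
        int core_seg = 0;
        while (brks[core_seg] <= core_pos) ++core_seg;
        off.sites.clear();
        double lo = 0.0;
        for (int seg = 0; seg <= ncross; ++seg) {
          const double hi2 = brks[seg];
          const std::vector<int>& src =
              ((seg % 2) == (core_seg % 2)) ? p1.sites
                                            : pop[runif_int(N2)].sites;
          // ids with lo <= pos < hi2
          auto it = std::lower_bound(
              src.begin(), src.end(), lo,
              [&site_pos](int id, double x) { return site_pos[id] < x; });
          for (; it != src.end() && site_pos[*it] < hi2; ++it)
            off.sites.push_back(*it);
          lo = hi2;
        }
      }
      const int nmut = (int)R::rpois(mut_per_gen);
      for (int q = 0; q < nmut; ++q) {
        const double mp = unif_rand() * L_bp;
        site_pos.push_back(mp);
        const int id = (int)site_pos.size() - 1;
        auto it = std::lower_bound(off.sites.begin(), off.sites.end(), id,
                                   pos_less);
        off.sites.insert(it, id);
      }
    }
    // recurrent beneficial origins on random non-carrier offspring
    if (origins[t] > 0) {
      non.clear();
      for (int j = 0; j < N2; ++j)
        if (!nxt[j].carrier) non.push_back(j);
      if ((int)non.size() < origins[t])
        stop("not enough non-carriers for new origins (generation %d)", t + 1);
      for (int q = 0; q < origins[t]; ++q) {
        const int pick = runif_int((int)non.size() - q);
        std::swap(non[pick], non[non.size() - 1 - q]);
        Hap& h = nxt[non[non.size() - 1 - q]];
        h.carrier = true;
        h.label = next_label++;
      }
    }
    pop.swap(nxt);
  }

  // sample without replacement
  std::vector<int> idx(N2);
  for (int j = 0; j < N2; ++j) idx[j] = j;
  for (int j = 0; j < n_sample; ++j)
    std::swap(idx[j], idx[j + runif_int(N2 - j)]);
  idx.resize(n_sample);

  // segregating sites in the sample
  std::vector<int> cnt((int)site_pos.size(), 0);
  for (int u = 0; u < n_sample; ++u)
    for (int id : pop[idx[u]].sites) cnt[id]++;
  std::vector<int> keep;
  for (int id = 0; id < (int)cnt.size(); ++id)
    if (cnt[id] > 0 && cnt[id] < n_sample) keep.push_back(id);
  std::sort(keep.begin(), keep.end(), pos_less);

  int sample_core = 0;
  std::vector<int> labels;
  for (int u = 0; u < n_sample; ++u)
    if (pop[idx[u]].carrier) {
      sample_core++;
      labels.push_back(pop[idx[u]].label);
    }
  std::sort(labels.begin(), labels.end());
  labels.erase(std::unique(labels.begin(), labels.end()), labels.end());

  const bool core_seg = sample_core > 0 && sample_core < n_sample;
  const int ncol_out = (int)keep.size() + (core_seg ? 1 : 0);
  int core_col = -1;
  NumericVector out_pos(ncol_out);
  IntegerMatrix out((int)n_sample, ncol_out);
  std::vector<int> col_of((int)site_pos.size(), -1);
  {
    int c = 0;
    bool placed = !core_seg;
    for (size_t q = 0; q < keep.size(); ++q) {
      if (!placed && site_pos[keep[q]] >= core_pos) {
        core_col = c;
        out_pos[c++] = core_pos;
        placed = true;
      }
      col_of[keep[q]] = c;
      out_pos[c++] = site_pos[keep[q]];
    }
    if (!placed) {
      core_col = c;
      out_pos[c] = core_pos;
    }
  }
  for (int u = 0; u < n_sample; ++u) {
    const Hap& h = pop[idx[u]];
    for (int id : h.sites)
      if (col_of[id] >= 0) out(u, col_of[id]) = 1;
    if (core_seg && h.carrier) out(u, core_col) = 1;
  }

  int pop_final = 0;
  for (int j = 0; j < N2; ++j)
    if (pop[j].carrier) pop_final++;

  return List::create(
      _["alleles"] = out, _["pos"] = out_pos,
      _["core_col"] = core_col >= 0 ? core_col + 1 : NA_INTEGER,
      _["sample_core_count"] = sample_core,
      _["founders"] = (int)labels.size(),
      _["pop_final_count"] = pop_final);
}
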