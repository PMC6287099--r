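// Forward-time diploid Wright-Fisher core with recombination, infinite-sites
// mutation on integer positions, and additive selection at one site.
//
// Haplotypes are sorted vectors of positions carrying the derived allele.
// R orchestrates epochs (burn-in, splits, sweep retries); this file only
// evolves one population for a fixed number of generations.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> Hap;

static void make_gamete(const Hap &a, const Hap &b, int L, double rec_rate,
                        double mu, std::mt19937_64 &rng,
                        std::unordered_set<int> &used, Hap &out) {
  out.clear();
  std::poisson_distribution<int> pois_x(rec_rate * L);
  std::uniform_int_distribution<int> upos(0, L - 1);
  std::bernoulli_distribution coin(0.5);

  int k = pois_x(rng);
  std::vector<int> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = upos(rng);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());
  bp.push_back(L);  // sentinel

  bool from_a = coin(rng);
  int seg_start = 0;
  out.reserve(a.size() + 8);
  for (size_t s = 0; s < bp.size(); ++s) {
    int seg_end = bp[s];
    const Hap &src = from_a ? a : b;
    Hap::const_iterator lo =
        std::lower_bound(src.begin(), src.end(), seg_start);
    Hap::const_iterator hi = std::lower_bound(lo, src.end(), seg_end);
    out.insert(out.end(), lo, hi);
    from_a = !from_a;
    seg_start = seg_end;
  }

  std::poisson_distribution<int> pois_m(mu * L);
  int m = pois_m(rng);
  if (m > 0) {
    size_t sorted_len = out.size();
    for (int i = 0; i < m; ++i) {
      int p;
      int tries = 0;
      do {
        p = upos(rng);
        ++tries;
      } while (used.count(p) && tries < 1000);
      if (used.count(p)) continue;  // position space exhausted; drop
      used.insert(p);
      out.push_back(p);
    }
    std::sort(out.begin() + sorted_len, out.end());
    std::inplace_merge(out.begin(), out.begin() + sorted_len, out.end());
  }
}

static int count_allele(const Hap &h, int pos) {
  return std::binary_search(h.begin(), h.end(), pos) ? 1 : 0;
}

static void purge_fixed(std::vector<Hap> &pop) {
  // remove positions carried by every haplotype (globally fixed in this pool)
  size_t n = pop.size();
  std::unordered_map<int, size_t> counts;
  for (const Hap &h : pop)
    for (int p : h) ++counts[p];
  std::unordered_set<int> fixed;
  for (auto &kv : counts)
    if (kv.second == n) fixed.insert(kv.first);
  if (fixed.empty()) return;
  for (Hap &h : pop) {
    Hap keep;
    keep.reserve(h.size());
    for (int p : h)
      if (!fixed.count(p)) keep.push_back(p);
    h.swap(keep);
  }
}

// [[Rcpp::export]]
List wf_evolve_cpp(List haps, int N, int L, double mu, double rec_rate,
                   int gens, double s, int sel_pos,
                   IntegerVector used_positions, int seed,
                   bool purge = false, int purge_every = 25,
                   bool stop_on_loss = false) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  int n_hap = haps.size();
  std::vector<Hap> pop(n_hap);
  for (int i = 0; i < n_hap; ++i) {
    IntegerVector v = haps[i];
    pop[i] = Hap(v.begin(), v.end());
  }
  std::unordered_set<int> used(used_positions.begin(), used_positions.end());

  std::vector<Hap> next(2 * N);
  std::vector<double> fitness(n_hap / 2);

  for (int g = 0; g < gens; ++g) {
    int n_par = static_cast<int>(pop.size()) / 2;
    // parent fitness
    bool selecting = (s != 0.0 && sel_pos >= 0);
    if (selecting) {
      fitness.assign(n_par, 1.0);
      for (int i = 0; i < n_par; ++i) {
        int c = count_allele(pop[2 * i], sel_pos) +
                count_allele(pop[2 * i + 1], sel_pos);
        fitness[i] = 1.0 + s * c / 2.0;  // 1, 1+s/2, 1+s
      }
    }
    std::discrete_distribution<int> pick_sel;
    std::uniform_int_distribution<int> pick_unif(0, n_par - 1);
    if (selecting)
      pick_sel = std::discrete_distribution<int>(fitness.begin(),
                                                 fitness.end());
    next.resize(2 * N);
    for (int i = 0; i < N; ++i) {
      int p1 = selecting ? pick_sel(rng) : pick_unif(rng);
      int p2 = selecting ? pick_sel(rng) : pick_unif(rng);
      make_gamete(pop[2 * p1], pop[2 * p1 + 1], L, rec_rate, mu, rng, used,
                  next[2 * i]);
      make_gamete(pop[2 * p2], pop[2 * p2 + 1], L, rec_rate, mu, rng, used,
                  next[2 * i + 1]);
    }
    pop.swap(next);
    if (purge && ((g + 1) % purge_every == 0)) purge_fixed(pop);
    if (stop_on_loss && s != 0.0 && sel_pos >= 0) {
      int c = 0;
      for (const Hap &h : pop) c += count_allele(h, sel_pos);
      if (c == 0) break;  // lost: caller will resimulate this epoch
    }
  }
  if (purge) purge_fixed(pop);

  int sel_count = 0;
  if (sel_pos >= 0)
    for (const Hap &h : pop) sel_count += count_allele(h, sel_pos);

  List out_haps(2 * N);
  for (int i = 0; i < 2 * N; ++i)
    out_haps[i] = IntegerVector(pop[i].begin(), pop[i].end());
  std::vector<int> used_sorted(used.begin(), used.end());
  std::sort(used_sorted.begin(), used_sorted.end());
  IntegerVector out_used(used_sorted.begin(), used_sorted.end());
  return List::create(_["haps"] = out_haps,
                      _["used_positions"] = out_used,
                      _["sel_count"] = sel_count);
}
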