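// EHH decay walk for one core site and one direction.
// Haplotype-identity groups are refined site by site outward from the core
// (core site excluded); EHH(x) = sum_h C(n_h,2) / C(n,2).

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List ehh_walk_cpp(IntegerMatrix h, NumericVector positions, int core_index,
                  int dir, double min_ehh, double max_extension_bp) {
  int n = h.nrow();
  int n_sites = h.ncol();
  int core = core_index - 1;  // 1-based from R
  double pairs_total = n * (n - 1) / 2.0;
  double core_pos = positions[core];

  std::vector<int> grp(n, 0);
  std::vector<int> remap;
  std::vector<int> tab;
  std::vector<double> out_pos(1, core_pos);
  std::vector<double> out_ehh(1, 1.0);
  double prev_pos = core_pos, prev_ehh = 1.0, ihh = 0.0;
  bool decayed = false, hit_edge = false;
  int n_groups = 1;

  int i = core + dir;
  while (i >= 0 && i < n_sites) {
    double d = positions[i] - core_pos;
    if (d < 0) d = -d;
    if (d > max_extension_bp) break;
    // refine: new id = old id * 2 + allele, then compact
    remap.assign(2 * n_groups + 2, -1);
    int next_id = 0;
    for (int k = 0; k < n; ++k) {
      int key = grp[k] * 2 + h(k, i);
      if (remap[key] < 0) remap[key] = next_id++;
      grp[k] = remap[key];
    }
    n_groups = next_id;
    tab.assign(n_groups, 0);
    for (int k = 0; k < n; ++k) ++tab[grp[k]];
    double e = 0.0;
    for (int g = 0; g < n_groups; ++g)
      e += tab[g] * (tab[g] - 1) / 2.0;
    e /= pairs_total;
    out_pos.push_back(positions[i]);
    out_ehh.push_back(e);
    double step = positions[i] - prev_pos;
    if (step < 0) step = -step;
    ihh += (prev_ehh + e) / 2.0 * step;
    prev_pos = positions[i];
    prev_ehh = e;
    if (e < min_ehh) {
      decayed = true;
      break;
    }
    i += dir;
  }
  if (!decayed && (i < 0 || i >= n_sites)) hit_edge = true;
  return List::create(_["pos"] = NumericVector(out_pos.begin(), out_pos.end()),
                      _["ehh"] = NumericVector(out_ehh.begin(), out_ehh.end()),
                      _["ihh"] = ihh, _["decayed"] = decayed,
                      _["hit_edge"] = hit_edge);
}

// iHH of both directions plus edge flag, without storing the EHH curves —
// the hot path of the XP-EHH scan.
// [[Rcpp::export]]
List ihh_cpp(IntegerMatrix h, NumericVector positions, int core_index,
             double min_ehh, double max_extension_bp) {
  double ihh = 0.0;
  bool undecayed_edge = false;
  int n = h.nrow();
  int n_sites = h.ncol();
  int core = core_index - 1;
  double pairs_total = n * (n - 1) / 2.0;
  double core_pos = positions[core];
  std::vector<int> grp, remap, tab;
  for (int dir = -1; dir <= 1; dir += 2) {
    grp.assign(n, 0);
    int n_groups = 1;
    double prev_pos = core_pos, prev_ehh = 1.0;
    bool decayed = false;
    int i = core + dir;
    while (i >= 0 && i < n_sites) {
      double d = positions[i] - core_pos;
      if (d < 0) d = -d;
      if (d > max_extension_bp) break;
      remap.assign(2 * n_groups + 2, -1);
      int next_id = 0;
      for (int k = 0; k < n; ++k) {
        int key = grp[k] * 2 + h(k, i);
        if (remap[key] < 0) remap[key] = next_id++;
        grp[k] = remap[key];
      }
      n_groups = next_id;
      tab.assign(n_groups, 0);
      for (int k = 0; k < n; ++k) ++tab[grp[k]];
      double e = 0.0;
      for (int g = 0; g < n_groups; ++g) e += tab[g] * (tab[g] - 1) / 2.0;
      e /= pairs_total;
      double step = positions[i] - prev_pos;
      if (step < 0) step = -step;
      ihh += (prev_ehh + e) / 2.0 * step;
      prev_pos = positions[i];
      prev_ehh = e;
      if (e < min_ehh) { decayed = true; break; }
      i += dir;
    }
    if (!decayed && (i < 0 || i >= n_sites)) undecayed_edge = true;
  }
  return List::create(_["ihh"] = ihh, _["undecayed_edge"] = undecayed_edge);
}
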