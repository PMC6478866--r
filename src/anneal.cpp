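#include <Rcpp.h>
using namespace Rcpp;

// Simulated-annealing minimum-set reserve selection (Marxan-style objective):
//   objective = sum(cost of selected units)
//             + blm * boundary(selected)
//             + spf * sum(penalty of unmet combinations)
// Boundary counts selected-unit edges facing unselected units or the grid
// exterior; every unit has perimeter 4 (rook edges, uniform edge length), so
// boundary = 4 * n_selected - (number of directed selected-selected edges).
//
// One call runs a single chain: random single-unit flip proposals under a
// geometric cooling schedule, a greedy repair pass that meets every feasible
// target, and a trim pass removing units whose removal strictly improves the
// objective without unmeeting targets. Uses R's RNG, so results are
// reproducible under set.seed().

static double flip_delta(int u, const std::vector<char>& sel,
                         const IntegerVector& cost,
                         const IntegerVector& adj_ptr, const IntegerVector& adj_idx,
                         const IntegerVector& uc_ptr, const IntegerVector& uc_idx,
                         const std::vector<int>& cover,
                         const NumericVector& penalty,
                         double blm, double spf) {
  int nsel_nb = 0;
  for (int k = adj_ptr[u]; k < adj_ptr[u + 1]; ++k)
    if (sel[adj_idx[k]]) ++nsel_nb;
  double d;
  if (!sel[u]) {
    d = cost[u] + blm * (4.0 - 2.0 * nsel_nb);
    for (int k = uc_ptr[u]; k < uc_ptr[u + 1]; ++k)
      if (cover[uc_idx[k]] == 0) d -= spf * penalty[uc_idx[k]];
  } else {
    d = -cost[u] - blm * (4.0 - 2.0 * nsel_nb);
    for (int k = uc_ptr[u]; k < uc_ptr[u + 1]; ++k)
      if (cover[uc_idx[k]] == 1) d += spf * penalty[uc_idx[k]];
  }
  return d;
}

static void apply_flip(int u, std::vector<char>& sel,
                       const IntegerVector& uc_ptr, const IntegerVector& uc_idx,
                       std::vector<int>& cover) {
  if (!sel[u]) {
    sel[u] = 1;
    for (int k = uc_ptr[u]; k < uc_ptr[u + 1]; ++k) ++cover[uc_idx[k]];
  } else {
    sel[u] = 0;
    for (int k = uc_ptr[u]; k < uc_ptr[u + 1]; ++k) --cover[uc_idx[k]];
  }
}

// [[Rcpp::export(name = ".anneal_run_cpp")]]
List anneal_run_cpp(IntegerVector cost,
                    IntegerVector adj_ptr, IntegerVector adj_idx,
                    IntegerVector uc_ptr, IntegerVector uc_idx,
                    NumericVector penalty,
                    double blm, double spf,
                    int n_iter, double t_init, double t_final,
                    LogicalVector init_sel) {
  const int n = cost.size();
  const int m = penalty.size();
  std::vector<char> sel(n, 0);
  std::vector<int> cover(m, 0);
  for (int u = 0; u < n; ++u)
    if (init_sel[u]) apply_flip(u, sel, uc_ptr, uc_idx, cover);

  // annealing chain
  if (n_iter > 0 && n > 0) {
    const double ratio = (t_init > 0 && t_final > 0)
                             ? std::pow(t_final / t_init, 1.0 / n_iter)
                             : 1.0;
    double temp = t_init;
    for (int it = 0; it < n_iter; ++it) {
      int u = (int)(unif_rand() * n);
      if (u == n) u = n - 1;
      double d = flip_delta(u, sel, cost, adj_ptr, adj_idx, uc_ptr, uc_idx,
                            cover, penalty, blm, spf);
      if (d < 0 || (temp > 0 && unif_rand() < std::exp(-d / temp)))
        apply_flip(u, sel, uc_ptr, uc_idx, cover);
      temp *= ratio;
    }
  }

  // greedy repair: meet every coverable target
  for (;;) {
    int best = -1, best_gain = 0;
    for (int u = 0; u < n; ++u) { // ascending u keeps the lowest id on ties
      if (sel[u]) continue;
      int gain = 0;
      for (int k = uc_ptr[u]; k < uc_ptr[u + 1]; ++k)
        if (cover[uc_idx[k]] == 0) ++gain;
      if (gain == 0) continue;
      if (best < 0 || gain > best_gain ||
          (gain == best_gain && cost[u] < cost[best])) {
        best = u;
        best_gain = gain;
      }
    }
    if (best < 0) break;
    apply_flip(best, sel, uc_ptr, uc_idx, cover);
  }

  // trim: drop units whose removal strictly improves the objective while
  // keeping all currently-met targets met
  bool changed = true;
  while (changed) {
    changed = false;
    for (int u = 0; u < n; ++u) {
      if (!sel[u]) continue;
      bool removable = true;
      for (int k = uc_ptr[u]; k < uc_ptr[u + 1]; ++k)
        if (cover[uc_idx[k]] == 1) { removable = false; break; }
      if (!removable) continue;
      double d = flip_delta(u, sel, cost, adj_ptr, adj_idx, uc_ptr, uc_idx,
                            cover, penalty, blm, spf);
      if (d < 0) {
        apply_flip(u, sel, uc_ptr, uc_idx, cover);
        changed = true;
      }
    }
  }

  // objective decomposition from scratch
  double tot_cost = 0, boundary = 0, pen = 0;
  int n_sel = 0;
  for (int u = 0; u < n; ++u) {
    if (!sel[u]) continue;
    ++n_sel;
    tot_cost += cost[u];
    int nb = 0;
    for (int k = adj_ptr[u]; k < adj_ptr[u + 1]; ++k)
      if (sel[adj_idx[k]]) ++nb;
    boundary += 4.0 - nb;
  }
  IntegerVector unmet;
  for (int c = 0; c < m; ++c)
    if (cover[c] == 0) {
      pen += spf * penalty[c];
      unmet.push_back(c + 1);
    }
  IntegerVector selected;
  for (int u = 0; u < n; ++u)
    if (sel[u]) selected.push_back(u + 1);

  return List::create(
      _["selected"] = selected, _["n_units"] = n_sel,
      _["total_cost"] = tot_cost, _["boundary"] = boundary,
      _["penalty"] = pen,
      _["objective"] = tot_cost + blm * boundary + pen,
      _["unmet"] = unmet);
}
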