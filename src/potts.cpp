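#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cellular Potts dynamics on an L x L square lattice (4-neighborhood).
// spin 0 = medium, 1..n_cells = cell id. Energy:
//   H = sum_{adjacent site pairs in different cells} J(type_i, type_j)
//     + lambda_area * sum_c (area_c - A)^2
// with cell-medium contacts charged J_med, plus an actin-inspired protrusion
// term: each lattice site carries an activity value that is set to max_act
// when its site is freshly claimed and decays by 1 per Monte-Carlo sweep;
// copy attempts from high-activity into low-activity sites receive an energy
// bonus lambda_act * dGM / max_act where dGM is the difference of geometric
// mean activities around source and target.

static const int DX[4] = {1, -1, 0, 0};
static const int DY[4] = {0, 0, 1, -1};

struct Lattice {
  int L;
  std::vector<int> spin;
  std::vector<double> act;
  std::vector<int> area;
  std::vector<int> type; // 1-based by cell id; type[0] unused
  inline int at(int x, int y) const { return spin[x + L * y]; }
};

static inline bool inb(int c, int L) { return c >= 0 && c < L; }

// geometric mean of activity over a site and its same-cell neighbors
static double gm_activity(const Lattice &lat, int x, int y) {
  int s = lat.at(x, y);
  if (s == 0) return 0.0;
  double logsum = 0.0;
  int cnt = 0;
  double a0 = lat.act[x + lat.L * y];
  if (a0 <= 0.0) return 0.0;
  logsum += std::log(a0);
  cnt++;
  for (int d = 0; d < 4; d++) {
    int nx = x + DX[d], ny = y + DY[d];
    if (!inb(nx, lat.L) || !inb(ny, lat.L)) continue;
    if (lat.at(nx, ny) != s) continue;
    double a = lat.act[nx + lat.L * ny];
    if (a <= 0.0) return 0.0; // geometric mean with a zero is zero
    logsum += std::log(a);
    cnt++;
  }
  return std::exp(logsum / cnt);
}

static double contact_energy(const Lattice &lat, const NumericMatrix &J,
                             double J_med, int site_spin, int x, int y,
                             int skip_x, int skip_y) {
  // contact energy of placing `site_spin` at (x, y), over its 4 neighbors,
  // excluding the (skip) partner used symmetric-pair-free accounting
  double e = 0.0;
  for (int d = 0; d < 4; d++) {
    int nx = x + DX[d], ny = y + DY[d];
    if (!inb(nx, lat.L) || !inb(ny, lat.L)) continue;
    int ns = lat.at(nx, ny);
    if (ns == site_spin) continue;
    if (site_spin == 0 && ns == 0) continue;
    if (site_spin == 0 || ns == 0) e += J_med;
    else e += J(lat.type[site_spin] - 1, lat.type[ns] - 1);
  }
  (void)skip_x;
  (void)skip_y;
  return e;
}

static double total_energy(const Lattice &lat, const NumericMatrix &J,
                           double J_med, double lambda_area, int target_area) {
  double H = 0.0;
  for (int y = 0; y < lat.L; y++) {
    for (int x = 0; x < lat.L; x++) {
      int s = lat.at(x, y);
      // right and down neighbors only: each adjacent pair counted once
      for (int d = 0; d < 2; d++) {
        int nx = (d == 0) ? x + 1 : x;
        int ny = (d == 0) ? y : y + 1;
        if (!inb(nx, lat.L) || !inb(ny, lat.L)) continue;
        int ns = lat.at(nx, ny);
        if (ns == s) continue;
        if (s == 0 || ns == 0) {
          if (s != 0 || ns != 0) H += J_med;
        } else {
          H += J(lat.type[s] - 1, lat.type[ns] - 1);
        }
      }
    }
  }
  for (size_t c = 1; c < lat.area.size(); c++) {
    double da = lat.area[c] - (double)target_area;
    H += lambda_area * da * da;
  }
  return H;
}

// [[Rcpp::export(name = ".potts_run_cpp")]]
List potts_run_cpp(IntegerMatrix spin0, IntegerVector cell_type, NumericMatrix J,
                   double J_med, double lambda_area, int target_area,
                   double lambda_act, double max_act, double temperature,
                   int iterations, int grow_rounds) {
  const int L = spin0.nrow();
  const int n_cells = cell_type.size();
  Lattice lat;
  lat.L = L;
  lat.spin.assign(spin0.begin(), spin0.end());
  lat.act.assign((size_t)L * L, 0.0);
  lat.type.assign(n_cells + 1, 0);
  for (int c = 0; c < n_cells; c++) lat.type[c + 1] = cell_type[c];
  lat.area.assign(n_cells + 1, 0);
  for (int i = 0; i < L * L; i++)
    if (lat.spin[i] > 0) lat.area[lat.spin[i]]++;

  RNGScope rngscope;

  // Growth phase: each cell below target area claims random adjacent empty
  // sites, round-robin in random cell order, until target area or stuck.
  std::vector<int> order(n_cells);
  for (int c = 0; c < n_cells; c++) order[c] = c + 1;
  std::vector<std::vector<int> > sites(n_cells + 1);
  for (int i = 0; i < L * L; i++)
    if (lat.spin[i] > 0) sites[lat.spin[i]].push_back(i);
  for (int round = 0; round < grow_rounds; round++) {
    // shuffle order
    for (int i = n_cells - 1; i > 0; i--) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    bool grew = false;
    for (int oi = 0; oi < n_cells; oi++) {
      int c = order[oi];
      if (lat.area[c] >= target_area) continue;
      // empty sites adjacent to cell c, found by scanning the cell's sites
      std::vector<int> cand;
      for (size_t si = 0; si < sites[c].size(); si++) {
        int i = sites[c][si];
        int x = i % L, y = i / L;
        for (int d = 0; d < 4; d++) {
          int nx = x + DX[d], ny = y + DY[d];
          if (inb(nx, L) && inb(ny, L) && lat.at(nx, ny) == 0)
            cand.push_back(nx + L * ny);
        }
      }
      if (cand.empty()) continue;
      int pick = (int)(unif_rand() * cand.size());
      if (pick >= (int)cand.size()) pick = cand.size() - 1;
      lat.spin[cand[pick]] = c;
      sites[c].push_back(cand[pick]);
      lat.area[c]++;
      grew = true;
    }
    if (!grew) break;
  }

  // Metropolis dynamics
  NumericVector energy_trace(iterations);
  const double invT = temperature > 0 ? 1.0 / temperature : 1e300;
  for (int mcs = 0; mcs < iterations; mcs++) {
    for (int att = 0; att < L * L; att++) {
      int xs = (int)(unif_rand() * L), ys = (int)(unif_rand() * L);
      if (xs >= L) xs = L - 1;
      if (ys >= L) ys = L - 1;
      int d = (int)(unif_rand() * 4);
      if (d >= 4) d = 3;
      int xt = xs + DX[d], yt = ys + DY[d];
      if (!inb(xt, L) || !inb(yt, L)) continue;
      int ss = lat.at(xs, ys), st = lat.at(xt, yt);
      if (ss == st) continue;
      if (st > 0 && lat.area[st] <= 1) continue; // never annihilate a cell
      // adhesion change at the target site
      double dH = contact_energy(lat, J, J_med, ss, xt, yt, xs, ys) -
                  contact_energy(lat, J, J_med, st, xt, yt, xs, ys);
      // area change
      if (ss > 0) {
        double a = lat.area[ss] - (double)target_area;
        dH += lambda_area * ((a + 1.0) * (a + 1.0) - a * a);
      }
      if (st > 0) {
        double a = lat.area[st] - (double)target_area;
        dH += lambda_area * ((a - 1.0) * (a - 1.0) - a * a);
      }
      // actin protrusion bonus
      if (lambda_act > 0.0 && max_act > 0.0) {
        double gms = gm_activity(lat, xs, ys);
        double gmt = gm_activity(lat, xt, yt);
        dH -= lambda_act * (gms - gmt) / max_act;
      }
      if (dH <= 0.0 || unif_rand() < std::exp(-dH * invT)) {
        if (st > 0) lat.area[st]--;
        if (ss > 0) lat.area[ss]++;
        lat.spin[xt + L * yt] = ss;
        lat.act[xt + L * yt] = (ss > 0) ? max_act : 0.0;
      }
    }
    for (int i = 0; i < L * L; i++)
      if (lat.act[i] > 0.0) lat.act[i] -= 1.0;
    energy_trace[mcs] = total_energy(lat, J, J_med, lambda_area, target_area);
  }

  IntegerMatrix out(L, L);
  std::copy(lat.spin.begin(), lat.spin.end(), out.begin());
  IntegerVector areas(n_cells);
  for (int c = 0; c < n_cells; c++) areas[c] = lat.area[c + 1];
  return List::create(_["spin"] = out, _["areas"] = areas,
                      _["energy"] = energy_trace,
                      _["final_energy"] = total_energy(lat, J, J_med,
                                                       lambda_area, target_area));
}
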