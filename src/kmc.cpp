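#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-row lattice kinetic Monte Carlo for tropomyosin loading on a growing
// actin filament.  Each site (i, j) with j in {0,1} (the two grooves) is
// empty or holds one molecule.  Rates:
//   on  (empty site):    k_on * w^a * c^b
//   off (occupied site): k_off / (w^a * c^b)
// a = occupied same-row immediate neighbours (0..2, fewer at the ends),
// b = occupancy of the opposite-groove site (0/1).
// Growth is an extra event of rate v_grow; when it fires at time t the site
// count becomes N = floor(t * v_grow), clamped non-decreasing.  Event
// selection is a cumulative-sum search in fixed order (row 0 sites, row 1
// sites, growth last), realised as a binary sum-tree descent.

namespace {

struct SumTree {
  int P;                       // number of leaves (power of two)
  std::vector<double> v;       // 2P nodes, leaves at [P, 2P)
  void init(int n) {
    P = 1;
    while (P < n) P <<= 1;
    v.assign(2 * P, 0.0);
  }
  void set(int leaf, double x) {
    int k = P + leaf;
    v[k] = x;
    for (k >>= 1; k >= 1; k >>= 1) v[k] = v[2 * k] + v[2 * k + 1];
  }
  double total() const { return v[1]; }
  // first leaf with cumulative sum exceeding x (0 <= x < total)
  int select(double x) const {
    int k = 1;
    while (k < P) {
      if (x < v[2 * k]) {
        k = 2 * k;
      } else {
        x -= v[2 * k];
        k = 2 * k + 1;
      }
    }
    return k - P;
  }
};

}  // namespace

// [[Rcpp::export]]
List kmc_run_cpp(double k_on, double k_off, double w, double c,
                 double v_grow, int n0, double max_time,
                 int stop_at_sites, bool deterministic_growth,
                 bool record_events, NumericVector snapshot_times,
                 double burnin, double max_events, bool stop_when_filled,
                 Nullable<IntegerMatrix> init_occupancy) {
  if (n0 < 1) stop("n0 must be >= 1");
  if (max_time <= 0) stop("max_time must be > 0");
  if (k_on < 0 || k_off < 0 || w < 0 || c < 0 || v_grow < 0)
    stop("rates and cooperativity factors must be non-negative");

  // site capacity over the whole run
  double cap = (double)n0 + (v_grow > 0 ? std::ceil(max_time * v_grow) : 0) + 2;
  if (cap > 2e7) stop("lattice capacity too large (max_time * v_grow)");
  const int M = (int)cap;

  // rate lookup tables indexed [a][b]
  double onf[3][2], off[3][2];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 2; ++b) {
      double f = std::pow(w, a) * std::pow(c, b);
      onf[a][b] = k_on * f;
      off[a][b] = (f > 0) ? k_off / f : R_PosInf;
    }

  std::vector<int> occ(2 * (size_t)M, 0);  // molecule id, 0 = empty
  SumTree tree;
  tree.init(2 * M);

  int N = n0;
  double t = 0.0;
  int n_occ = 0;
  int n_mols = 0;
  if (init_occupancy.isNotNull()) {
    IntegerMatrix ini(init_occupancy);
    if (ini.nrow() != 2 || ini.ncol() != n0)
      stop("init_occupancy must be a 2 x n0 matrix");
    for (int i = 0; i < n0; ++i)
      for (int j = 0; j < 2; ++j)
        if (ini(j, i) != 0) {
          occ[(size_t)j * M + i] = ++n_mols;
          ++n_occ;
        }
  }

  auto idx = [M](int i, int j) { return j * M + i; };
  auto site_rate = [&](int i, int j) -> double {
    int a = 0;
    if (i > 0 && occ[idx(i - 1, j)]) ++a;
    if (i < N - 1 && occ[idx(i + 1, j)]) ++a;
    int b = occ[idx(i, 1 - j)] ? 1 : 0;
    return occ[idx(i, j)] ? off[a][b] : onf[a][b];
  };
  auto update_site = [&](int i, int j) {
    tree.set(idx(i, j), i < N ? site_rate(i, j) : 0.0);
  };
  auto touch = [&](int i, int j) {  // site and every rate it influences
    update_site(i, j);
    if (i > 0) update_site(i - 1, j);
    if (i < N - 1) update_site(i + 1, j);
    update_site(i, 1 - j);
  };
  auto grow_to = [&](double new_time) {
    int Nn = (int)std::floor(new_time * v_grow);
    if (Nn > M) Nn = M;
    if (Nn <= N) return;
    int old = N;
    N = Nn;
    for (int i = std::max(0, old - 1); i < N; ++i)
      for (int j = 0; j < 2; ++j) update_site(i, j);
  };

  for (int i = 0; i < N; ++i)
    for (int j = 0; j < 2; ++j) update_site(i, j);

  std::vector<double> ev_t;
  std::vector<int> ev_type, ev_site, ev_row, ev_mol;

  const int nsnap = snapshot_times.size();
  List snaps(nsnap);
  int snap_i = 0;
  auto state_matrix = [&]() {
    IntegerMatrix m(2, N);
    for (int i = 0; i < N; ++i) {
      m(0, i) = occ[idx(i, 0)];
      m(1, i) = occ[idx(i, 1)];
    }
    return m;
  };

  double occ_int = 0.0, obs_time = 0.0;
  double n_events = 0.0;
  std::string status = "max_time";

  RNGScope scope;
  while (true) {
    double growth_rate = (!deterministic_growth && v_grow > 0) ? v_grow : 0.0;
    double Rtot = tree.total() + growth_rate;
    if (Rtot <= 0) {
      status = "absorbing";
      break;
    }
    double dt = exp_rand() / Rtot;
    double t_new = t + dt;
    double t_cut = std::min(t_new, max_time);
    while (snap_i < nsnap && snapshot_times[snap_i] <= t_cut) {
      snaps[snap_i] = state_matrix();
      ++snap_i;
    }
    if (t_cut > burnin) {
      double span = t_cut - std::max(t, burnin);
      occ_int += n_occ * span;
      obs_time += span;
    }
    if (t_new >= max_time) {
      t = max_time;
      status = "max_time";
      break;
    }
    t = t_new;

    if (deterministic_growth && v_grow > 0) {
      grow_to(t);
      if (stop_at_sites > 0 && N >= stop_at_sites) {
        status = "target_length";
        break;
      }
    }

    double u = unif_rand() * Rtot;
    if (u < tree.total()) {
      int leaf = tree.select(u);
      int j = leaf / M, i = leaf % M;
      if (occ[idx(i, j)]) {  // unbind
        int mol = occ[idx(i, j)];
        occ[idx(i, j)] = 0;
        --n_occ;
        if (record_events) {
          ev_t.push_back(t); ev_type.push_back(2);
          ev_site.push_back(i + 1); ev_row.push_back(j + 1);
          ev_mol.push_back(mol);
        }
      } else {  // bind
        occ[idx(i, j)] = ++n_mols;
        ++n_occ;
        if (record_events) {
          ev_t.push_back(t); ev_type.push_back(1);
          ev_site.push_back(i + 1); ev_row.push_back(j + 1);
          ev_mol.push_back(n_mols);
        }
      }
      touch(i, j);
      if (stop_when_filled && v_grow == 0 && n_occ == 2 * N) {
        status = "filled";
        break;
      }
    } else {  // growth event
      grow_to(t);
      if (record_events) {
        ev_t.push_back(t); ev_type.push_back(3);
        ev_site.push_back(N); ev_row.push_back(NA_INTEGER);
        ev_mol.push_back(NA_INTEGER);
      }
      if (stop_at_sites > 0 && N >= stop_at_sites) {
        status = "target_length";
        break;
      }
    }
    if (++n_events >= max_events) {
      status = "event_cap";
      break;
    }
  }

  // the run is over: the state is frozen, so any remaining snapshot slots
  // within the horizon get the final configuration
  while (snap_i < nsnap && snapshot_times[snap_i] <= max_time) {
    snaps[snap_i] = state_matrix();
    ++snap_i;
  }

  List events = R_NilValue;
  if (record_events) {
    events = List::create(
        _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
        _["type"] = IntegerVector(ev_type.begin(), ev_type.end()),
        _["site"] = IntegerVector(ev_site.begin(), ev_site.end()),
        _["row"] = IntegerVector(ev_row.begin(), ev_row.end()),
        _["molecule"] = IntegerVector(ev_mol.begin(), ev_mol.end()));
  }

  return List::create(
      _["t"] = t, _["N"] = N, _["occupancy"] = state_matrix(),
      _["n_molecules"] = n_mols, _["status"] = status,
      _["events"] = events, _["snapshots"] = snaps,
      _["occupancy_time_integral"] = occ_int, _["observed_time"] = obs_time,
      _["n_events"] = n_events);
}
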