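#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Spatial Moran process with exact Doob-Gillespie timing on an L x L torus.
// Site indexing is column-major and 0-based: s = row + L * col, matching R
// matrix layout. Cell types: 1 = producer (P / A), 0 = nonproducer (NP / B).
//
// Variants: 0 = neutral (all rates g0/4, no field), 1 = competition
// (producers pay cost kappa, everyone gains alpha * c from the producer
// field), 2 = mutualism (each type gains alpha * c_other from the field
// produced by the complementary type; both pay kappa).
//
// The resource field(s) are maintained exactly by kernel superposition: a
// type flip at one site adds/subtracts the single-source kernel translated
// to that site. All randomness comes from R's RNG (unif_rand / exp_rand),
// so set.seed() in R makes runs bit-reproducible.

namespace {

struct Lattice {
  int L, N;
  std::vector<int> type;      // 0/1 per site
  std::vector<int> mismatch;  // number of differing cardinal neighbors
  std::vector<int> bpos;      // index into blist, or -1 if interior
  std::vector<int> blist;     // boundary sites (mismatch > 0)
  int np_count;               // number of type-0 cells

  void init(const IntegerMatrix& m) {
    L = m.nrow();
    N = L * L;
    type.assign(m.begin(), m.end());
    mismatch.assign(N, 0);
    bpos.assign(N, -1);
    blist.clear();
    np_count = 0;
    for (int s = 0; s < N; ++s) if (type[s] == 0) ++np_count;
    for (int s = 0; s < N; ++s) {
      mismatch[s] = count_mismatch(s);
      if (mismatch[s] > 0) add_boundary(s);
    }
  }

  inline int row(int s) const { return s % L; }
  inline int col(int s) const { return s / L; }
  inline int neighbor(int s, int k) const {
    int r = s % L, c = s / L;
    switch (k) {
      case 0: r = (r + 1) % L; break;
      case 1: r = (r + L - 1) % L; break;
      case 2: c = (c + 1) % L; break;
      default: c = (c + L - 1) % L; break;
    }
    return r + L * c;
  }
  int count_mismatch(int s) const {
    int t = type[s], n = 0;
    for (int k = 0; k < 4; ++k) if (type[neighbor(s, k)] != t) ++n;
    return n;
  }
  void add_boundary(int s) {
    bpos[s] = (int)blist.size();
    blist.push_back(s);
  }
  void remove_boundary(int s) {
    int pos = bpos[s], last = blist.back();
    blist[pos] = last;
    bpos[last] = pos;
    blist.pop_back();
    bpos[s] = -1;
  }
  void refresh_site(int s) {
    int m = count_mismatch(s);
    mismatch[s] = m;
    if (m > 0 && bpos[s] < 0) add_boundary(s);
    else if (m == 0 && bpos[s] >= 0) remove_boundary(s);
  }
  // Flip the type of site s and update boundary bookkeeping.
  void flip(int s) {
    type[s] = 1 - type[s];
    np_count += (type[s] == 0) ? 1 : -1;
    refresh_site(s);
    for (int k = 0; k < 4; ++k) refresh_site(neighbor(s, k));
  }
};

// field += dir * kernel translated so the kernel origin sits at site s0
void add_kernel(std::vector<double>& field, const NumericMatrix& kernel,
                int s0, double dir, int L) {
  int r0 = s0 % L, c0 = s0 / L;
  for (int c = 0; c < L; ++c) {
    int kc = c - c0; if (kc < 0) kc += L;
    const double* kcol = &kernel(0, kc);
    double* fcol = &field[(size_t)L * c];
    for (int r = 0; r < L; ++r) {
      int kr = r - r0; if (kr < 0) kr += L;
      fcol[r] += dir * kcol[kr];
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(IntegerMatrix types, NumericMatrix kernel,
                 NumericMatrix field_p, NumericMatrix field_b,
                 double g0, double kappa, double alpha, int variant,
                 double max_events, double t_max, double record_stride,
                 IntegerVector snapshot_counts, double snapshot_dt) {
  Lattice lat;
  lat.init(types);
  const int L = lat.L, N = lat.N;

  std::vector<double> fP(field_p.begin(), field_p.end());
  std::vector<double> fB;
  if (variant == 2) fB.assign(field_b.begin(), field_b.end());

  // per-step event storage (at most 4 per boundary site)
  std::vector<int> ev_div, ev_tgt;
  std::vector<double> ev_cum;
  ev_div.reserve(4 * N); ev_tgt.reserve(4 * N); ev_cum.reserve(4 * N);

  // selection-bias accumulators, binned by NP count
  std::vector<double> bias_sum(N + 1, 0.0);
  std::vector<double> bias_n(N + 1, 0.0);

  // trajectory rows: event, time, np_fraction, total_rate, divider_type
  std::vector<double> traj;
  auto record = [&](double ev, double t, double total, double dtype) {
    traj.push_back(ev); traj.push_back(t);
    traj.push_back((double)lat.np_count / N);
    traj.push_back(total); traj.push_back(dtype);
  };

  // snapshots at first passage of given NP counts, plus stroboscopic ones
  std::vector<bool> snap_done(snapshot_counts.size(), false);
  List snaps;
  std::vector<double> snap_time, snap_event, snap_np;
  auto take_snapshot = [&](double t, double ev) {
    IntegerMatrix g(L, L);
    std::copy(lat.type.begin(), lat.type.end(), g.begin());
    snaps.push_back(g);
    snap_time.push_back(t); snap_event.push_back(ev);
    snap_np.push_back((double)lat.np_count / N);
  };
  auto check_count_snapshots = [&](double t, double ev) {
    for (int i = 0; i < snapshot_counts.size(); ++i)
      if (!snap_done[i] && lat.np_count == snapshot_counts[i]) {
        snap_done[i] = true;
        take_snapshot(t, ev);
      }
  };
  double next_strobe = (snapshot_dt > 0) ? 0.0 : R_PosInf;

  auto growth = [&](int s) -> double {
    int t = lat.type[s];
    switch (variant) {
      case 0: return g0;
      case 1: return (t == 1) ? g0 - kappa + alpha * fP[s] : g0 + alpha * fP[s];
      default: return g0 - kappa + alpha * (t == 1 ? fB[s] : fP[s]);
    }
  };

  double time = 0.0, events = 0.0;
  double dtype_last = NA_REAL;
  bool absorbed = (lat.np_count == 0 || lat.np_count == N);
  bool hit_tmax = false;

  check_count_snapshots(0.0, 0.0);

  while (!absorbed && events < max_events && !hit_tmax) {
    // build the event table: one directed event per cross-type adjacency
    ev_div.clear(); ev_tgt.clear(); ev_cum.clear();
    double total = 0.0, np_to_p = 0.0;
    for (int bi = 0; bi < (int)lat.blist.size(); ++bi) {
      int s = lat.blist[bi];
      double g = growth(s);
      if (g <= 0) continue;
      int t = lat.type[s];
      double r4 = g * 0.25;
      for (int k = 0; k < 4; ++k) {
        int nb = lat.neighbor(s, k);
        if (lat.type[nb] != t) {
          total += r4;
          if (t == 0) np_to_p += r4;
          ev_div.push_back(s); ev_tgt.push_back(nb); ev_cum.push_back(total);
        }
      }
    }
    if (events == 0.0) record(0.0, 0.0, total, NA_REAL);
    if (total <= 0.0) break;  // mixed grid but no admissible event (rates 0)

    bias_sum[lat.np_count] += np_to_p / total;
    bias_n[lat.np_count] += 1.0;

    double tau = exp_rand() / total;
    // stroboscopic snapshots of the state that persists until each tick
    while (time + tau >= next_strobe && next_strobe <= t_max) {
      take_snapshot(next_strobe, events);
      next_strobe += snapshot_dt;
    }
    if (time + tau > t_max) { time = t_max; hit_tmax = true; break; }
    time += tau;

    // select the event: inverse CDF on the cumulative-rate array
    double u = unif_rand() * total;
    int lo = 0, hi = (int)ev_cum.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (ev_cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    int tgt = ev_tgt[lo];
    int dtyp = lat.type[ev_div[lo]];
    dtype_last = dtyp;

    // apply: target adopts the divider's type; update fields by superposition
    lat.flip(tgt);
    if (variant == 1) {
      add_kernel(fP, kernel, tgt, dtyp == 1 ? 1.0 : -1.0, L);
    } else if (variant == 2) {
      add_kernel(fP, kernel, tgt, dtyp == 1 ? 1.0 : -1.0, L);
      add_kernel(fB, kernel, tgt, dtyp == 1 ? -1.0 : 1.0, L);
    }
    events += 1.0;
    absorbed = (lat.np_count == 0 || lat.np_count == N);
    check_count_snapshots(time, events);
    long long stride = (long long)record_stride;
    if (stride < 1) stride = 1;
    if ((long long)events % stride == 0 || absorbed)
      record(events, time, total, dtype_last);
    if ((long long)events % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  if (traj.empty() || traj[traj.size() - 5] != events)
    record(events, time, 0.0, dtype_last);

  IntegerMatrix final_grid(L, L);
  std::copy(lat.type.begin(), lat.type.end(), final_grid.begin());
  NumericMatrix out_fp(L, L), out_fb(1, 1);
  std::copy(fP.begin(), fP.end(), out_fp.begin());
  if (variant == 2) {
    out_fb = NumericMatrix(L, L);
    std::copy(fB.begin(), fB.end(), out_fb.begin());
  }

  int nrow = (int)traj.size() / 5;
  NumericMatrix tm(nrow, 5);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < 5; ++j) tm(i, j) = traj[(size_t)5 * i + j];

  return List::create(
    _["grid"] = final_grid,
    _["time"] = time,
    _["event_count"] = events,
    _["absorbed"] = absorbed,
    _["np_count"] = lat.np_count,
    _["trajectory"] = tm,
    _["bias_sum"] = NumericVector(bias_sum.begin(), bias_sum.end()),
    _["bias_n"] = NumericVector(bias_n.begin(), bias_n.end()),
    _["snapshots"] = snaps,
    _["snapshot_time"] = NumericVector(snap_time.begin(), snap_time.end()),
    _["snapshot_event"] = NumericVector(snap_event.begin(), snap_event.end()),
    _["snapshot_np_fraction"] = NumericVector(snap_np.begin(), snap_np.end()),
    _["field"] = out_fp,
    _["field_other"] = out_fb);
}
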