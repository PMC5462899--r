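#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Receptor lookup: uniform cell list over the receptor cluster, 3x3
// neighbourhood scan, nearest free-site receptor wins (lower index on ties).
// ---------------------------------------------------------------------------
struct CellList {
  double x0, y0, cs;
  int nx, ny;
  std::vector<std::vector<int>> cells;

  void build(const std::vector<double>& rx, const std::vector<double>& ry,
             double capture) {
    double xmin = 1e30, xmax = -1e30, ymin = 1e30, ymax = -1e30;
    for (size_t i = 0; i < rx.size(); ++i) {
      xmin = std::min(xmin, rx[i]); xmax = std::max(xmax, rx[i]);
      ymin = std::min(ymin, ry[i]); ymax = std::max(ymax, ry[i]);
    }
    if (rx.empty()) { xmin = ymin = 0; xmax = ymax = 1; }
    x0 = xmin - capture; y0 = ymin - capture;
    double span = std::max(xmax - xmin, ymax - ymin) + 2 * capture;
    cs = std::max(2.0 * capture, span / 64.0);
    nx = std::max(1, (int)std::ceil((xmax + capture - x0) / cs));
    ny = std::max(1, (int)std::ceil((ymax + capture - y0) / cs));
    cells.assign((size_t)nx * ny, {});
    for (size_t i = 0; i < rx.size(); ++i) {
      int cx = std::min(nx - 1, std::max(0, (int)((rx[i] - x0) / cs)));
      int cy = std::min(ny - 1, std::max(0, (int)((ry[i] - y0) / cs)));
      cells[(size_t)cy * nx + cx].push_back((int)i);
    }
  }

  // nearest receptor to (x, y) within `capture` for which pred() is true
  template <typename Pred>
  int nearest(double x, double y, double capture, Pred pred,
              const std::vector<double>& rx,
              const std::vector<double>& ry) const {
    int cx = (int)std::floor((x - x0) / cs);
    int cy = (int)std::floor((y - y0) / cs);
    double best = capture * capture;
    int who = -1;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = cy + dy;
      if (yy < 0 || yy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = cx + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int j : cells[(size_t)yy * nx + xx]) {
          if (!pred(j)) continue;
          double ddx = rx[j] - x, ddy = ry[j] - y;
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 < best) { best = d2; who = j; }
        }
      }
    }
    return who;
  }
};

// ---------------------------------------------------------------------------
// Particle-based trial: vesicular release, 3D diffusion between the
// postsynaptic plane (z = 0, reflective, receptor-bearing) and the
// presynaptic bouton (box resting cleft-width above the plane), stochastic
// receptor gating, absorption at the escape radius.
//
// Step sizes are banded by distance from the binding plane: molecules in
// or near the cleft slab (under the bouton footprint, within 50 nm of
// the plane) use the fine step dt; molecules below 0.25 um use 10 dt;
// below 2 um, 100 dt; beyond, 1000 dt. Binding probabilities are
// calibrated for each tier's step size.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_trial(double bw2, double bd2, double bh, double cleft,
                   double cluster_half, double escape_radius,
                   NumericVector rx_in, NumericVector ry_in, double capture,
                   IntegerVector is_open, IntegerVector nbound,
                   IntegerVector r0_ptr, IntegerVector r0_to,
                   NumericVector r0_rate,
                   IntegerVector k1_ptr, IntegerVector k1_to,
                   NumericVector k1_rate,
                   NumericVector pbind_fine, NumericVector pbind_mid,
                   NumericVector pbind_t2, NumericVector pbind_t3,
                   double D, double dt_fine,
                   NumericVector release_times, int n_per_release,
                   double rel_x, double rel_y, double rel_z,
                   double duration, double sample_dt, int init_state,
                   bool record_events, double seed) {
  Xoshiro rng((uint64_t)seed);
  const int n_states = is_open.size();
  const int n_rec = rx_in.size();
  std::vector<double> rx(rx_in.begin(), rx_in.end());
  std::vector<double> ry(ry_in.begin(), ry_in.end());

  CellList grid;
  grid.build(rx, ry, capture);

  const double tick = 10.0 * dt_fine;
  const long n_ticks = (long)std::ceil(duration / tick - 1e-9);
  const int sample_stride = std::max(1L, (long)std::llround(sample_dt / tick));
  const double esc2 = escape_radius * escape_radius;
  // the fine step is needed where binding happens inside the confined
  // cleft slab (under the bouton, where the half-space crossing-flux
  // calibration would be biased); in open half-space the calibrated
  // coarse step is valid, so the fine band is the bouton footprint plus
  // an approach margin
  const double fine_band_z = 0.05;
  const double fine_x = bw2 + 0.1, fine_y = bd2 + 0.1;
  const double bind_half = cluster_half + capture;
  // gating update cadence: a few ticks keeps the per-step transition
  // probability small (rate * dt << 1) while avoiding per-tick overhead
  const int gate_stride = 5;
  const double gate_dt = gate_stride * tick;

  // per-state totals and per-update gating probabilities
  std::vector<double> r0_tot(n_states, 0.0), k1_tot(n_states, 0.0);
  std::vector<double> p_leave(n_states, 0.0);
  for (int s = 0; s < n_states; ++s) {
    for (int e = r0_ptr[s]; e < r0_ptr[s + 1]; ++e) r0_tot[s] += r0_rate[e];
    for (int e = k1_ptr[s]; e < k1_ptr[s + 1]; ++e) k1_tot[s] += k1_rate[e];
    if (r0_tot[s] > 0) p_leave[s] = -std::expm1(-r0_tot[s] * gate_dt);
  }

  std::vector<int> rstate(n_rec, init_state);
  long n_open = 0, n_bound_mol = 0;

  // molecules (slots are never reused); live molecules sit in one of four
  // step-size tiers by distance from the binding plane
  std::vector<double> mx, my, mz;
  std::vector<int> tier_list[4], incoming[4];
  long n_alive = 0;
  long released = 0, escaped = 0;

  // release schedule as tick indices
  std::vector<long> rel_tick(release_times.size());
  for (int i = 0; i < release_times.size(); ++i)
    rel_tick[i] = (long)std::llround(release_times[i] / tick);

  // output samples
  const long n_samp = n_ticks / sample_stride + 1;
  NumericVector out_t(n_samp);
  IntegerVector out_open(n_samp), out_bound(n_samp), out_free(n_samp),
      out_escaped(n_samp);
  long samp = 0;
  auto record = [&](double t) {
    out_t[samp] = t;
    out_open[samp] = (int)n_open;
    out_bound[samp] = (int)n_bound_mol;
    out_free[samp] = (int)n_alive;
    out_escaped[samp] = (int)escaped;
    ++samp;
  };

  std::vector<double> ev_t;
  std::vector<int> ev_rec, ev_from, ev_to;
  auto log_event = [&](double t, int rec, int from, int to) {
    if (!record_events) return;
    ev_t.push_back(t); ev_rec.push_back(rec + 1);
    ev_from.push_back(from + 1); ev_to.push_back(to + 1);
  };

  auto has_free_site = [&](int j) { return k1_tot[rstate[j]] > 0.0; };

  // advance molecule i by one step of length h; returns false if removed
  auto step = [&](int i, double h, const NumericVector& pbind,
                  double tnow) -> bool {
    const double sg = std::sqrt(2.0 * D * h);
    const double xo = mx[i], yo = my[i], zo = mz[i];
    double x1 = xo + sg * rng.norm();
    double y1 = yo + sg * rng.norm();
    double z1 = zo + sg * rng.norm();

    if (z1 < 0.0) {
      // crossing of the postsynaptic plane: binding attempt at the
      // interpolated crossing point, otherwise reflect
      double frac = zo / (zo - z1);
      double xc = xo + frac * (x1 - xo);
      double yc = yo + frac * (y1 - yo);
      if (n_rec > 0 && std::fabs(xc) <= bind_half &&
          std::fabs(yc) <= bind_half) {
        int j = grid.nearest(xc, yc, capture, has_free_site, rx, ry);
        if (j >= 0) {
          int s = rstate[j];
          if (rng.unif() < pbind[s]) {
            double v = rng.unif() * k1_tot[s];
            int dest = k1_to[k1_ptr[s + 1] - 1];
            double acc = 0.0;
            for (int e = k1_ptr[s]; e < k1_ptr[s + 1]; ++e) {
              acc += k1_rate[e];
              if (v < acc) { dest = k1_to[e]; break; }
            }
            rstate[j] = dest;
            n_open += is_open[dest] - is_open[s];
            n_bound_mol += 1;
            log_event(tnow, j, s, dest);
            return false;        // molecule now bound
          }
        }
      }
      z1 = -z1;
    }

    // presynaptic bouton as an obstacle
    bool under1 = (std::fabs(x1) < bw2 && std::fabs(y1) < bd2);
    if (under1 && z1 > cleft && z1 < cleft + bh) {
      bool under0 = (std::fabs(xo) < bw2 && std::fabs(yo) < bd2);
      if (under0 && zo <= cleft) {
        // bounced off the bouton underside while in the cleft; fold
        // between the two surfaces (no second binding attempt: folding
        // only happens outside the receptor-bearing fine band)
        for (int it = 0; it < 12; ++it) {
          if (z1 > cleft) z1 = 2.0 * cleft - z1;
          else if (z1 < 0.0) z1 = -z1;
          else break;
        }
        if (z1 < 0.0 || z1 > cleft) z1 = 0.5 * cleft;
      } else if (zo >= cleft + bh) {
        z1 = 2.0 * (cleft + bh) - z1;
      } else {
        // lateral entry: reflect off the side wall(s) crossed
        if (std::fabs(xo) >= bw2 && std::fabs(x1) < bw2)
          x1 = (x1 < 0 ? -1.0 : 1.0) * (2.0 * bw2 - std::fabs(x1));
        if (std::fabs(yo) >= bd2 && std::fabs(y1) < bd2)
          y1 = (y1 < 0 ? -1.0 : 1.0) * (2.0 * bd2 - std::fabs(y1));
        if (std::fabs(x1) < bw2 && std::fabs(y1) < bd2 && z1 > cleft &&
            z1 < cleft + bh) {
          x1 = xo; y1 = yo; z1 = zo;   // rare corner case: reject move
        }
      }
    }

    if (x1 * x1 + y1 * y1 + z1 * z1 > esc2) {
      ++escaped;
      return false;
    }
    mx[i] = x1; my[i] = y1; mz[i] = z1;
    return true;
  };

  auto tier_of = [&](int i) {
    double z = mz[i];
    if (z < fine_band_z && std::fabs(mx[i]) < fine_x &&
        std::fabs(my[i]) < fine_y)
      return 0;
    if (z < 0.25) return 1;
    if (z < 2.0) return 2;
    return 3;
  };
  auto spawn = [&](double x, double y, double z) {
    mx.push_back(x); my.push_back(y); mz.push_back(z);
    int i = (int)mx.size() - 1;
    incoming[tier_of(i)].push_back(i);
    ++n_alive;
  };

  record(0.0);
  size_t next_rel = 0;
  for (long k = 0; k < n_ticks; ++k) {
    double t0 = k * tick;
    double t1 = (k + 1) * tick;

    while (next_rel < rel_tick.size() && rel_tick[next_rel] == k) {
      for (int m = 0; m < n_per_release; ++m) spawn(rel_x, rel_y, rel_z);
      released += n_per_release;
      ++next_rel;
    }
    for (int tt = 0; tt < 4; ++tt) {
      if (!incoming[tt].empty()) {
        tier_list[tt].insert(tier_list[tt].end(), incoming[tt].begin(),
                             incoming[tt].end());
        incoming[tt].clear();
      }
    }

    // molecules, coarsest tier first; moved molecules are staged into
    // `incoming` so no molecule steps twice in one tick
    for (int tt = 3; tt >= 0; --tt) {
      if (tt == 2 && (k % 10) != 0) continue;
      if (tt == 3 && (k % 100) != 0) continue;
      std::vector<int>& lst = tier_list[tt];
      for (long a = (long)lst.size() - 1; a >= 0; --a) {
        int i = lst[a];
        bool ok = true;
        if (tt == 0) {
          for (int ss = 0; ss < 10; ++ss) {
            ok = step(i, dt_fine, pbind_fine, t0 + (ss + 1) * dt_fine);
            if (!ok) break;
          }
        } else if (tt == 1) {
          ok = step(i, tick, pbind_mid, t1);
        } else if (tt == 2) {
          ok = step(i, 10.0 * tick, pbind_t2, t1);
        } else {
          ok = step(i, 100.0 * tick, pbind_t3, t1);
        }
        if (!ok) {
          --n_alive;
          lst[a] = lst.back();
          lst.pop_back();
          continue;
        }
        int nt = tier_of(i);
        if (nt != tt) {
          incoming[nt].push_back(i);
          lst[a] = lst.back();
          lst.pop_back();
        }
      }
    }

    // receptor gating (concentration-independent transitions)
    if ((k + 1) % gate_stride == 0) {
      for (int j = 0; j < n_rec; ++j) {
        int s = rstate[j];
        if (p_leave[s] <= 0) continue;
        double u = rng.unif();
        if (u >= p_leave[s]) continue;
        double v = (u / p_leave[s]) * r0_tot[s];
        int dest = r0_to[r0_ptr[s + 1] - 1];
        double acc = 0.0;
        for (int e = r0_ptr[s]; e < r0_ptr[s + 1]; ++e) {
          acc += r0_rate[e];
          if (v < acc) { dest = r0_to[e]; break; }
        }
        int db = nbound[dest] - nbound[s];
        rstate[j] = dest;
        n_open += is_open[dest] - is_open[s];
        log_event(t1, j, s, dest);
        if (db < 0) {
          // unbinding: the released agonist re-enters the cleft just
          // above the receptor
          n_bound_mol -= 1;
          spawn(rx[j], ry[j], 1e-3);
        }
      }
    }

    if ((k + 1) % sample_stride == 0) record(t1);
  }

  IntegerVector rstate_out(n_rec);
  for (int j = 0; j < n_rec; ++j) rstate_out[j] = rstate[j] + 1;

  List events;
  if (record_events)
    events = List::create(_["time"] = wrap(ev_t), _["receptor"] = wrap(ev_rec),
                          _["from"] = wrap(ev_from), _["to"] = wrap(ev_to));
  return List::create(
      _["time"] = out_t[Range(0, samp - 1)],
      _["open"] = out_open[Range(0, samp - 1)],
      _["bound"] = out_bound[Range(0, samp - 1)],
      _["free"] = out_free[Range(0, samp - 1)],
      _["escaped"] = out_escaped[Range(0, samp - 1)],
      _["released"] = (double)released,
      _["receptor_state"] = rstate_out,
      _["events"] = events);
}

// ---------------------------------------------------------------------------
// Well-mixed validation box for the binding-probability calibration:
// closed reflecting box, uniform molecules, receptor disks tiling the
// floor. Bindings are counted but do not consume molecules or sites
// ("ghost" binding), so the concentration stays constant and the observed
// flux can be compared with the mass-action rate k_on * C * N_receptors.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_binding_flux(double box_side, double box_height, int n_mol,
                      NumericVector rx_in, NumericVector ry_in,
                      double capture, double pbind, double D, double dt,
                      int n_steps, double seed) {
  Xoshiro rng((uint64_t)seed);
  std::vector<double> rx(rx_in.begin(), rx_in.end());
  std::vector<double> ry(ry_in.begin(), ry_in.end());
  CellList grid;
  grid.build(rx, ry, capture);
  auto always = [](int) { return true; };

  std::vector<double> x(n_mol), y(n_mol), z(n_mol);
  for (int i = 0; i < n_mol; ++i) {
    x[i] = rng.unif() * box_side;
    y[i] = rng.unif() * box_side;
    z[i] = rng.unif() * box_height;
  }
  const double sg = std::sqrt(2.0 * D * dt);
  long hits = 0;
  auto fold = [](double v, double hi) {
    // reflect into [0, hi]
    for (int it = 0; it < 64; ++it) {
      if (v < 0) v = -v;
      else if (v > hi) v = 2 * hi - v;
      else break;
    }
    return std::min(std::max(v, 0.0), hi);
  };
  for (int k = 0; k < n_steps; ++k) {
    for (int i = 0; i < n_mol; ++i) {
      double x1 = x[i] + sg * rng.norm();
      double y1 = y[i] + sg * rng.norm();
      double z1 = z[i] + sg * rng.norm();
      if (z1 < 0.0) {
        double frac = z[i] / (z[i] - z1);
        double xc = fold(x[i] + frac * (x1 - x[i]), box_side);
        double yc = fold(y[i] + frac * (y1 - y[i]), box_side);
        int j = grid.nearest(xc, yc, capture, always, rx, ry);
        if (j >= 0 && rng.unif() < pbind) ++hits;
      }
      x[i] = fold(x1, box_side);
      y[i] = fold(y1, box_side);
      z[i] = fold(z1, box_height);
    }
  }
  return List::create(_["bindings"] = (double)hits,
                      _["time_ms"] = n_steps * dt);
}

// Per-axis displacement variance after k unobstructed steps, using the
// simulator's own stepping RNG (free-diffusion check: variance = 2 D k dt).
// [[Rcpp::export]]
NumericVector cpp_free_displacement(int n_mol, double D, double dt, int k,
                                    double seed) {
  Xoshiro rng((uint64_t)seed);
  const double sg = std::sqrt(2.0 * D * dt);
  NumericVector dx(n_mol);
  for (int i = 0; i < n_mol; ++i) {
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += sg * rng.norm();
    dx[i] = s;
  }
  return dx;
}
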