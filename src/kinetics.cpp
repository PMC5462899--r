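#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// Exact stochastic simulation (Gillespie) of an ensemble of independent
// channels sharing one gating scheme, aggregated over channel counts per
// state. Rates are piecewise constant in time (concentration segments);
// waiting times are capped at segment boundaries, which is valid by
// memorylessness.
// [[Rcpp::export]]
List cpp_gillespie(int n_states, IntegerVector tr_from, IntegerVector tr_to,
                   NumericVector tr_rate, IntegerVector tr_order,
                   NumericVector seg_start, NumericVector seg_conc,
                   IntegerVector init_counts, NumericVector sample_times,
                   double seed) {
  const int n_tr = tr_from.size();
  const int n_seg = seg_start.size();
  const int n_samp = sample_times.size();
  Xoshiro rng((uint64_t)seed);

  std::vector<long> counts(init_counts.begin(), init_counts.end());
  IntegerMatrix out(n_samp, n_states);

  double t = 0.0;
  int seg = 0;
  int samp = 0;
  std::vector<double> w(n_tr);
  long n_events = 0;

  auto record_until = [&](double tnow) {
    while (samp < n_samp && sample_times[samp] <= tnow + 1e-12) {
      for (int s = 0; s < n_states; ++s) out(samp, s) = (int)counts[s];
      ++samp;
    }
  };

  const double t_end = sample_times[n_samp - 1];
  while (t < t_end) {
    while (seg + 1 < n_seg && seg_start[seg + 1] <= t + 1e-12) ++seg;
    double seg_end = (seg + 1 < n_seg) ? seg_start[seg + 1] : t_end;
    if (seg_end > t_end) seg_end = t_end;
    double conc = seg_conc[seg];
    double R = 0.0;
    for (int j = 0; j < n_tr; ++j) {
      double k = tr_rate[j] * (tr_order[j] == 1 ? conc : 1.0);
      w[j] = k * counts[tr_from[j]];
      R += w[j];
    }
    if (R <= 0.0) {            // frozen chain within this segment
      record_until(seg_end);
      t = seg_end;
      if (seg + 1 >= n_seg && t >= t_end) break;
      continue;
    }
    double dt = rng.rexp(R);
    if (t + dt >= seg_end) {   // cap at boundary, rates change there
      record_until(seg_end);
      t = seg_end;
      continue;
    }
    record_until(t + dt);
    t += dt;
    double u = rng.unif() * R;
    double acc = 0.0;
    int j = n_tr - 1;
    for (int q = 0; q < n_tr; ++q) {
      acc += w[q];
      if (u < acc) { j = q; break; }
    }
    counts[tr_from[j]] -= 1;
    counts[tr_to[j]] += 1;
    ++n_events;
  }
  record_until(t_end);
  return List::create(_["counts"] = out, _["n_events"] = (double)n_events);
}

// Discrete-time stochastic ensemble of channels driven by a spatially
// uniform concentration profile, using the same per-step first-transition
// update as the particle simulator's gating engine: within one step a
// channel leaves its state with probability 1 - exp(-R dt) and picks the
// destination in proportion to the outgoing rates.
// [[Rcpp::export]]
IntegerMatrix cpp_channel_ensemble(int n_states, IntegerVector out_ptr,
                                   IntegerVector out_to,
                                   NumericVector out_rate0,
                                   NumericVector out_rate1,
                                   NumericVector seg_start,
                                   NumericVector seg_conc,
                                   int n_channels, int init_state,
                                   double dt, double duration,
                                   int sample_stride, double seed) {
  Xoshiro rng((uint64_t)seed);
  const int n_ticks = (int)std::ceil(duration / dt - 1e-9);
  const int n_seg = seg_start.size();
  const int n_samp = n_ticks / sample_stride + 1;
  IntegerMatrix out(n_samp, n_states);

  std::vector<int> state(n_channels, init_state);
  std::vector<double> p_leave(n_states);
  std::vector<double> cumw(out_to.size());
  std::vector<double> tot(n_states);

  auto set_segment = [&](double conc) {
    for (int s = 0; s < n_states; ++s) {
      double R = 0.0;
      for (int e = out_ptr[s]; e < out_ptr[s + 1]; ++e) {
        double k = out_rate0[e] + conc * out_rate1[e];
        R += k;
        cumw[e] = R;
      }
      tot[s] = R;
      p_leave[s] = (R > 0) ? -std::expm1(-R * dt) : 0.0;
    }
  };

  int seg = -1;
  out(0, init_state) = n_channels;
  int samp = 1;
  for (int k = 0; k < n_ticks; ++k) {
    double t = k * dt;
    int want = seg;
    while (want + 1 < n_seg && seg_start[want + 1] <= t + 1e-12) ++want;
    if (want != seg || seg < 0) {
      seg = (want < 0) ? 0 : want;
      set_segment(seg_conc[seg]);
    }
    for (int c = 0; c < n_channels; ++c) {
      int s = state[c];
      if (p_leave[s] <= 0) continue;
      double u = rng.unif();
      if (u >= p_leave[s]) continue;
      double v = (u / p_leave[s]) * tot[s];   // u | u < p is uniform
      int dest = out_to[out_ptr[s + 1] - 1];
      for (int e = out_ptr[s]; e < out_ptr[s + 1]; ++e) {
        if (v < cumw[e]) { dest = out_to[e]; break; }
      }
      state[c] = dest;
    }
    if ((k + 1) % sample_stride == 0) {
      for (int c = 0; c < n_channels; ++c) out(samp, state[c]) += 1;
      ++samp;
    }
  }
  return out;
}
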