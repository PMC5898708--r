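#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Self-contained deterministic RNG (xorshift128+ seeded via splitmix64) so
// that per-fiber streams are independent of each other and of R's RNG state.
struct Rng {
  uint64_t s0, s1;
  bool have_cached = false;
  double cached = 0.0;
  Rng() : s0(1), s1(2) {}
  explicit Rng(uint64_t seed) { reseed(seed); }
  void reseed(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    auto mix = [](uint64_t z) {
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    s0 = mix(z);
    z += 0x9E3779B97F4A7C15ULL;
    s1 = mix(z);
    if (s0 == 0 && s1 == 0) s1 = 1;
    have_cached = false;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() { // Box-Muller with caching
    if (have_cached) { have_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2);
    have_cached = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// Leaky integrate-and-fire population driven by a fiber x time drive matrix.
// Membrane update per step: V <- a*V + (1-a)*I (+ membrane noise events).
// Spike when V crosses the refractoriness-elevated, stochastically perturbed
// threshold; V resets, spike emitted at crossing + latency + jitter, kept
// consistent with the per-fiber absolute refractory period.
// [[Rcpp::export]]
List lif_population(NumericMatrix drive, double dt_ms, double tau_m_ms,
                    double threshold, double relative_spread,
                    double abs_ref_mean_ms, double abs_ref_sd_ms,
                    double rel_ref_tau_ms, double rel_ref_strength,
                    double latency_mean_ms, double jitter_sd_ms,
                    double membrane_noise_sd, int seed) {
  const int n_fib = drive.nrow();
  const int n_t = drive.ncol();
  const double a = std::exp(-dt_ms / tau_m_ms);
  const double b = 1.0 - a;
  // threshold perturbation is redrawn after each spike and on a ~1 ms clock,
  // so an isolated pulse sees a single draw (firing-efficiency CV ~ RS)
  const int redraw_steps = std::max(1, (int)std::lround(1.0 / dt_ms));
  // membrane noise is injected as discrete 50 us events with variance-
  // preserving scaling; the membrane (tau >> 50 us) integrates many events,
  // so the voltage statistics match per-step injection
  const int noise_steps = std::max(1, (int)std::lround(0.05 / dt_ms));
  const double noise_scale = std::sqrt((double)noise_steps);

  std::vector<Rng> rng(n_fib);
  std::vector<double> V(n_fib, 0.0), eta(n_fib, 0.0), abs_ref(n_fib),
      t_abs_end(n_fib, -1e30), last_spike(n_fib, -1e30);
  std::vector<int> since_redraw(n_fib, 0);
  std::vector<std::vector<double>> spikes(n_fib);

  for (int f = 0; f < n_fib; ++f) {
    rng[f].reseed((uint64_t)seed * 0x9E3779B9ULL +
                  0x85EBCA6BULL * (uint64_t)(f + 1));
    double ar = abs_ref_mean_ms + abs_ref_sd_ms * rng[f].norm();
    int guard = 0;
    while (ar <= 0.0 && guard++ < 100)
      ar = abs_ref_mean_ms + abs_ref_sd_ms * rng[f].norm();
    abs_ref[f] = ar > 0.0 ? ar : 0.01;
    if (relative_spread > 0) eta[f] = relative_spread * rng[f].norm();
  }

  const double rel_window = 20.0 * rel_ref_tau_ms;
  const double *dp = REAL(drive);
  for (int t = 0; t < n_t; ++t) {
    const double now = t * dt_ms;
    const bool noise_now = membrane_noise_sd > 0 && (t % noise_steps == 0);
    const double *col = dp + (size_t)t * n_fib;
    for (int f = 0; f < n_fib; ++f) {
      if (now < t_abs_end[f]) { V[f] = 0.0; continue; }
      const double I = col[f];
      if (!R_finite(I)) stop("non-finite drive");
      double v = a * V[f] + b * I;
      if (noise_now) v += membrane_noise_sd * noise_scale * rng[f].norm();
      if (++since_redraw[f] >= redraw_steps) {
        eta[f] = relative_spread > 0 ? relative_spread * rng[f].norm() : 0.0;
        since_redraw[f] = 0;
      }
      double thr = threshold * (1.0 + eta[f]);
      if (thr < 0.05 * threshold) thr = 0.05 * threshold;
      const double rel = now - t_abs_end[f];
      if (rel_ref_strength > 0 && rel >= 0 && rel < rel_window)
        thr *= 1.0 + rel_ref_strength * std::exp(-rel / rel_ref_tau_ms);
      if (v >= thr) {
        double t_spike = now + latency_mean_ms;
        if (jitter_sd_ms > 0) t_spike += jitter_sd_ms * rng[f].norm();
        if (t_spike < now) t_spike = now;
        if (t_spike < last_spike[f] + abs_ref[f])
          t_spike = last_spike[f] + abs_ref[f];
        spikes[f].push_back(t_spike);
        last_spike[f] = t_spike;
        v = 0.0;
        t_abs_end[f] = now + abs_ref[f];
        eta[f] = relative_spread > 0 ? relative_spread * rng[f].norm() : 0.0;
        since_redraw[f] = 0;
      }
      V[f] = v;
    }
  }
  List out(n_fib);
  for (int f = 0; f < n_fib; ++f)
    out[f] = NumericVector(spikes[f].begin(), spikes[f].end());
  return out;
}
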