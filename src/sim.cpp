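// Compiled simulation kernels: exact SSA and chemical Langevin integration for
// the four-gene developmental network, and Euler-Maruyama integration for the
// two-dimensional toy SDE. All randomness is drawn from R's RNG so that
// set.seed() in R fully determines every sample path.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Piecewise parameter schedule: mode 0 constant, 1 linear ramp, 2 step.
static inline double sched_at(int mode, double from, double to, double duration,
                              double t) {
  if (mode == 1) {
    if (duration <= 0.0) return to;
    double frac = t / duration;
    if (frac < 0.0) frac = 0.0;
    if (frac > 1.0) frac = 1.0;
    return from + (to - from) * frac;
  }
  if (mode == 2) return (t < duration) ? from : to;
  return from;
}

// Birth propensities a1..a4 of the developmental network. k holds
// [k0..k14, kd]; L is supplied separately (it may be scheduled).
static inline void dev_birth(const double *x, const double *k, double L,
                             double *a) {
  const double N = x[0], O = x[1], F = x[2], G = x[3];
  const double P = k[1] + k[2] * N * N + k[0] * O + k[3] * L;
  const double Q = 1.0 + k[0] * O * (k[2] * N * N + k[0] * O + k[3] * L +
                                     k[4] * F * F) +
                   k[5] * O * G * G;
  a[0] = k[0] * O * P / Q;
  a[1] = (k[6] + k[7] * O) / (1.0 + k[7] * O + k[8] * G * G);
  a[2] = (k[9] + k[10] * O) / (1.0 + k[10] * O);
  a[3] = (k[11] + k[12] * G * G + k[14] * O) /
         (1.0 + k[12] * G * G + k[13] * N * N + k[14] * O);
}

// Exact Gillespie simulation of the developmental network, recorded on a
// uniform output grid. A time-varying L is frozen on a sub-grid of width
// <= 1% of the ramp duration (piecewise-constant propensity approximation):
// the next-reaction time is resampled whenever the sub-grid boundary is
// reached before the sampled event fires.
// [[Rcpp::export]]
List ssa_dev_cpp(NumericVector x0, NumericVector k, double t_end,
                 double record_interval, int smode, double sfrom, double sto,
                 double sduration, double Lconst) {
  const int d = 4;
  double x[4] = {x0[0], x0[1], x0[2], x0[3]};
  const int n_rec = (int)std::floor(t_end / record_interval + 1e-9) + 1;
  NumericMatrix states(n_rec, d);
  NumericVector times(n_rec);
  for (int i = 0; i < n_rec; ++i) times[i] = i * record_interval;
  for (int j = 0; j < d; ++j) states(0, j) = x[j];
  int irec = 1;

  // Sub-grid for freezing a scheduled L between events.
  double sub = R_PosInf;
  if (smode != 0 && sduration > 0.0) sub = sduration / 100.0;

  double kk[16];
  for (int i = 0; i < 16; ++i) kk[i] = k[i];
  const double kd = kk[15];

  double t = 0.0;
  double a[8];
  while (t < t_end) {
    const double L = (smode == 0) ? Lconst : sched_at(smode, sfrom, sto, sduration, t);
    dev_birth(x, kk, L, a);
    a[4] = kd * x[0];
    a[5] = kd * x[1];
    a[6] = kd * x[2];
    a[7] = kd * x[3];
    double a0 = 0.0;
    for (int j = 0; j < 8; ++j) a0 += a[j];

    double boundary = t_end;
    if (R_FINITE(sub)) {
      double nb = (std::floor(t / sub) + 1.0) * sub;
      if (nb < boundary) boundary = nb;
    }

    if (a0 <= 0.0) {
      // No enabled reactions: trajectory legitimately constant to the boundary.
      t = boundary;
      while (irec < n_rec && times[irec] <= t + 1e-12) {
        for (int j = 0; j < d; ++j) states(irec, j) = x[j];
        ++irec;
      }
      if (boundary >= t_end) break;
      continue;
    }

    const double tau = exp_rand() / a0;
    if (t + tau > boundary) {
      t = boundary;
      while (irec < n_rec && times[irec] <= t + 1e-12) {
        for (int j = 0; j < d; ++j) states(irec, j) = x[j];
        ++irec;
      }
      continue;
    }

    const double t_new = t + tau;
    while (irec < n_rec && times[irec] < t_new) {
      for (int j = 0; j < d; ++j) states(irec, j) = x[j];
      ++irec;
    }
    t = t_new;

    double u = unif_rand() * a0;
    int r = 0;
    double cum = a[0];
    while (u > cum && r < 7) cum += a[++r];
    if (r < 4) {
      x[r] += 1.0;
    } else {
      x[r - 4] -= 1.0;
      if (x[r - 4] < 0.0) stop("SSA internal error: negative copy number");
    }
  }
  while (irec < n_rec) {
    for (int j = 0; j < d; ++j) states(irec, j) = x[j];
    ++irec;
  }
  return List::create(_["times"] = times, _["states"] = states);
}

// Chemical Langevin (Euler-Maruyama) integration of the developmental
// network with per-reaction noise amplitude sqrt(a_j). Coordinates are
// clamped at zero after each step; the clamp count is reported.
// [[Rcpp::export]]
List cle_dev_cpp(NumericVector x0, NumericVector k, double t_end, double dt,
                 double record_interval, int smode, double sfrom, double sto,
                 double sduration, double Lconst, bool with_noise) {
  const int d = 4;
  double x[4] = {x0[0], x0[1], x0[2], x0[3]};
  const int n_steps = (int)std::llround(t_end / dt);
  const int rec_every = (int)std::llround(record_interval / dt);
  const int n_rec = n_steps / rec_every + 1;
  NumericMatrix states(n_rec, d);
  NumericVector times(n_rec);
  for (int i = 0; i < n_rec; ++i) times[i] = i * rec_every * dt;
  for (int j = 0; j < d; ++j) states(0, j) = x[j];
  int irec = 1;
  long clamped = 0;

  double kk[16];
  for (int i = 0; i < 16; ++i) kk[i] = k[i];
  const double kd = kk[15];
  const double sqdt = std::sqrt(dt);

  double a[8];
  for (int s = 1; s <= n_steps; ++s) {
    const double t = (s - 1) * dt;
    const double L = (smode == 0) ? Lconst : sched_at(smode, sfrom, sto, sduration, t);
    dev_birth(x, kk, L, a);
    a[4] = kd * x[0];
    a[5] = kd * x[1];
    a[6] = kd * x[2];
    a[7] = kd * x[3];
    for (int j = 0; j < d; ++j) {
      double dx = (a[j] - a[j + 4]) * dt;
      if (with_noise) {
        dx += std::sqrt(a[j]) * sqdt * norm_rand() -
              std::sqrt(a[j + 4]) * sqdt * norm_rand();
      }
      x[j] += dx;
      if (x[j] < 0.0) {
        x[j] = 0.0;
        ++clamped;
      }
      if (!R_FINITE(x[j]))
        stop("CLE integration produced a non-finite state at step %d", s);
    }
    if (s % rec_every == 0) {
      for (int j = 0; j < d; ++j) states(irec, j) = x[j];
      ++irec;
    }
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["clamped"] = (double)clamped);
}

// Euler-Maruyama integration of the toy SDE (drift -grad U + curl, isotropic
// additive noise sigma). beta may be scheduled. drift_scale is a test hook
// (0 suppresses the drift so pure Wiener increments can be checked).
// [[Rcpp::export]]
List em_toy_cpp(NumericVector x0, double alpha, double lambda, double beta,
                double cc, double sigma, double t_end, double dt,
                double record_interval, int smode, double sfrom, double sto,
                double sduration, double drift_scale) {
  double x1 = x0[0], x2 = x0[1];
  const int n_steps = (int)std::llround(t_end / dt);
  const int rec_every = (int)std::llround(record_interval / dt);
  const int n_rec = n_steps / rec_every + 1;
  NumericMatrix states(n_rec, 2);
  NumericVector times(n_rec);
  for (int i = 0; i < n_rec; ++i) times[i] = i * rec_every * dt;
  states(0, 0) = x1;
  states(0, 1) = x2;
  int irec = 1;
  const double sq = sigma * std::sqrt(dt);

  for (int s = 1; s <= n_steps; ++s) {
    const double t = (s - 1) * dt;
    const double b = (smode == 0) ? beta : sched_at(smode, sfrom, sto, sduration, t);
    const double g1 = 2.0 * alpha * x1 - 4.0 * lambda * x1 * x1 * x1 - b;
    const double g2 = -4.0 * lambda * x2 * x2 * x2;
    const double f1 = g1 + cc * (-g2);
    const double f2 = cc * g1 + g2;
    x1 += drift_scale * f1 * dt;
    x2 += drift_scale * f2 * dt;
    if (sigma > 0.0) {
      x1 += sq * norm_rand();
      x2 += sq * norm_rand();
    }
    if (!R_FINITE(x1) || !R_FINITE(x2))
      stop("Euler-Maruyama integration produced a non-finite state at step %d", s);
    if (s % rec_every == 0) {
      states(irec, 0) = x1;
      states(irec, 1) = x2;
      ++irec;
    }
  }
  return List::create(_["times"] = times, _["states"] = states);
}
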