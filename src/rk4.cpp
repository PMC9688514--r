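#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout shared with R/params.R (par_order).
enum Par { BETA, ETA, R_MIN, P1, P2, P3, A_, SMALL_A, XI, EPSILON, LAMBDA,
           THETA, ALPHA, MU, DELTA, R_, B_, GAMMA, VARTHETA, NPAR };

static inline void rhs(double t, const double y[5], double dy[5],
                       const double* p) {
  const double CD = y[0], CT = y[1], CM = y[2], CE = y[3], Tm = y[4];
  const double CF = CD + CT;
  // time-dependent antigen-driven expansion rate
  const double kappa = p[R_MIN] + p[P1] / (1.0 + std::pow(p[P2] * t, p[P3]));
  const double F = Tm / (p[A_] + Tm);                       // antigen saturation
  const double fden = p[VARTHETA] * Tm + p[SMALL_A] + CF;   // kill saturation
  const double f = (fden > 0.0) ? CF / fden : 0.0;

  dy[0] = -(p[BETA] + p[ETA]) * CD;
  dy[1] = p[ETA] * CD + kappa * F * CT - (p[XI] + p[EPSILON] + p[LAMBDA]) * CT
          + p[THETA] * Tm * CM - p[ALPHA] * Tm * CT;
  dy[2] = p[EPSILON] * CT - p[THETA] * Tm * CM - p[MU] * CM;
  dy[3] = p[LAMBDA] * CT - p[DELTA] * CE;
  dy[4] = p[R_] * Tm * (1.0 - p[B_] * Tm) - p[GAMMA] * f * Tm;
}

// Classical RK4 step; returns false on non-finite state.
static inline bool rk4_step(double t, double h, double y[5], const double* p) {
  double k1[5], k2[5], k3[5], k4[5], yt[5];
  rhs(t, y, k1, p);
  for (int i = 0; i < 5; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
  rhs(t + 0.5 * h, yt, k2, p);
  for (int i = 0; i < 5; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
  rhs(t + 0.5 * h, yt, k3, p);
  for (int i = 0; i < 5; ++i) yt[i] = y[i] + h * k3[i];
  rhs(t + h, yt, k4, p);
  for (int i = 0; i < 5; ++i) {
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (!std::isfinite(y[i])) return false;
  }
  return true;
}

// Integrate the five-compartment system on [0, t_end] with fixed step <= dt,
// applying impulsive doses to the distributed compartment at dose_day, and
// recording states at out_times (sorted, within [0, t_end]). Doses applied
// before recording at coincident times. Negative components are clipped to
// zero after each step; the most negative pre-clip excursion relative to the
// running max of each component is returned as a diagnostic.
// [[Rcpp::export]]
List rk4_integrate(NumericVector params, double T0, double t_end, double dt,
                   NumericVector out_times, NumericVector dose_day,
                   NumericVector dose_cells) {
  if (params.size() != NPAR) stop("expected %d parameters, got %d", NPAR,
                                  (int)params.size());
  std::vector<double> p(params.begin(), params.end());

  const int n_out = out_times.size();
  NumericMatrix out(n_out, 5);

  // merged event grid: doses + outputs + t_end
  std::vector<double> events;
  events.reserve(n_out + dose_day.size() + 1);
  for (int i = 0; i < n_out; ++i) events.push_back(out_times[i]);
  for (int i = 0; i < dose_day.size(); ++i) events.push_back(dose_day[i]);
  events.push_back(t_end);
  std::sort(events.begin(), events.end());
  events.erase(std::unique(events.begin(), events.end()), events.end());

  double y[5] = {0.0, 0.0, 0.0, 0.0, T0};
  double runmax[5] = {0.0, 0.0, 0.0, 0.0, T0};
  double worst_neg = 0.0;  // most negative value of (y_i / runmax_i) seen
  double t = 0.0;
  int i_out = 0, i_dose = 0;
  double first_bad = -1.0;

  // events at t = 0: dose first, then record
  size_t i_ev = 0;
  while (i_ev < events.size() && events[i_ev] < 0.0) ++i_ev;

  for (; i_ev < events.size(); ++i_ev) {
    double te = events[i_ev];
    if (te > t && first_bad < 0.0) {
      int nstep = (int)std::ceil((te - t) / dt - 1e-12);
      if (nstep < 1) nstep = 1;
      double h = (te - t) / nstep;
      for (int s = 0; s < nstep; ++s) {
        if (!rk4_step(t + s * h, h, y, p.data())) {
          first_bad = t + (s + 1) * h;
          break;
        }
        for (int i = 0; i < 5; ++i) {
          if (y[i] < 0.0) {
            if (runmax[i] > 0.0 && y[i] / runmax[i] < worst_neg)
              worst_neg = y[i] / runmax[i];
            y[i] = 0.0;
          }
          if (y[i] > runmax[i]) runmax[i] = y[i];
        }
      }
      t = te;
    } else {
      t = te;
    }
    if (first_bad >= 0.0) break;
    while (i_dose < dose_day.size() && dose_day[i_dose] <= t + 1e-12) {
      y[0] += dose_cells[i_dose];
      if (y[0] > runmax[0]) runmax[0] = y[0];
      ++i_dose;
    }
    while (i_out < n_out && out_times[i_out] <= t + 1e-12) {
      for (int i = 0; i < 5; ++i) out(i_out, i) = y[i];
      ++i_out;
    }
  }

  return List::create(_["states"] = out,
                      _["ok"] = first_bad < 0.0,
                      _["first_bad_time"] = first_bad,
                      _["worst_negative_rel"] = worst_neg);
}
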