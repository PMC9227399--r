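#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 core for the two ZA/IPP models. The time grid is built
// on the R side (uniform nodes plus exactly-placed sample and event
// times); here one classic RK4 step is taken per consecutive node pair.
//
// Parameter packing:
//   model 1: kZY kXY kYZ rhoZY kXZ kXG kXGZ lambdaGZ G0      (state Y Z G)
//   model 2: kZY kXY kYZ rhoZY kXZ kXG kXGU lambdaUBG kBUZ kUBG G0 U0
//                                                            (state Y Z G B)
// kG is derived inside from the steady-state relation kG = kXGtot * G0.

static inline void rhs1(const double *s, double *ds, const double *p,
                        double kG) {
  ds[0] = -(p[0] + p[1]) * s[0] + (p[2] / p[3]) * s[1];
  ds[1] = p[3] * p[0] * s[0] - (p[4] + p[2]) * s[1];
  ds[2] = kG - (p[5] + p[6] * std::exp(-p[7] * s[1])) * s[2];
}

static inline void rhs2(const double *s, double *ds, const double *p,
                        double kG) {
  const double U = p[11] - s[3];
  ds[0] = -(p[0] + p[1]) * s[0] + (p[2] / p[3]) * s[1];
  ds[1] = p[3] * p[0] * s[0] - (p[4] + p[2]) * s[1];
  ds[2] = kG - (p[6] * U + p[5]) * s[2];
  ds[3] = p[8] * s[1] * U - p[9] * std::exp(-p[10] * s[2]) * s[3];
}

// [[Rcpp::export(name = ".rk4_traj_cpp")]]
List rk4_traj_cpp(int model, NumericVector params, NumericVector x0,
                  NumericVector t_nodes, bool pulse, double t_star,
                  double ystar_plus) {
  const int d = (model == 1) ? 3 : 4;
  const int n = t_nodes.size();
  if (x0.size() != d) stop("state dimension does not match model");
  const double *p = params.begin();
  const double kGuse = (model == 1) ? (p[5] + p[6]) * p[8]
                                    : (p[6] * p[11] + p[5]) * p[10];

  NumericMatrix out(n, d);
  double s[4], k1[4], k2[4], k3[4], k4[4], tmp[4];
  for (int j = 0; j < d; ++j) s[j] = x0[j];
  for (int j = 0; j < d; ++j) out(0, j) = s[j];

  bool event_done = false;
  double y_pre = NA_REAL;
  // event exactly at t = 0 is not meaningful (t_star > 0 enforced in R)
  for (int i = 0; i < n - 1; ++i) {
    // apply the medium-replacement jump when standing on the event node
    if (pulse && !event_done && std::fabs(t_nodes[i] - t_star) < 1e-9) {
      y_pre = s[0];
      s[0] = ystar_plus;
      for (int j = 0; j < d; ++j) out(i, j) = s[j];
      event_done = true;
    }
    const double h = t_nodes[i + 1] - t_nodes[i];
    if (h <= 0) stop("time grid must be strictly increasing");
    if (model == 1) {
      rhs1(s, k1, p, kGuse);
      for (int j = 0; j < d; ++j) tmp[j] = s[j] + 0.5 * h * k1[j];
      rhs1(tmp, k2, p, kGuse);
      for (int j = 0; j < d; ++j) tmp[j] = s[j] + 0.5 * h * k2[j];
      rhs1(tmp, k3, p, kGuse);
      for (int j = 0; j < d; ++j) tmp[j] = s[j] + h * k3[j];
      rhs1(tmp, k4, p, kGuse);
    } else {
      rhs2(s, k1, p, kGuse);
      for (int j = 0; j < d; ++j) tmp[j] = s[j] + 0.5 * h * k1[j];
      rhs2(tmp, k2, p, kGuse);
      for (int j = 0; j < d; ++j) tmp[j] = s[j] + 0.5 * h * k2[j];
      rhs2(tmp, k3, p, kGuse);
      for (int j = 0; j < d; ++j) tmp[j] = s[j] + h * k3[j];
      rhs2(tmp, k4, p, kGuse);
    }
    for (int j = 0; j < d; ++j) {
      s[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!std::isfinite(s[j]))
        stop("non-finite state at t = %f", t_nodes[i + 1]);
      if (s[j] < 0.0) {
        if (s[j] > -1e-12) s[j] = 0.0;  // round-off guard only
        else stop("state component %d went negative (%e) at t = %f",
                  j + 1, s[j], t_nodes[i + 1]);
      }
    }
    if (model == 2 && s[3] > p[11]) {
      if (s[3] < p[11] + 1e-12) s[3] = p[11];
      else stop("bound enzyme exceeded U0 at t = %f", t_nodes[i + 1]);
    }
    for (int j = 0; j < d; ++j) out(i + 1, j) = s[j];
  }
  // event scheduled on the final node (degenerate but well-defined)
  if (pulse && !event_done && std::fabs(t_nodes[n - 1] - t_star) < 1e-9) {
    y_pre = out(n - 1, 0);
    out(n - 1, 0) = ystar_plus;
    event_done = true;
  }
  return List::create(_["states"] = out, _["y_pre"] = y_pre,
                      _["event_applied"] = event_done);
}
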