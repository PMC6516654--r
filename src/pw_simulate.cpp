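#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Piecewise-analytic propagation of the two-compartment system
//   dA1/dt = r(t) - (cl(t) + CL12) * A1/V1 + CL12 * A2/V2
//   dA2/dt =         CL12 * A1/V1         - CL12 * A2/V2
// with r(t) and cl(t) constant on each piece.  Within a piece the system is
// linear with constant coefficients; it is solved in the eigenbasis of the
// 2x2 rate matrix, whose eigenvalues are always real for a compartmental
// matrix (discriminant (a11-a22)^2 + 4*a12*a21 >= 0).

// phi1(z) = (e^z - 1)/z,  phi2(z) = (e^z - 1 - z)/z^2, with series near 0.
static inline double phi1(double z) {
  if (std::fabs(z) < 1e-5)
    return 1.0 + z / 2.0 + z * z / 6.0 + z * z * z / 24.0;
  return std::expm1(z) / z;
}
static inline double phi2(double z) {
  if (std::fabs(z) < 1e-4)
    return 0.5 + z / 6.0 + z * z / 24.0 + z * z * z / 120.0;
  return (std::expm1(z) - z) / (z * z);
}

struct StepResult {
  double A1, A2, I1; // state after dt and integral of A1 over [0, dt]
};

// Advance (A1, A2) by dt under constant coefficients; also return int A1 dt.
static StepResult advance_piece(double A1, double A2, double dt, double V1,
                                double V2, double CL12, double cl, double r) {
  StepResult out;
  const double a11 = -(cl + CL12) / V1;
  const double a12 = CL12 / V2;
  const double a21 = CL12 / V1;
  const double a22 = -CL12 / V2;
  const double scale =
      std::fabs(a11) + std::fabs(a12) + std::fabs(a21) + std::fabs(a22);

  if (scale * dt < 1e-14) { // no transfer, no elimination: pure infusion
    out.A1 = A1 + r * dt;
    out.A2 = A2;
    out.I1 = A1 * dt + 0.5 * r * dt * dt;
    return out;
  }

  const double tr = a11 + a22;
  const double det = a11 * a22 - a12 * a21;
  double disc = tr * tr - 4.0 * det;
  if (disc < 0.0) disc = 0.0; // guard rounding; analytically >= 0
  const double sq = std::sqrt(disc);
  const double l1 = 0.5 * (tr + sq);
  const double l2 = 0.5 * (tr - sq);

  if (sq > 1e-12 * std::max(1.0, std::fabs(tr))) {
    // eigenvectors: columns of P
    double p11, p21, p12, p22;
    const double tol = 1e-14 * std::max(1.0, scale);
    if (std::fabs(a12) > tol) {
      p11 = a12; p21 = l1 - a11;
      p12 = a12; p22 = l2 - a11;
    } else if (std::fabs(a21) > tol) {
      p11 = l1 - a22; p21 = a21;
      p12 = l2 - a22; p22 = a21;
    } else { // diagonal
      p11 = 1.0; p21 = 0.0;
      p12 = 0.0; p22 = 1.0;
      // order so that column 1 belongs to l1 = a11 or a22
      if (std::fabs(a11 - l1) > std::fabs(a22 - l1)) {
        p11 = 0.0; p21 = 1.0; p12 = 1.0; p22 = 0.0;
      }
    }
    const double dP = p11 * p22 - p12 * p21;
    if (std::fabs(dP) > 1e-300) {
      // y = P^{-1} x, beta = P^{-1} b with b = (r, 0)
      const double y1 = (p22 * A1 - p12 * A2) / dP;
      const double y2 = (-p21 * A1 + p11 * A2) / dP;
      const double b1 = p22 * r / dP;
      const double b2 = -p21 * r / dP;
      const double z1 = l1 * dt, z2 = l2 * dt;
      const double e1 = std::exp(z1), e2 = std::exp(z2);
      const double yt1 = y1 * e1 + b1 * dt * phi1(z1);
      const double yt2 = y2 * e2 + b2 * dt * phi1(z2);
      const double Y1 = y1 * dt * phi1(z1) + b1 * dt * dt * phi2(z1);
      const double Y2 = y2 * dt * phi1(z2) + b2 * dt * dt * phi2(z2);
      out.A1 = p11 * yt1 + p12 * yt2;
      out.A2 = p21 * yt1 + p22 * yt2;
      out.I1 = p11 * Y1 + p12 * Y2;
      return out;
    }
  }

  // defective/near-defective matrix (only reachable in degenerate
  // parameterizations): classical RK4 with fine fixed steps on the
  // augmented state (A1, A2, I1)
  int n = 200;
  const double h = dt / n;
  double x1 = A1, x2 = A2, I = 0.0;
  for (int i = 0; i < n; ++i) {
    const double k11 = r + a11 * x1 + a12 * x2;
    const double k12 = a21 * x1 + a22 * x2;
    const double k13 = x1;
    const double m1 = x1 + 0.5 * h * k11, m2 = x2 + 0.5 * h * k12;
    const double k21 = r + a11 * m1 + a12 * m2;
    const double k22 = a21 * m1 + a22 * m2;
    const double k23 = m1;
    const double n1 = x1 + 0.5 * h * k21, n2 = x2 + 0.5 * h * k22;
    const double k31 = r + a11 * n1 + a12 * n2;
    const double k32 = a21 * n1 + a22 * n2;
    const double k33 = n1;
    const double q1 = x1 + h * k31, q2 = x2 + h * k32;
    const double k41 = r + a11 * q1 + a12 * q2;
    const double k42 = a21 * q1 + a22 * q2;
    const double k43 = q1;
    x1 += h / 6.0 * (k11 + 2 * k21 + 2 * k31 + k41);
    x2 += h / 6.0 * (k12 + 2 * k22 + 2 * k32 + k42);
    I += h / 6.0 * (k13 + 2 * k23 + 2 * k33 + k43);
  }
  out.A1 = x1; out.A2 = x2; out.I1 = I;
  return out;
}

//' @name pw_sim_cpp
//' @title Piecewise-constant two-compartment propagation (internal)
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix pw_sim_cpp(double V1, double V2, double CL12, double cl_body,
                         NumericVector breaks, NumericVector rate,
                         NumericVector cl_dial, NumericVector out_times,
                         NumericVector state0) {
  const int m = rate.size();
  if (breaks.size() != m + 1)
    stop("length(breaks) must equal length(rate) + 1");
  if (cl_dial.size() != m) stop("length(cl_dial) must equal length(rate)");
  const int n_out = out_times.size();
  NumericMatrix out(n_out, 7); // t, A1, A2, auc, elim, dial, infused
  colnames(out) = CharacterVector::create("time", "A1", "A2", "cum_auc",
                                          "cum_elim", "cum_dial", "cum_inf");
  double A1 = state0[0], A2 = state0[1];
  double auc = 0.0, elim = 0.0, dial = 0.0, inf = 0.0;
  int k = 0;
  const double eps = 1e-9;
  for (int j = 0; j < m; ++j) {
    const double t0 = breaks[j], t1 = breaks[j + 1];
    const double cl = cl_body + cl_dial[j];
    // outputs inside (or at the right edge of) this piece
    while (k < n_out && out_times[k] <= t1 + eps) {
      double dt = out_times[k] - t0;
      if (dt < 0.0) dt = 0.0;
      StepResult s = advance_piece(A1, A2, dt, V1, V2, CL12, cl, rate[j]);
      out(k, 0) = out_times[k];
      out(k, 1) = s.A1;
      out(k, 2) = s.A2;
      out(k, 3) = auc + s.I1 / V1;
      out(k, 4) = elim + cl_body * s.I1 / V1;
      out(k, 5) = dial + cl_dial[j] * s.I1 / V1;
      out(k, 6) = inf + rate[j] * dt;
      ++k;
    }
    StepResult s = advance_piece(A1, A2, t1 - t0, V1, V2, CL12, cl, rate[j]);
    A1 = s.A1;
    A2 = s.A2;
    auc += s.I1 / V1;
    elim += cl_body * s.I1 / V1;
    dial += cl_dial[j] * s.I1 / V1;
    inf += rate[j] * (t1 - t0);
  }
  if (k < n_out) stop("output times extend beyond the simulated horizon");
  return out;
}
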