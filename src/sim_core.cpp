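#include <Rcpp.h>
using namespace Rcpp;

// Quasi-static extrusion integrator.
//
// State: internal syringe pressure P (kPa). Per sample of length dt:
//   inflow  Q_in  = plunger_speed * A_syringe            (mm^3/s)
//   outflow Q_out = 0                       if P <= Py
//                 = qc * (P - Py)^(1/n)     otherwise     (mm^3/s)
//   dP/dt = (Q_in - Q_out) / C
// integrated with a backward-Euler step solved by safeguarded Newton
// (Q_out is monotone in P, so the step equation has a unique root).
// qc bundles the power-law Rabinowitsch capillary solution for the excess
// wall stress (P - Py) * r / (2L):
//   qc = pi r^3 * n/(3n+1) * (1000 r / (2 L K))^(1/n)
// pscale applies an instantaneous pressure rescaling at a sample (air
// bubble entering: stored volume conserved while compliance jumps).
//
// [[Rcpp::export]]
List sim_core(NumericVector speed, double dt, double area,
              NumericVector compliance, NumericVector qc,
              double yield_pressure, double inv_n,
              NumericVector pscale, double density) {
  int n = speed.size();
  NumericVector pressure(n), outflow(n), mass(n);
  double P = 0.0, m = 0.0;
  for (int i = 0; i < n; ++i) {
    P *= pscale[i];
    double C = compliance[i];
    double q = qc[i];
    double Qin = speed[i] * area;
    double Pnf = P + dt * Qin / C;  // no-outflow candidate
    double Qo = 0.0;
    if (q <= 0.0 || Pnf <= yield_pressure) {
      P = Pnf > 0.0 ? Pnf : 0.0;
    } else {
      double lo = yield_pressure, hi = Pnf;
      double x = P > lo ? (P < hi ? P : hi) : 0.5 * (lo + hi);
      for (int it = 0; it < 100; ++it) {
        double excess = x - yield_pressure;
        double Qx = q * std::pow(excess, inv_n);
        double g = x - Pnf + dt * Qx / C;
        if (g > 0.0) hi = x; else lo = x;
        double dg = 1.0 + (excess > 0.0
                             ? dt * q * inv_n * std::pow(excess, inv_n - 1.0) / C
                             : 0.0);
        double step = g / dg;
        double xn = x - step;
        if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);
        if (std::fabs(xn - x) < 1e-12 * (1.0 + std::fabs(x))) { x = xn; break; }
        x = xn;
        if (hi - lo < 1e-13 * (1.0 + hi)) break;
      }
      P = x;
      double excess = P - yield_pressure;
      Qo = excess > 0.0 ? q * std::pow(excess, inv_n) : 0.0;
    }
    m += density * Qo * dt;
    pressure[i] = P;
    outflow[i] = Qo;
    mass[i] = m;
  }
  return List::create(_["pressure"] = pressure, _["outflow"] = outflow,
                      _["extruded_mass"] = mass);
}
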