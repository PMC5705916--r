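// Compiled right-hand sides and adaptive Cash-Karp RK4(5) integrator.
//
// State layout (fixed): 0 Ec, 1 Rp, 2 G, 3 A, 4 C, 5 F, 6 E, 7 H.
// Parameter vector layout must match .params_to_vector() on the R side.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static const int NS = 8;
static const double UNIT_CONV = 1e-9;

enum ParIdx {
  P_MU_E_MAX = 0, P_K_G, P_K_A, P_K_AR, P_MU_R_MAX1, P_MU_R_MAX2, P_K_C,
  P_R_A, P_Y_EG, P_Y_EA, P_Y_RC, P_Y_RA, P_M_G, P_F_C, P_F_F, P_F_E,
  P_PHI_H, P_K_I, P_N_I, P_V_FIX, NPAR
};

static inline double monod(double s, double K) { return s / (K + s); }

static void rhs(const double *y, const double *p, bool communal, double *dy) {
  const double Ec = y[0], Rp = y[1], G = y[2], A = y[3], C = y[4], Fo = y[5];

  const double I = 1.0 / (1.0 + std::pow((C + Fo) / p[P_K_I], p[P_N_I]));
  const double mG = monod(G, p[P_K_G]);
  const double mC = monod(C, p[P_K_C]);

  const double mu_E = p[P_MU_E_MAX] * mG * monod(A, p[P_K_A]) * I;
  const double q_G = mu_E / p[P_Y_EG] + p[P_M_G] * UNIT_CONV * mG * I;

  if (!communal) {
    const double mu_R1 = p[P_MU_R_MAX1] * mC * I;
    const double mu_R2 = p[P_MU_R_MAX2] * mC * monod(A, p[P_K_AR]) * I;
    const double mu_R = mu_R1 + mu_R2;
    dy[0] = mu_E * Ec;
    dy[1] = mu_R * Rp;
    dy[2] = -q_G * Ec;
    dy[3] = p[P_R_A] * UNIT_CONV * mu_R1 * Rp - (mu_E / p[P_Y_EA]) * Ec -
            (mu_R2 / p[P_Y_RA]) * Rp;
    dy[4] = p[P_F_C] * q_G * Ec - (mu_R / p[P_Y_RC]) * Rp;
    dy[5] = p[P_F_F] * q_G * Ec;
    dy[6] = p[P_F_E] * q_G * Ec;
    dy[7] = p[P_PHI_H] * UNIT_CONV * mu_R1 * Rp;
  } else {
    const double mu_R = (p[P_MU_R_MAX1] + p[P_MU_R_MAX2]) * mC *
                        monod(A, p[P_K_AR]) * I;
    const double fix = p[P_V_FIX] * UNIT_CONV * mC * I * Rp;
    dy[0] = mu_E * Ec;
    dy[1] = mu_R * Rp;
    dy[2] = -q_G * Ec;
    dy[3] = fix - (mu_E / p[P_Y_EA]) * Ec - (mu_R / p[P_Y_RA]) * Rp;
    dy[4] = p[P_F_C] * q_G * Ec - (mu_R / p[P_Y_RC]) * Rp;
    dy[5] = p[P_F_F] * q_G * Ec;
    dy[6] = p[P_F_E] * q_G * Ec;
    dy[7] = p[P_PHI_H] * UNIT_CONV * mC * I * Rp;
  }
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(NumericVector y, NumericVector pvec, bool communal) {
  if (y.size() != NS) stop("state vector must have length 8");
  if (pvec.size() != NPAR) stop("parameter vector must have length 20");
  NumericVector dy(NS);
  rhs(&y[0], &pvec[0], communal, &dy[0]);
  dy.names() = CharacterVector::create("Ec", "Rp", "G", "A", "C", "F", "E", "H");
  return dy;
}

// Cash-Karp embedded Runge-Kutta coefficients.
static const double b21 = 1.0 / 5.0;
static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
                    b54 = 35.0 / 27.0;
static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                    b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                    b65 = 253.0 / 4096.0;
static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
                    c6 = 512.0 / 1771.0;
static const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
                    dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
                    dc6 = c6 - 1.0 / 4.0;

// Integrate from times[0] to times[n-1], recording the state at every grid
// time. Adaptive step-size control on the embedded 4th/5th-order error;
// tiny negative undershoots are clamped to zero and counted.
// [[Rcpp::export(name = ".integrate_cpp")]]
List integrate_cpp(NumericVector y0, NumericVector pvec, bool communal,
                   NumericVector times, double rtol, double atol_cells,
                   double atol_conc, double max_steps) {
  if (y0.size() != NS) stop("initial state must have length 8");
  if (pvec.size() != NPAR) stop("parameter vector must have length 20");
  const int nt = times.size();
  if (nt < 2) stop("need at least two output times");
  for (int i = 1; i < nt; ++i) {
    if (!(times[i] > times[i - 1])) stop("output times must strictly increase");
  }

  NumericMatrix out(nt, NS);
  double y[NS], ytmp[NS], yerr[NS], ynew[NS];
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS];
  double atol[NS];
  for (int j = 0; j < NS; ++j) {
    y[j] = y0[j];
    atol[j] = (j < 2) ? atol_cells : atol_conc;
    out(0, j) = y[j];
  }

  const double *p = &pvec[0];
  double t = times[0];
  double h = (times[nt - 1] - times[0]) / 100.0;  // cautious initial step
  const double hmin = 1e-12;
  long nsteps = 0, nreject = 0, nclamp = 0;
  int iout = 1;
  std::string err;

  while (iout < nt) {
    const double tnext = times[iout];
    if (h > tnext - t) h = tnext - t;
    if (h < hmin) h = hmin;

    rhs(y, p, communal, k1);
    for (int j = 0; j < NS; ++j) ytmp[j] = y[j] + h * b21 * k1[j];
    rhs(ytmp, p, communal, k2);
    for (int j = 0; j < NS; ++j)
      ytmp[j] = y[j] + h * (b31 * k1[j] + b32 * k2[j]);
    rhs(ytmp, p, communal, k3);
    for (int j = 0; j < NS; ++j)
      ytmp[j] = y[j] + h * (b41 * k1[j] + b42 * k2[j] + b43 * k3[j]);
    rhs(ytmp, p, communal, k4);
    for (int j = 0; j < NS; ++j)
      ytmp[j] = y[j] + h * (b51 * k1[j] + b52 * k2[j] + b53 * k3[j] +
                            b54 * k4[j]);
    rhs(ytmp, p, communal, k5);
    for (int j = 0; j < NS; ++j)
      ytmp[j] = y[j] + h * (b61 * k1[j] + b62 * k2[j] + b63 * k3[j] +
                            b64 * k4[j] + b65 * k5[j]);
    rhs(ytmp, p, communal, k6);

    double errmax = 0.0;
    for (int j = 0; j < NS; ++j) {
      ynew[j] = y[j] + h * (c1 * k1[j] + c3 * k3[j] + c4 * k4[j] + c6 * k6[j]);
      yerr[j] = h * (dc1 * k1[j] + dc3 * k3[j] + dc4 * k4[j] + dc5 * k5[j] +
                     dc6 * k6[j]);
      const double sc = atol[j] + rtol * std::max(std::fabs(y[j]),
                                                  std::fabs(ynew[j]));
      const double e = std::fabs(yerr[j]) / sc;
      if (e > errmax) errmax = e;
    }

    if (++nsteps > max_steps) {
      err = "step budget exhausted (" + std::to_string((long)max_steps) +
            " steps) at t=" + std::to_string(t);
      break;
    }

    if (errmax <= 1.0 || h <= hmin * 2) {
      // accept; clamp small negative undershoots to the admissible region
      t += h;
      for (int j = 0; j < NS; ++j) {
        if (ynew[j] < 0.0) {
          ynew[j] = 0.0;
          ++nclamp;
        }
        y[j] = ynew[j];
      }
      while (iout < nt && t >= times[iout] - 1e-12) {
        for (int j = 0; j < NS; ++j) out(iout, j) = y[j];
        ++iout;
      }
      // step-size growth, capped at 5x
      double fac = (errmax > 0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      ++nreject;
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < hmin) {
        err = "step size underflow at t=" + std::to_string(t);
        break;
      }
    }
  }

  return List::create(
    _["states"] = out,
    _["steps"] = (double)nsteps,
    _["rejected"] = (double)nreject,
    _["clamped"] = (double)nclamp,
    _["completed"] = (iout >= nt),
    _["message"] = err);
}
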