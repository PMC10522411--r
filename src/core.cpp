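// Compiled core: model right-hand side, analytic Jacobian, an L-stable
// Rosenbrock 4(3) integrator with steady-state event detection, and the
// Nelder-Mead restart used by the allocation optimizer.
//
// Fixed layouts shared with the R level (see R/dynamics.R):
//   state  x: a k c n e_Kre e_Kex e_C e_Af e_Ar e_N r z          (12)
//   alloc  f: f_Kre f_Kex f_C f_Af f_Ar f_N f_R f_Z              (8)
//   flux   j: j_Kre j_Kex j_C j_Af j_Ar j_N j_R                  (7)
//   params p: a_sat k_sat c_sat n_sat k_Kre k_Kex k_C k_Af k_Ar
//             k_N k_R alpha_Cf alpha_Cr gamma_K f_Z              (15)

#include <Rcpp.h>
#include <cmath>
#include <cfloat>
#include <cstring>

using namespace Rcpp;

static const int NX = 12;
static const int NF = 8;
static const int NJ = 7;
static const int NP = 15;

// parameter indices
enum { P_ASAT, P_KSAT, P_CSAT, P_NSAT, P_KKRE, P_KKEX, P_KC, P_KAF,
       P_KAR, P_KN, P_KR, P_ACF, P_ACR, P_GK, P_FZ };

// ---------------------------------------------------------------------------
// fluxes and growth rate

static inline void cg_fluxes_c(const double* x, const double* p, double* j) {
  const double sk = x[1] / (x[1] + p[P_KSAT]);
  const double sc = x[2] / (x[2] + p[P_CSAT]);
  const double sn = x[3] / (x[3] + p[P_NSAT]);
  const double sa = x[0] / (x[0] + p[P_ASAT]);
  j[0] = p[P_KKRE] * x[4] * sk;
  j[1] = p[P_KKEX] * x[5] * sk;
  j[2] = p[P_KC]   * x[6];
  j[3] = p[P_KAF]  * x[7] * sc * sn;
  j[4] = p[P_KAR]  * x[8] * sc * sn;
  j[5] = p[P_KN]   * x[9];
  j[6] = p[P_KR]   * x[10] * sa;
}

static inline double cg_mu_c(const double* j) {
  return j[2] + j[5] - j[1];
}

// Regulated allocation: f_R follows the amino-acid pool, metabolic
// fractions of the base allocation are rescaled to keep sum(f) = 1.
// Returns false when rescaling is impossible.
static bool regulated_alloc(double a, const double* basef, double fZ,
                            double delta, double a0, double* f) {
  double fR = delta * (a - a0);
  const double fRmax = 1.0 - fZ;
  if (fR < 0.0) fR = 0.0;
  if (fR > fRmax) fR = fRmax;
  double s = 0.0;
  for (int i = 0; i < 6; ++i) s += basef[i];
  const double budget = 1.0 - fZ - fR;
  if (s <= 0.0) {
    if (budget > 1e-12) return false;
    for (int i = 0; i < 6; ++i) f[i] = 0.0;
  } else {
    for (int i = 0; i < 6; ++i) f[i] = basef[i] * budget / s;
  }
  f[6] = fR;
  f[7] = fZ;
  return true;
}

// rhs; returns false on non-finite input/output (used to reject steps)
static bool cg_rhs_c(const double* x, const double* f, const double* p,
                     double* dx) {
  double j[NJ];
  cg_fluxes_c(x, p, j);
  for (int l = 0; l < NJ; ++l) if (!std::isfinite(j[l])) return false;
  const double mu  = cg_mu_c(j);
  const double gK  = p[P_GK];
  const double aCf = p[P_ACF], aCr = p[P_ACR];
  dx[0] = j[3] + j[4] - j[6] - mu * x[0];
  dx[1] = gK * j[5] - j[0] - j[1] - mu * x[1];
  dx[2] = j[2] + j[0] - aCf * j[3] - aCr * j[4] - mu * x[2];
  dx[3] = (1.0 - gK) * j[5] - (1.0 - aCf) * j[3] - (1.0 - aCr) * j[4]
          - mu * x[3];
  for (int i = 4; i < NX; ++i) dx[i] = f[i - 4] * j[6] - mu * x[i];
  for (int i = 0; i < NX; ++i) if (!std::isfinite(dx[i])) return false;
  return true;
}

struct RhsSpec {
  const double* p;
  bool regulated;
  const double* f;      // fixed allocation (non-regulated)
  const double* basef;  // base allocation (regulated)
  double delta, a0;
};

// evaluates rhs under either fixed or regulated allocation; fills fbuf with
// the allocation actually used
static bool eval_rhs(const RhsSpec& s, const double* x, double* dx,
                     double* fbuf) {
  if (s.regulated) {
    if (!regulated_alloc(x[0], s.basef, s.p[P_FZ], s.delta, s.a0, fbuf))
      return false;
  } else {
    std::memcpy(fbuf, s.f, NF * sizeof(double));
  }
  return cg_rhs_c(x, fbuf, s.p, dx);
}

// ---------------------------------------------------------------------------
// analytic Jacobian of the rhs
//
// dx = S(f) j(x) - mu(x) x, so J = S * dj/dx - mu I - x (dmu/dx)^T.
// In regulated mode f depends on a = x[0]; only the protein rows pick up
// the extra term (df_i/da) j_R on the first column (zero inside clamps).

static void cg_jac_c(const RhsSpec& s, const double* x, double* J /*12x12*/) {
  const double* p = s.p;
  double f[NF];
  if (s.regulated) {
    regulated_alloc(x[0], s.basef, p[P_FZ], s.delta, s.a0, f);
  } else {
    std::memcpy(f, s.f, NF * sizeof(double));
  }
  double j[NJ];
  cg_fluxes_c(x, p, j);
  const double mu = cg_mu_c(j);

  // saturation terms and their derivatives
  const double dk = x[1] + p[P_KSAT], dc = x[2] + p[P_CSAT];
  const double dn = x[3] + p[P_NSAT], da = x[0] + p[P_ASAT];
  const double sk = x[1] / dk, sc = x[2] / dc, sn = x[3] / dn, sa = x[0] / da;
  const double skp = p[P_KSAT] / (dk * dk);
  const double scp = p[P_CSAT] / (dc * dc);
  const double snp = p[P_NSAT] / (dn * dn);
  const double sap = p[P_ASAT] / (da * da);

  // dj/dx, 7 x 12, sparse
  double Jj[NJ][NX];
  std::memset(Jj, 0, sizeof(Jj));
  Jj[0][4]  = p[P_KKRE] * sk;  Jj[0][1] = p[P_KKRE] * x[4] * skp;
  Jj[1][5]  = p[P_KKEX] * sk;  Jj[1][1] = p[P_KKEX] * x[5] * skp;
  Jj[2][6]  = p[P_KC];
  Jj[3][7]  = p[P_KAF] * sc * sn;
  Jj[3][2]  = p[P_KAF] * x[7] * scp * sn;
  Jj[3][3]  = p[P_KAF] * x[7] * sc * snp;
  Jj[4][8]  = p[P_KAR] * sc * sn;
  Jj[4][2]  = p[P_KAR] * x[8] * scp * sn;
  Jj[4][3]  = p[P_KAR] * x[8] * sc * snp;
  Jj[5][9]  = p[P_KN];
  Jj[6][10] = p[P_KR] * sa;    Jj[6][0] = p[P_KR] * x[10] * sap;

  // dmu/dx = row(j_C) + row(j_N) - row(j_Kex)
  double gmu[NX];
  for (int q = 0; q < NX; ++q) gmu[q] = Jj[2][q] + Jj[5][q] - Jj[1][q];

  // stoichiometry matrix S(f), 12 x 7
  double S[NX][NJ];
  std::memset(S, 0, sizeof(S));
  const double gK = p[P_GK], aCf = p[P_ACF], aCr = p[P_ACR];
  S[0][3] = 1.0;  S[0][4] = 1.0;  S[0][6] = -1.0;
  S[1][0] = -1.0; S[1][1] = -1.0; S[1][5] = gK;
  S[2][0] = 1.0;  S[2][2] = 1.0;  S[2][3] = -aCf; S[2][4] = -aCr;
  S[3][3] = -(1.0 - aCf); S[3][4] = -(1.0 - aCr); S[3][5] = 1.0 - gK;
  for (int i = 4; i < NX; ++i) S[i][6] = f[i - 4];

  for (int i = 0; i < NX; ++i)
    for (int q = 0; q < NX; ++q) {
      double v = 0.0;
      for (int l = 0; l < NJ; ++l) v += S[i][l] * Jj[l][q];
      v -= x[i] * gmu[q];
      if (i == q) v -= mu;
      J[i * NX + q] = v;
    }

  if (s.regulated) {
    // df/da is nonzero between the clamps of f_R = delta (a - a0)
    const double fR = s.delta * (x[0] - s.a0);
    if (fR > 0.0 && fR < 1.0 - p[P_FZ]) {
      double sb = 0.0;
      for (int i = 0; i < 6; ++i) sb += s.basef[i];
      if (sb > 0.0) {
        for (int i = 4; i < NX; ++i) {
          double dfda;
          if (i == 10)      dfda = s.delta;                       // ribosome
          else if (i == 11) dfda = 0.0;                           // housekeeping
          else              dfda = -s.delta * s.basef[i - 4] / sb;
          J[i * NX + 0] += dfda * j[6];
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// dense LU with partial pivoting (n = 12)

static bool ludcmp(double* A, int n, int* piv) {
  for (int k = 0; k < n; ++k) {
    int pk = k;
    double amax = std::fabs(A[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(A[i * n + k]);
      if (v > amax) { amax = v; pk = i; }
    }
    if (amax < 1e-300) return false;
    piv[k] = pk;
    if (pk != k)
      for (int q = 0; q < n; ++q) std::swap(A[k * n + q], A[pk * n + q]);
    const double d = 1.0 / A[k * n + k];
    for (int i = k + 1; i < n; ++i) {
      const double m = A[i * n + k] * d;
      A[i * n + k] = m;
      if (m != 0.0)
        for (int q = k + 1; q < n; ++q) A[i * n + q] -= m * A[k * n + q];
    }
  }
  return true;
}

static void lubksb(const double* A, int n, const int* piv, double* b) {
  // forward substitution in gather form: entries stay untouched until
  // their position is processed, so the successive row interchanges of
  // the factorization apply cleanly
  for (int i = 0; i < n; ++i) {
    double sum = b[piv[i]];
    b[piv[i]] = b[i];
    for (int q = 0; q < i; ++q) sum -= A[i * n + q] * b[q];
    b[i] = sum;
  }
  for (int i = n - 1; i >= 0; --i) {
    for (int q = i + 1; q < n; ++q) b[i] -= A[i * n + q] * b[q];
    b[i] /= A[i * n + i];
  }
}

// ---------------------------------------------------------------------------
// Rosenbrock 4(3), Kaps-Rentrop with Shampine's parameter set (L-stable,
// embedded third-order error estimate; autonomous form).

static const double GAM = 0.5;
static const double A21 = 2.0, A31 = 48.0 / 25.0, A32 = 6.0 / 25.0;
static const double C21 = -8.0, C31 = 372.0 / 25.0, C32 = 12.0 / 5.0;
static const double C41 = -112.0 / 125.0, C42 = -54.0 / 125.0,
                    C43 = -2.0 / 5.0;
static const double B1 = 19.0 / 9.0, B2 = 0.5, B3 = 25.0 / 108.0,
                    B4 = 125.0 / 108.0;
static const double E1 = 17.0 / 54.0, E2 = 7.0 / 36.0, E3 = 0.0,
                    E4 = 125.0 / 108.0;

struct SolveOpts {
  double rtol, atol, ss_tol, t_max, h0;
  int max_steps;
  bool detect_ss;   // stop at the steady-state residual criterion
  // integrator undershoot below zero is clipped when smaller than this
  // (componentwise error is controlled to ~atol, so undershoots of that
  // order are expected for pools decaying to zero); larger negativity is
  // a convergence failure
  double neg_tol() const { return std::max(1e-12, 10.0 * atol); }
};

struct SolveOut {
  double x[NX];
  double t;
  int steps;
  int status;       // 0 converged; 1 budget exhausted; 2 negativity;
                    // 3 numerical failure; 4 infeasible regulated allocation
  double residual;  // max_i |dx_i| / max(|x_i|, 1e-8) at the final state
  int newton_attempts, newton_hit;
};

static double ss_residual(const double* x, const double* dx) {
  double r = 0.0;
  for (int i = 0; i < NX; ++i) {
    const double v = std::fabs(dx[i]) / std::max(std::fabs(x[i]), 1e-8);
    if (v > r) r = v;
  }
  return r;
}

// Newton polish on the steady-state equations.  Near the growth optimum
// the fixed point can be a slowly decaying spiral, where time stepping
// alone needs very long horizons to satisfy the residual criterion;
// once the trajectory is close, Newton converges quadratically.  The
// attempt is conservative: it bails out (returning false, state
// untouched) on large steps, negative components or non-decreasing
// residuals, in which case integration simply continues.
static bool newton_polish(const RhsSpec& spec, const double* y_in,
                          double ss_tol, double neg_tol, double* y_out,
                          double* res_out) {
  double y[NX], dy[NX], fbuf[NF], J[NX * NX], step[NX];
  int piv[NX];
  std::memcpy(y, y_in, sizeof(y));
  if (!eval_rhs(spec, y, dy, fbuf)) return false;
  double res = ss_residual(y, dy);
  for (int it = 0; it < 25; ++it) {
    if (res < ss_tol) {
      std::memcpy(y_out, y, NX * sizeof(double));
      *res_out = res;
      return true;
    }
    cg_jac_c(spec, y, J);
    if (!ludcmp(J, NX, piv)) return false;
    for (int i = 0; i < NX; ++i) step[i] = -dy[i];
    lubksb(J, NX, piv, step);
    double stepmax = 0.0;
    for (int i = 0; i < NX; ++i)
      stepmax = std::max(stepmax, std::fabs(step[i]));
    if (stepmax > 0.5 || !std::isfinite(stepmax)) return false;
    // damped: fall back to half and quarter steps before giving up
    bool moved = false;
    for (double lam = 1.0; lam >= 0.24 && !moved; lam *= 0.5) {
      double ynew[NX];
      bool ok = true;
      for (int i = 0; i < NX; ++i) {
        ynew[i] = y[i] + lam * step[i];
        if (ynew[i] < 0.0) {
          if (ynew[i] > -neg_tol) ynew[i] = 0.0;
          else { ok = false; break; }
        }
      }
      if (!ok) continue;
      double dynew[NX];
      if (!eval_rhs(spec, ynew, dynew, fbuf)) continue;
      const double resnew = ss_residual(ynew, dynew);
      if (resnew < res || resnew < ss_tol) {
        std::memcpy(y, ynew, sizeof(y));
        std::memcpy(dy, dynew, sizeof(dy));
        res = resnew;
        moved = true;
      }
    }
    if (!moved) return false;
  }
  if (res < ss_tol) {
    std::memcpy(y_out, y, NX * sizeof(double));
    *res_out = res;
    return true;
  }
  return false;
}

static void integrate(const RhsSpec& spec, const double* x0,
                      const SolveOpts& o, SolveOut& out) {
  double y[NX], dy[NX], fbuf[NF];
  std::memcpy(y, x0, sizeof(y));
  double t = 0.0, h = o.h0;
  out.status = 1;
  out.steps = 0;
  out.residual = NA_REAL;
  out.newton_attempts = 0;
  out.newton_hit = -1;

  if (!eval_rhs(spec, y, dy, fbuf)) {
    out.status = spec.regulated ? 4 : 3;
    std::memcpy(out.x, y, sizeof(out.x));
    out.t = t;
    return;
  }
  out.residual = ss_residual(y, dy);
  if (o.detect_ss && out.residual < o.ss_tol) out.status = 0;

  double J[NX * NX], M[NX * NX];
  int piv[NX];
  double g1[NX], g2[NX], g3[NX], g4[NX], rhs[NX], ytmp[NX], ynew[NX],
      err[NX], dynew[NX];

  while (out.status == 1 && out.steps < o.max_steps && t < o.t_max) {
    if (t + h > o.t_max) h = o.t_max - t;
    cg_jac_c(spec, y, J);
    bool accepted = false;
    int tries = 0;
    while (!accepted && tries < 60) {
      ++tries;
      const double gh = 1.0 / (GAM * h);
      for (int i = 0; i < NX * NX; ++i) M[i] = -J[i];
      for (int i = 0; i < NX; ++i) M[i * NX + i] += gh;
      if (!ludcmp(M, NX, piv)) { h *= 0.5; continue; }

      // stage 1
      for (int i = 0; i < NX; ++i) g1[i] = dy[i];
      lubksb(M, NX, piv, g1);
      // stage 2
      for (int i = 0; i < NX; ++i) ytmp[i] = y[i] + A21 * g1[i];
      if (!eval_rhs(spec, ytmp, rhs, fbuf)) { h *= 0.5; continue; }
      for (int i = 0; i < NX; ++i) g2[i] = rhs[i] + C21 * g1[i] / h;
      lubksb(M, NX, piv, g2);
      // stage 3
      for (int i = 0; i < NX; ++i)
        ytmp[i] = y[i] + A31 * g1[i] + A32 * g2[i];
      if (!eval_rhs(spec, ytmp, rhs, fbuf)) { h *= 0.5; continue; }
      for (int i = 0; i < NX; ++i)
        g3[i] = rhs[i] + (C31 * g1[i] + C32 * g2[i]) / h;
      lubksb(M, NX, piv, g3);
      // stage 4 reuses the stage-3 function value
      for (int i = 0; i < NX; ++i)
        g4[i] = rhs[i] + (C41 * g1[i] + C42 * g2[i] + C43 * g3[i]) / h;
      lubksb(M, NX, piv, g4);

      double errnorm = 0.0;
      for (int i = 0; i < NX; ++i) {
        ynew[i] = y[i] + B1 * g1[i] + B2 * g2[i] + B3 * g3[i] + B4 * g4[i];
        err[i]  = E1 * g1[i] + E2 * g2[i] + E3 * g3[i] + E4 * g4[i];
        const double sc =
            o.atol + o.rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        const double e = std::fabs(err[i]) / sc;
        if (e > errnorm) errnorm = e;
      }
      bool finite = true;
      for (int i = 0; i < NX; ++i)
        if (!std::isfinite(ynew[i])) { finite = false; break; }
      if (!finite || !std::isfinite(errnorm)) { h *= 0.5; continue; }

      if (errnorm <= 1.0) {
        // integrator undershoot below zero: clip tiny, fail on larger
        for (int i = 0; i < NX; ++i) {
          if (ynew[i] < 0.0) {
            if (ynew[i] > -o.neg_tol()) ynew[i] = 0.0;
            else { out.status = 2; break; }
          }
        }
        if (out.status == 2) break;
        if (!eval_rhs(spec, ynew, dynew, fbuf)) {
          out.status = spec.regulated ? 4 : 3;
          break;
        }
        t += h;
        ++out.steps;
        std::memcpy(y, ynew, sizeof(y));
        std::memcpy(dy, dynew, sizeof(dy));
        out.residual = ss_residual(y, dy);
        if (o.detect_ss && out.residual < o.ss_tol) out.status = 0;
        // attempt a Newton jump to the fixed point: cheap to try (a
        // failed attempt bails after one Jacobian solve), so probe
        // periodically even before the residual is small
        if (out.status == 1 && o.detect_ss && out.residual < 0.05 &&
            (out.residual < 1e-4 || out.steps % 5 == 0)) {
          double ypol[NX], respol;
          ++out.newton_attempts;
          if (newton_polish(spec, y, o.ss_tol, o.neg_tol(), ypol, &respol)) {
            // reject a polish that lands on the degenerate washout state
            // unless the trajectory itself was already settled
            double jpol[NJ];
            cg_fluxes_c(ypol, spec.p, jpol);
            if (cg_mu_c(jpol) > 0.0 || out.residual < 1e-6) {
              std::memcpy(y, ypol, sizeof(y));
              out.residual = respol;
              out.status = 0;
              out.newton_hit = out.steps;
            }
          }
        }
        accepted = true;
        double fac = 0.9 * std::pow(errnorm, -0.25);
        if (fac > 5.0) fac = 5.0;
        if (fac < 1.0) fac = 1.0;
        h *= fac;
      } else {
        double fac = 0.9 * std::pow(errnorm, -1.0 / 3.0);
        if (fac < 0.1) fac = 0.1;
        if (fac > 0.5) fac = 0.5;
        h *= fac;
        if (h < 1e-14) { out.status = 3; break; }
      }
    }
    if (!accepted && out.status == 1) { out.status = 3; }
    if (out.status != 1 && out.status != 0) break;
    if (out.status == 0) break;
  }

  std::memcpy(out.x, y, sizeof(out.x));
  out.t = t;
}

// ---------------------------------------------------------------------------
// exported wrappers

static void check_len(const NumericVector& v, int n, const char* what) {
  if (v.size() != n) stop("%s must have length %d", what, n);
}

// [[Rcpp::export]]
NumericVector cg_fluxes_cpp(NumericVector x, NumericVector p) {
  check_len(x, NX, "x"); check_len(p, NP, "p");
  NumericVector j(NJ);
  cg_fluxes_c(REAL(x), REAL(p), REAL(j));
  return j;
}

// [[Rcpp::export]]
NumericVector cg_rhs_cpp(NumericVector x, NumericVector f, NumericVector p) {
  check_len(x, NX, "x"); check_len(f, NF, "f"); check_len(p, NP, "p");
  NumericVector dx(NX);
  if (!cg_rhs_c(REAL(x), REAL(f), REAL(p), REAL(dx)))
    stop("non-finite right-hand side");
  return dx;
}

// [[Rcpp::export]]
NumericVector cg_rhs_regulated_cpp(NumericVector x, NumericVector basef,
                                   NumericVector p, double delta, double a0) {
  check_len(x, NX, "x"); check_len(basef, NF, "basef"); check_len(p, NP, "p");
  double f[NF], dx[NX];
  if (!regulated_alloc(x[0], REAL(basef), p[P_FZ], delta, a0, f))
    stop("regulated allocation infeasible: all metabolic base fractions are zero while f_R + f_Z < 1");
  if (!cg_rhs_c(REAL(x), f, REAL(p), dx))
    stop("non-finite right-hand side");
  return NumericVector(dx, dx + NX);
}

// [[Rcpp::export]]
NumericVector cg_regulated_alloc_cpp(double a, NumericVector basef,
                                     double fZ, double delta, double a0) {
  check_len(basef, NF, "basef");
  double f[NF];
  if (!regulated_alloc(a, REAL(basef), fZ, delta, a0, f))
    stop("regulated allocation infeasible: all metabolic base fractions are zero while f_R + f_Z < 1");
  return NumericVector(f, f + NF);
}

// [[Rcpp::export]]
NumericMatrix cg_jac_cpp(NumericVector x, NumericVector f, NumericVector p) {
  check_len(x, NX, "x"); check_len(f, NF, "f"); check_len(p, NP, "p");
  RhsSpec spec; spec.p = REAL(p); spec.regulated = false; spec.f = REAL(f);
  spec.basef = NULL; spec.delta = 0; spec.a0 = 0;
  double J[NX * NX];
  cg_jac_c(spec, REAL(x), J);
  NumericMatrix out(NX, NX);
  for (int i = 0; i < NX; ++i)
    for (int q = 0; q < NX; ++q) out(i, q) = J[i * NX + q];
  return out;
}

static List solve_common(const RhsSpec& spec, NumericVector x0, double rtol,
                         double atol, double ss_tol, double t_max,
                         int max_steps, bool detect_ss, double h0) {
  SolveOpts o;
  o.rtol = rtol; o.atol = atol; o.ss_tol = ss_tol; o.t_max = t_max;
  o.max_steps = max_steps; o.detect_ss = detect_ss; o.h0 = h0;
  SolveOut out;
  integrate(spec, REAL(x0), o, out);
  NumericVector xss(out.x, out.x + NX);
  double j[NJ];
  cg_fluxes_c(out.x, spec.p, j);
  const double mu = cg_mu_c(j);
  return List::create(
      _["x"] = xss, _["mu"] = mu, _["t"] = out.t, _["steps"] = out.steps,
      _["status"] = out.status, _["residual"] = out.residual,
      _["converged"] = (out.status == 0),
      _["newton_attempts"] = out.newton_attempts,
      _["newton_hit"] = out.newton_hit);
}

// [[Rcpp::export]]
List cg_solve_cpp(NumericVector x0, NumericVector f, NumericVector p,
                  double rtol, double atol, double ss_tol, double t_max,
                  int max_steps, bool detect_ss, double h0) {
  check_len(x0, NX, "x0"); check_len(f, NF, "f"); check_len(p, NP, "p");
  RhsSpec spec; spec.p = REAL(p); spec.regulated = false; spec.f = REAL(f);
  spec.basef = NULL; spec.delta = 0; spec.a0 = 0;
  return solve_common(spec, x0, rtol, atol, ss_tol, t_max, max_steps,
                      detect_ss, h0);
}

// [[Rcpp::export]]
List cg_solve_regulated_cpp(NumericVector x0, NumericVector basef,
                            NumericVector p, double delta, double a0,
                            double rtol, double atol, double ss_tol,
                            double t_max, int max_steps, bool detect_ss,
                            double h0) {
  check_len(x0, NX, "x0"); check_len(basef, NF, "basef"); check_len(p, NP, "p");
  RhsSpec spec; spec.p = REAL(p); spec.regulated = true; spec.f = NULL;
  spec.basef = REAL(basef); spec.delta = delta; spec.a0 = a0;
  return solve_common(spec, x0, rtol, atol, ss_tol, t_max, max_steps,
                      detect_ss, h0);
}

// [[Rcpp::export]]
List cg_newton_cpp(NumericVector x, NumericVector f, NumericVector p,
                   double ss_tol) {
  check_len(x, NX, "x"); check_len(f, NF, "f"); check_len(p, NP, "p");
  RhsSpec spec; spec.p = REAL(p); spec.regulated = false; spec.f = REAL(f);
  spec.basef = NULL; spec.delta = 0; spec.a0 = 0;
  double ypol[NX], respol = NA_REAL;
  bool ok = newton_polish(spec, REAL(x), ss_tol, 1e-11, ypol, &respol);
  return List::create(_["ok"] = ok,
                      _["x"] = NumericVector(ypol, ypol + NX),
                      _["residual"] = respol);
}

// ---------------------------------------------------------------------------
// growth-rate objective and Nelder-Mead restart
//
// The optimized coordinates are the non-fixed allocation entries; f_Z is
// held at its parameter value and f_R is eliminated through the allocation
// constraint.  Any infeasibility maps to the penalty 1/eps so the simplex
// can recover (the optimizer minimizes the doubling time ln 2 / mu).

struct Objective {
  const double* p;
  const int* free_idx;   // 0-based indices into the allocation vector
  int nfree;
  bool k0_zero;
  SolveOpts solver;
  mutable long evals;

  double penalty() const { return 1.0 / DBL_EPSILON; }

  // builds the full allocation; returns false if infeasible
  bool build_f(const double* v, double* f) const {
    for (int i = 0; i < NF; ++i) f[i] = 0.0;
    f[7] = p[P_FZ];
    double s = p[P_FZ];
    for (int i = 0; i < nfree; ++i) {
      if (v[i] < 0.0) return false;
      f[free_idx[i]] = v[i];
      s += v[i];
    }
    f[6] = 1.0 - s;                      // residual: ribosomal fraction
    if (f[6] < 0.0) return false;
    return true;
  }

  double value(const double* v, double* mu_out) const {
    ++evals;
    if (mu_out) *mu_out = NA_REAL;
    double f[NF];
    if (!build_f(v, f)) return penalty();
    if (f[6] <= 0.0) return penalty();            // no ribosome, no growth
    if (f[3] <= 0.0 && f[4] <= 0.0) return penalty();  // no amino-acid path
    // always integrate from the standard initial condition: reusing the
    // previous steady state as a warm start is faster but can hand the
    // Newton polish a saddle of the flow when consecutive trial
    // allocations straddle a basin boundary
    double x0[NX];
    x0[0] = 0.05; x0[1] = k0_zero ? 0.0 : 0.05; x0[2] = 0.05; x0[3] = 0.05;
    for (int i = 4; i < NX; ++i) x0[i] = 0.8 * f[i - 4];
    RhsSpec spec; spec.p = p; spec.regulated = false; spec.f = f;
    spec.basef = NULL; spec.delta = 0; spec.a0 = 0;
    SolveOut out;
    integrate(spec, x0, solver, out);
    if (out.status != 0) return penalty();
    double j[NJ];
    cg_fluxes_c(out.x, p, j);
    const double mu = cg_mu_c(j);
    if (!(mu > 0.0)) return penalty();
    if (mu_out) *mu_out = mu;
    return M_LN2 / mu;
  }
};

// [[Rcpp::export]]
List cg_restart_cpp(NumericVector p, IntegerVector free_idx,
                    NumericVector start, bool k0_zero, double nm_tol,
                    int nm_max_iter, double simplex_a, double simplex_b,
                    double rtol, double atol, double ss_tol, double t_max,
                    int max_steps) {
  check_len(p, NP, "p");
  if (free_idx.size() != start.size())
    stop("free_idx and start must have equal length");
  const int n = free_idx.size();

  Objective obj;
  obj.p = REAL(p);
  obj.free_idx = INTEGER(free_idx);
  obj.nfree = n;
  obj.k0_zero = k0_zero;
  obj.solver.rtol = rtol; obj.solver.atol = atol; obj.solver.ss_tol = ss_tol;
  obj.solver.t_max = t_max; obj.solver.max_steps = max_steps;
  obj.solver.detect_ss = true; obj.solver.h0 = 1e-5;
  obj.evals = 0;

  std::vector<double> best(n);
  double fbest;
  bool nm_converged = false;
  int iters = 0;

  if (n == 0) {
    fbest = obj.value(NULL, NULL);
    nm_converged = true;
  } else {
    // simplex: vertex 0 at the start, vertex i displaces coordinate i-1 by
    // a + b * x_i (affine simplexer)
    const int nv = n + 1;
    std::vector<std::vector<double> > vx(nv, std::vector<double>(n));
    std::vector<double> vf(nv);
    for (int i = 0; i < n; ++i) vx[0][i] = start[i];
    for (int v = 1; v < nv; ++v) {
      vx[v] = vx[0];
      vx[v][v - 1] += simplex_a + simplex_b * vx[0][v - 1];
    }
    for (int v = 0; v < nv; ++v) vf[v] = obj.value(vx[v].data(), NULL);

    std::vector<double> cen(n), xr(n), xe(n), xc(n);
    for (iters = 0; iters < nm_max_iter; ++iters) {
      // order: lo = best, hi = worst, nh = next worst
      int lo = 0, hi = 0;
      for (int v = 1; v < nv; ++v) {
        if (vf[v] < vf[lo]) lo = v;
        if (vf[v] > vf[hi]) hi = v;
      }
      int nh = lo;
      for (int v = 0; v < nv; ++v)
        if (v != hi && vf[v] > vf[nh]) nh = v;

      const double frange = vf[hi] - vf[lo];
      double dia = 0.0;
      for (int v = 0; v < nv; ++v)
        for (int i = 0; i < n; ++i)
          dia = std::max(dia, std::fabs(vx[v][i] - vx[lo][i]));
      if (frange <= nm_tol * (std::fabs(vf[lo]) + nm_tol) || dia <= nm_tol) {
        nm_converged = true;
        break;
      }

      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int v = 0; v < nv; ++v) if (v != hi) s += vx[v][i];
        cen[i] = s / n;
      }
      for (int i = 0; i < n; ++i) xr[i] = cen[i] + (cen[i] - vx[hi][i]);
      const double fr = obj.value(xr.data(), NULL);
      if (fr < vf[lo]) {
        for (int i = 0; i < n; ++i) xe[i] = cen[i] + 2.0 * (cen[i] - vx[hi][i]);
        const double fe = obj.value(xe.data(), NULL);
        if (fe < fr) { vx[hi] = xe; vf[hi] = fe; }
        else         { vx[hi] = xr; vf[hi] = fr; }
      } else if (fr < vf[nh]) {
        vx[hi] = xr; vf[hi] = fr;
      } else {
        const bool outside = fr < vf[hi];
        if (outside)
          for (int i = 0; i < n; ++i) xc[i] = cen[i] + 0.5 * (xr[i] - cen[i]);
        else
          for (int i = 0; i < n; ++i)
            xc[i] = cen[i] + 0.5 * (vx[hi][i] - cen[i]);
        const double fc = obj.value(xc.data(), NULL);
        if (fc < std::min(fr, vf[hi])) {
          vx[hi] = xc; vf[hi] = fc;
        } else {
          // shrink towards the best vertex
          for (int v = 0; v < nv; ++v) {
            if (v == lo) continue;
            for (int i = 0; i < n; ++i)
              vx[v][i] = vx[lo][i] + 0.5 * (vx[v][i] - vx[lo][i]);
            vf[v] = obj.value(vx[v].data(), NULL);
          }
        }
      }
    }
    int lo = 0;
    for (int v = 1; v < nv; ++v) if (vf[v] < vf[lo]) lo = v;
    best = vx[lo];
    fbest = vf[lo];
  }

  // re-evaluate the best point to recover mu and the full allocation
  double mu = NA_REAL, fvec[NF];
  bool feasible = false;
  if (fbest < 0.5 / DBL_EPSILON) {
    obj.value(best.data(), &mu);
    obj.build_f(best.data(), fvec);
    feasible = R_finite(mu) && mu > 0.0;
  } else {
    for (int i = 0; i < NF; ++i) fvec[i] = NA_REAL;
  }

  return List::create(
      _["f"] = NumericVector(fvec, fvec + NF), _["mu"] = mu,
      _["td"] = fbest, _["feasible"] = feasible,
      _["nm_converged"] = nm_converged, _["iterations"] = iters,
      _["evaluations"] = (double)obj.evals);
}
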