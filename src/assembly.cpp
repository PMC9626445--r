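// Element kernels for the coupled Lagrangian biphasic growth problem.
//
// Unknowns per node: displacement u (3), fluid pressure p, nutrient
// concentration c. Cellwise frozen fields per time level: growth stretch g,
// solid fraction phi_s, tumour indicator chi, spectral data of the initial
// diffusion tensor, anisotropy weights a1/a2.
//
// One-point (barycentre) quadrature on P1 tetrahedra: all gradients are
// constant per element; mass-type terms use the barycentre value with the
// shape-function average 1/4.
//
// The consistent tangent is obtained numerically: central finite differences
// of the element residual for the displacement columns (so no fourth-order
// elasticity tensor is hand-coded) and exact analytic columns for the
// pressure and concentration dofs, which enter the residual linearly.

#include <RcppArmadillo.h>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

struct Pars {
  double mu1t, mu2t, kt, mu1h, mu2h, kh;
  double k0, alpha0, mHM, phisn;
  double zeta, Sn, dt;
};

static Pars unpack(const Rcpp::NumericVector& par) {
  Pars P;
  P.mu1t = par["mu1_t"]; P.mu2t = par["mu2_t"]; P.kt = par["kappa_t"];
  P.mu1h = par["mu1_h"]; P.mu2h = par["mu2_h"]; P.kh = par["kappa_h"];
  P.k0 = par["k0"]; P.alpha0 = par["alpha0"]; P.mHM = par["m"];
  P.phisn = par["phi_sn"]; P.zeta = par["zeta"]; P.Sn = par["S_n"];
  P.dt = par["dt"];
  return P;
}

// 3x3 dense (column-major: m[col*3 + row]) helpers
static inline double det3(const double* F) {
  return F[0] * (F[4] * F[8] - F[7] * F[5]) -
         F[3] * (F[1] * F[8] - F[7] * F[2]) +
         F[6] * (F[1] * F[5] - F[4] * F[2]);
}
static inline void inv3(const double* F, double J, double* Fi) {
  Fi[0] = (F[4] * F[8] - F[7] * F[5]) / J;
  Fi[1] = -(F[1] * F[8] - F[7] * F[2]) / J;
  Fi[2] = (F[1] * F[5] - F[4] * F[2]) / J;
  Fi[3] = -(F[3] * F[8] - F[6] * F[5]) / J;
  Fi[4] = (F[0] * F[8] - F[6] * F[2]) / J;
  Fi[5] = -(F[0] * F[5] - F[3] * F[2]) / J;
  Fi[6] = (F[3] * F[7] - F[6] * F[4]) / J;
  Fi[7] = -(F[0] * F[7] - F[6] * F[1]) / J;
  Fi[8] = (F[0] * F[4] - F[3] * F[1]) / J;
}
static inline void matvec3(const double* A, const double* x, double* y) {
  y[0] = A[0] * x[0] + A[3] * x[1] + A[6] * x[2];
  y[1] = A[1] * x[0] + A[4] * x[1] + A[7] * x[2];
  y[2] = A[2] * x[0] + A[5] * x[1] + A[8] * x[2];
}
static inline void matTvec3(const double* A, const double* x, double* y) {
  y[0] = A[0] * x[0] + A[1] * x[1] + A[2] * x[2];
  y[1] = A[3] * x[0] + A[4] * x[1] + A[5] * x[2];
  y[2] = A[6] * x[0] + A[7] * x[1] + A[8] * x[2];
}
static inline void matmul3(const double* A, const double* B, double* C) {
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      C[c * 3 + r] = A[r] * B[c * 3] + A[3 + r] * B[c * 3 + 1] +
                     A[6 + r] * B[c * 3 + 2];
}
// C = A * B * A^T for symmetric B (general A); result symmetric
static inline void congruence(const double* A, const double* B, double* C) {
  double T[9];
  matmul3(A, B, T);            // T = A*B
  double At[9] = {A[0], A[3], A[6], A[1], A[4], A[7], A[2], A[5], A[8]};
  matmul3(T, At, C);           // C = A*B*A^T
}

static inline double holmes_mow(double Je, const Pars& P) {
  return P.k0 * std::pow((Je - P.phisn) / (1.0 - P.phisn), P.alpha0) *
         std::exp(P.mHM * (Je * Je - 1.0) / 2.0);
}

struct ElemFixed {
  double G[12];       // shape gradients, node-major xyz: G[a*3+d]
  double V, g, phis, chi, Jsk, stab;
  double cek[4];      // previous-level nodal concentrations
  double lam[3];
  double evec[9];     // eigenvector columns e_i = evec + 3*i
  double a1, a2;
};

// Geometry-dependent intermediates shared by the residual and the analytic
// pressure/concentration columns.
struct Kin {
  double J, Je, kJe;
  double Fi[9];       // F^{-1}
  double Ts[9];       // blended Cauchy stress
  double Km[9];       // K*/mu = J k Fi A Fi^T
  double Dstar[9];    // J Fi D Fi^T
  double D[9], A[9];  // reoriented spatial tensors
};

static bool kinematics(const ElemFixed& E, const double* ue, const Pars& P,
                       Kin& K) {
  double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  // Grad u = sum_a u_a (x) gradN_a
  for (int a = 0; a < 4; ++a)
    for (int d = 0; d < 3; ++d)
      for (int i = 0; i < 3; ++i)
        F[d * 3 + i] += ue[a * 3 + i] * E.G[a * 3 + d];
  double J = det3(F);
  if (J <= 0) return false;
  double g3 = E.g * E.g * E.g;
  double Je = J / g3;
  if (Je <= P.phisn) return false;
  inv3(F, J, K.Fi);
  K.J = J; K.Je = Je;
  K.kJe = holmes_mow(Je, P);

  // Bbar = J^{-2/3} F F^T (the unimodular elastic left Cauchy-Green tensor;
  // the growth stretch cancels between F_e = F/g and J_e = J/g^3)
  double s = std::pow(J, -2.0 / 3.0);
  double Bb[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      Bb[c * 3 + r] = s * (F[r] * F[c] + F[3 + r] * F[3 + c] +
                           F[6 + r] * F[6 + c]);
  double I1 = Bb[0] + Bb[4] + Bb[8];
  double B2[9];
  matmul3(Bb, Bb, B2);
  double mu1 = E.chi * P.mu1t + (1 - E.chi) * P.mu1h;
  double mu2 = E.chi * P.mu2t + (1 - E.chi) * P.mu2h;
  double kap = E.chi * P.kt + (1 - E.chi) * P.kh;
  double dr[9];
  for (int k = 0; k < 9; ++k)
    dr[k] = 0.5 * mu1 * Bb[k] + 0.5 * mu2 * (I1 * Bb[k] - B2[k]);
  double trdr = (dr[0] + dr[4] + dr[8]) / 3.0;
  double tvol = kap * std::log(Je) / Je;
  for (int k = 0; k < 9; ++k) K.Ts[k] = (2.0 / Je) * dr[k];
  K.Ts[0] += tvol - (2.0 / Je) * trdr;
  K.Ts[4] += tvol - (2.0 / Je) * trdr;
  K.Ts[8] += tvol - (2.0 / Je) * trdr;

  // reoriented diffusion / preferential-direction tensors
  double D[9] = {0}, Ah[9] = {0};
  const double w[3] = {E.a1, E.a2, 1.0};
  for (int i = 0; i < 3; ++i) {
    double fi[3];
    matvec3(F, E.evec + 3 * i, fi);
    double n2 = fi[0] * fi[0] + fi[1] * fi[1] + fi[2] * fi[2];
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) {
        double o = fi[r] * fi[c] / n2;
        D[c * 3 + r] += E.lam[i] * o;
        Ah[c * 3 + r] += w[i] * E.lam[i] * o;
      }
  }
  double trA = Ah[0] + Ah[4] + Ah[8];
  for (int k = 0; k < 9; ++k) K.A[k] = 3.0 * Ah[k] / trA;
  for (int k = 0; k < 9; ++k) K.D[k] = D[k];
  double tmp[9];
  congruence(K.Fi, K.A, tmp);
  for (int k = 0; k < 9; ++k) K.Km[k] = J * K.kJe * tmp[k];
  congruence(K.Fi, D, tmp);
  for (int k = 0; k < 9; ++k) K.Dstar[k] = J * tmp[k];
  return true;
}

static bool element_residual(const ElemFixed& E, const double* ue,
                             const double* pe, const double* ce,
                             const Pars& P, double* R, Kin* kout = nullptr) {
  Kin K;
  if (!kinematics(E, ue, P, K)) return false;
  double pbar = 0.25 * (pe[0] + pe[1] + pe[2] + pe[3]);
  // total first Piola-Kirchhoff stress P = J (T - p I) F^{-T}
  double TmP[9];
  for (int k = 0; k < 9; ++k) TmP[k] = K.Ts[k];
  TmP[0] -= pbar; TmP[4] -= pbar; TmP[8] -= pbar;
  double FiT[9] = {K.Fi[0], K.Fi[3], K.Fi[6], K.Fi[1], K.Fi[4], K.Fi[7],
                   K.Fi[2], K.Fi[5], K.Fi[8]};
  double Ptot[9];
  matmul3(TmP, FiT, Ptot);
  for (int k = 0; k < 9; ++k) Ptot[k] *= K.J;

  double gradp[3] = {0, 0, 0}, gradc[3] = {0, 0, 0};
  for (int a = 0; a < 4; ++a)
    for (int d = 0; d < 3; ++d) {
      gradp[d] += pe[a] * E.G[a * 3 + d];
      gradc[d] += ce[a] * E.G[a * 3 + d];
    }
  double Kgp[3];
  matvec3(K.Km, gradp, Kgp);
  double Dgc[3];
  matvec3(K.Dstar, gradc, Dgc);
  double phl = 1.0 - E.phis;
  double adv = (Kgp[0] * gradc[0] + Kgp[1] * gradc[1] + Kgp[2] * gradc[2]) / phl;

  for (int a = 0; a < 4; ++a) {
    const double* ga = E.G + 3 * a;
    for (int i = 0; i < 3; ++i)
      R[3 * a + i] = E.V * (Ptot[i] * ga[0] + Ptot[3 + i] * ga[1] +
                            Ptot[6 + i] * ga[2]);
    R[12 + a] = E.V * ((K.J - E.Jsk) * 0.25 +
                       P.dt * (ga[0] * Kgp[0] + ga[1] * Kgp[1] +
                               ga[2] * Kgp[2]) +
                       P.dt * E.stab * (ga[0] * gradp[0] + ga[1] * gradp[1] +
                                        ga[2] * gradp[2]));
    // reaction and storage terms evaluated nodewise (lumped quadrature:
    // monotone for the stiff consumption/supply reaction)
    double srca = (-P.zeta * E.phis * ce[a] + P.Sn * (1.0 - ce[a])) * E.chi;
    R[16 + a] = E.V * (K.J * (ce[a] - E.cek[a]) * 0.25 -
                       P.dt * adv * 0.25 +
                       P.dt * (ga[0] * Dgc[0] + ga[1] * Dgc[1] +
                               ga[2] * Dgc[2]) -
                       P.dt * K.J * srca * 0.25);
  }
  if (kout) *kout = K;
  return true;
}

// Analytic tangent columns for the pressure and concentration dofs (the
// residual is linear in both). Fills columns 12..19 of the 20x20 local
// tangent Jloc (column-major, Jloc[j*20+i]).
static void linear_columns(const ElemFixed& E, const Kin& K,
                           const double* gradp, const double* gradc,
                           const Pars& P, double* Jloc) {
  double phl = 1.0 - E.phis;
  double Kgp[3];
  matvec3(K.Km, gradp, Kgp);
  for (int b = 0; b < 4; ++b) {
    const double* gb = E.G + 3 * b;
    double Kgb[3], Dgb[3];
    matvec3(K.Km, gb, Kgb);
    matvec3(K.Dstar, gb, Dgb);
    // column for p_b
    double* colp = Jloc + (12 + b) * 20;
    for (int a = 0; a < 4; ++a) {
      const double* ga = E.G + 3 * a;
      // d(Ru_a)/dp_b : P contributes -J pbar F^{-T}; dpbar/dp_b = 1/4
      for (int i = 0; i < 3; ++i)
        colp[3 * a + i] = -E.V * K.J * 0.25 *
          (K.Fi[i * 3 + 0] * ga[0] + K.Fi[i * 3 + 1] * ga[1] +
           K.Fi[i * 3 + 2] * ga[2]);  // (F^{-T})_{id} = Fi[d*? ] see below
      colp[12 + a] = E.V * P.dt *
        ((ga[0] * Kgb[0] + ga[1] * Kgb[1] + ga[2] * Kgb[2]) +
         E.stab * (ga[0] * gb[0] + ga[1] * gb[1] + ga[2] * gb[2]));
      colp[16 + a] = -E.V * P.dt * 0.25 *
        (Kgb[0] * gradc[0] + Kgb[1] * gradc[1] + Kgb[2] * gradc[2]) / phl;
    }
    // column for c_b
    double* colc = Jloc + (16 + b) * 20;
    double dsrc = (-P.zeta * E.phis - P.Sn) * E.chi;
    for (int a = 0; a < 4; ++a) {
      const double* ga = E.G + 3 * a;
      for (int i = 0; i < 3; ++i) colc[3 * a + i] = 0.0;
      colc[12 + a] = 0.0;
      double diag = (a == b) ? E.V * (K.J * 0.25 - P.dt * K.J * dsrc * 0.25)
                             : 0.0;
      colc[16 + a] = diag -
                     E.V * P.dt * 0.25 *
                       (Kgp[0] * gb[0] + Kgp[1] * gb[1] +
                        Kgp[2] * gb[2]) / phl +
                     E.V * P.dt * (ga[0] * Dgb[0] + ga[1] * Dgb[1] +
                                   ga[2] * Dgb[2]);
    }
  }
}

// [[Rcpp::export(name = ".fem_assemble")]]
Rcpp::List fem_assemble(const Rcpp::NumericMatrix& gradN,
                        const Rcpp::NumericVector& vol,
                        const Rcpp::IntegerMatrix& tets,
                        const Rcpp::NumericMatrix& u,
                        const Rcpp::NumericVector& p,
                        const Rcpp::NumericVector& c,
                        const Rcpp::NumericVector& Jsk,
                        const Rcpp::NumericVector& ck,
                        const Rcpp::NumericVector& g,
                        const Rcpp::NumericVector& phis,
                        const Rcpp::NumericVector& chi,
                        const Rcpp::NumericMatrix& lam,
                        const Rcpp::NumericMatrix& evec,
                        const Rcpp::NumericVector& a1,
                        const Rcpp::NumericVector& a2,
                        const Rcpp::NumericVector& stab,
                        const Rcpp::NumericVector& par,
                        bool jacobian) {
  const Pars P = unpack(par);
  const int ne = tets.nrow(), M = u.nrow();
  Rcpp::NumericVector res(5 * M);
  Rcpp::NumericVector jac(jacobian ? ne * 400 : 0);
  const double eps_u = 1e-6;
  bool ok = true;
  int bad_cell = 0;

  double ue[12], pe[4], ce[4], R0[20], Rp_[20], Rm_[20];
  int nd[4];
  for (int e = 0; e < ne && ok; ++e) {
    ElemFixed E;
    for (int k = 0; k < 12; ++k) E.G[k] = gradN(e, k);
    E.V = vol[e]; E.g = g[e]; E.phis = phis[e]; E.chi = chi[e];
    E.Jsk = Jsk[e]; E.stab = stab[e];
    for (int i = 0; i < 3; ++i) E.lam[i] = lam(e, i);
    for (int k = 0; k < 9; ++k) E.evec[k] = evec(e, k);
    E.a1 = a1[e]; E.a2 = a2[e];
    for (int a = 0; a < 4; ++a) {
      nd[a] = tets(e, a) - 1;
      for (int i = 0; i < 3; ++i) ue[a * 3 + i] = u(nd[a], i);
      pe[a] = p[nd[a]];
      ce[a] = c[nd[a]];
      E.cek[a] = ck[nd[a]];
    }
    Kin K;
    if (!element_residual(E, ue, pe, ce, P, R0, &K)) {
      ok = false; bad_cell = e + 1; break;
    }
    for (int a = 0; a < 4; ++a) {
      for (int d = 0; d < 3; ++d) res[3 * nd[a] + d] += R0[a * 3 + d];
      res[3 * M + nd[a]] += R0[12 + a];
      res[4 * M + nd[a]] += R0[16 + a];
    }
    if (!jacobian) continue;

    double Jloc[400];
    // displacement columns by central differences
    for (int j = 0; j < 12 && ok; ++j) {
      double keep = ue[j];
      ue[j] = keep + eps_u;
      bool okp = element_residual(E, ue, pe, ce, P, Rp_);
      ue[j] = keep - eps_u;
      bool okm = element_residual(E, ue, pe, ce, P, Rm_);
      ue[j] = keep;
      if (!okp || !okm) { ok = false; bad_cell = e + 1; break; }
      for (int i = 0; i < 20; ++i)
        Jloc[j * 20 + i] = (Rp_[i] - Rm_[i]) / (2 * eps_u);
    }
    if (!ok) break;
    double gradp[3] = {0, 0, 0}, gradc[3] = {0, 0, 0};
    for (int a = 0; a < 4; ++a)
      for (int d = 0; d < 3; ++d) {
        gradp[d] += pe[a] * E.G[a * 3 + d];
        gradc[d] += ce[a] * E.G[a * 3 + d];
      }
    linear_columns(E, K, gradp, gradc, P, Jloc);
    std::copy(Jloc, Jloc + 400, jac.begin() + e * 400);
  }
  return Rcpp::List::create(Rcpp::Named("res") = res,
                            Rcpp::Named("jac") = jac,
                            Rcpp::Named("ok") = ok,
                            Rcpp::Named("bad_cell") = bad_cell);
}

// Accumulate element-major triplet values into the precomputed sparse
// skeleton: out[map[t]] += jac[keep_idx[t]].
// [[Rcpp::export(name = ".accumulate_triplets")]]
Rcpp::NumericVector accumulate_triplets(const Rcpp::NumericVector& jac,
                                        const Rcpp::IntegerVector& keep_idx,
                                        const Rcpp::IntegerVector& map,
                                        int nnz) {
  Rcpp::NumericVector out(nnz);
  const int n = keep_idx.size();
  for (int t = 0; t < n; ++t)
    out[map[t] - 1] += jac[keep_idx[t] - 1];
  return out;
}

// Per-cell converged-state quantities for output, growth updates and tensor
// refreshes: J_s, J_e, Sigma, Holmes-Mow mobility, blended Cauchy stress,
// reoriented D and A, and the pullback D*.
// [[Rcpp::export(name = ".fem_cell_state")]]
Rcpp::List fem_cell_state(const Rcpp::NumericMatrix& gradN,
                          const Rcpp::IntegerMatrix& tets,
                          const Rcpp::NumericMatrix& u,
                          const Rcpp::NumericVector& g,
                          const Rcpp::NumericVector& chi,
                          const Rcpp::NumericMatrix& lam,
                          const Rcpp::NumericMatrix& evec,
                          const Rcpp::NumericVector& a1,
                          const Rcpp::NumericVector& a2,
                          const Rcpp::NumericVector& par) {
  const Pars P = unpack(par);
  const int ne = tets.nrow();
  Rcpp::NumericVector Js(ne), Je(ne), Sigma(ne), kval(ne);
  Rcpp::NumericMatrix Ts(ne, 6), Dc(ne, 6), Ac(ne, 6), Dst(ne, 6);
  const int ci[6] = {0, 3, 6, 4, 7, 8};  // xx xy xz yy yz zz (column-major)
  double ue[12];
  for (int e = 0; e < ne; ++e) {
    ElemFixed E;
    for (int k = 0; k < 12; ++k) E.G[k] = gradN(e, k);
    E.V = 1.0; E.g = g[e]; E.phis = 0.5; E.chi = chi[e];
    E.Jsk = 0; E.stab = 0;
    for (int a = 0; a < 4; ++a) E.cek[a] = 0;
    for (int i = 0; i < 3; ++i) E.lam[i] = lam(e, i);
    for (int k = 0; k < 9; ++k) E.evec[k] = evec(e, k);
    E.a1 = a1[e]; E.a2 = a2[e];
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) ue[a * 3 + i] = u(tets(e, a) - 1, i);
    Kin K;
    if (!kinematics(E, ue, P, K))
      Rcpp::stop("inverted element or pore closure at cell %d", e + 1);
    Js[e] = K.J; Je[e] = K.Je;
    Sigma[e] = -(K.Ts[0] + K.Ts[4] + K.Ts[8]) / 3.0;
    kval[e] = K.kJe;
    for (int k = 0; k < 6; ++k) {
      Ts(e, k) = K.Ts[ci[k]];
      Dc(e, k) = K.D[ci[k]];
      Ac(e, k) = K.A[ci[k]];
      Dst(e, k) = K.Dstar[ci[k]];
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("J_s") = Js, Rcpp::Named("J_e") = Je,
    Rcpp::Named("Sigma") = Sigma, Rcpp::Named("k") = kval,
    Rcpp::Named("T_s") = Ts, Rcpp::Named("D") = Dc,
    Rcpp::Named("A") = Ac, Rcpp::Named("D_star") = Dst);
}
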