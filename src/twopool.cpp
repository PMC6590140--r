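// Two-pool (myelin water / intra-extracellular water) steady-state signal
// models for the SPGR + phase-cycled bSSFP + IR-SPGR protocol, and the
// stochastic region contraction (SRC) fitter that inverts them voxelwise.
//
// The Bloch-McConnell generator without RF decouples into a longitudinal
// 2x2 block (T1 + exchange) and a transverse 2x2 block (T2 + exchange);
// shared off-resonance precession factors out of the transverse block as a
// scalar rotation, so every matrix exponential needed is a real 2x2.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// analytic exp(A * t) for real 2x2 A with real spectrum (exchange matrices)
static arma::mat22 expm2(const arma::mat22& A, double t) {
  const double tr = A(0, 0) + A(1, 1);
  const double det = A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0);
  double disc = tr * tr - 4.0 * det;
  disc = disc > 0.0 ? std::sqrt(disc) : 0.0;
  const double l1 = 0.5 * (tr + disc), l2 = 0.5 * (tr - disc);
  arma::mat22 E;
  if (disc < 1e-9 * std::max(1.0, std::fabs(tr))) {
    // near-defective: first-order expansion about the mean eigenvalue
    const double lm = 0.5 * tr, elm = std::exp(lm * t);
    arma::mat22 N = A; N(0, 0) -= lm; N(1, 1) -= lm;
    E = elm * (arma::eye(2, 2) + t * N);
  } else {
    const double e1 = std::exp(l1 * t), e2 = std::exp(l2 * t);
    arma::mat22 I2 = arma::eye(2, 2);
    E = (e1 * (A - l2 * I2) - e2 * (A - l1 * I2)) / (l1 - l2);
  }
  return E;
}

struct TwoPool {
  double m0, f_m, t1_m, t1_f, t2_m, t2_f, k_mf, df0, kappa;
  double k_fm() const {
    return f_m >= 1.0 ? 0.0 : k_mf * f_m / (1.0 - f_m);
  }
};

// longitudinal generator (units: 1/ms; k_mf given in 1/s)
static void longitudinal_blocks(const TwoPool& p, double tr, arma::mat22& E,
                                arma::vec2& b) {
  const double kmf = p.k_mf / 1000.0, kfm = p.k_fm() / 1000.0;
  arma::mat22 A;
  A(0, 0) = -1.0 / p.t1_m - kmf; A(0, 1) = kfm;
  A(1, 0) = kmf;                 A(1, 1) = -1.0 / p.t1_f - kfm;
  arma::vec2 C;
  C(0) = p.m0 * p.f_m / p.t1_m;
  C(1) = p.m0 * (1.0 - p.f_m) / p.t1_f;
  E = expm2(A, tr);
  b = arma::solve(arma::mat(A), arma::vec((E - arma::eye(2, 2)) * C));
}

static void transverse_block(const TwoPool& p, double tr, arma::mat22& E) {
  const double kmf = p.k_mf / 1000.0, kfm = p.k_fm() / 1000.0;
  arma::mat22 A;
  A(0, 0) = -1.0 / p.t2_m - kmf; A(0, 1) = kfm;
  A(1, 0) = kmf;                 A(1, 1) = -1.0 / p.t2_f - kfm;
  E = expm2(A, tr);
}

// ideally spoiled SPGR: longitudinal steady state with instantaneous
// kappa*alpha rotation, signal = sin(kappa*alpha) * total Mz
static double spgr_two_pool(const TwoPool& p, double tr, double alpha_deg) {
  arma::mat22 E; arma::vec2 b;
  longitudinal_blocks(p, tr, E, b);
  const double a = p.kappa * alpha_deg * DEG;
  arma::mat22 M = arma::eye(2, 2) - E * std::cos(a);
  arma::vec2 mz = arma::solve(arma::mat(M), arma::vec(b));
  return std::fabs(std::sin(a) * (mz(0) + mz(1)));
}

// bSSFP steady state: s_{n+1} = D(theta) Rx(a) s_n + b, solved as a 6x6
// linear system; state = (mx_m, my_m, mx_f, my_f, mz_m, mz_f)
static double bssfp_two_pool(const TwoPool& p, double tr, double alpha_deg,
                             double cycle_deg) {
  arma::mat22 EL; arma::vec2 bL;
  longitudinal_blocks(p, tr, EL, bL);
  arma::mat22 ET; transverse_block(p, tr, ET);
  const double theta = 2.0 * M_PI * p.df0 * (tr / 1000.0) + cycle_deg * DEG;
  const double ct = std::cos(theta), st = std::sin(theta);
  const double a = p.kappa * alpha_deg * DEG;
  const double ca = std::cos(a), sa = std::sin(a);

  arma::mat D(6, 6, arma::fill::zeros);
  // transverse: pools mixed by ET, (x, y) rotated by theta
  for (int pq = 0; pq < 2; ++pq)
    for (int q = 0; q < 2; ++q) {
      D(2 * pq,     2 * q)     = ET(pq, q) * ct;
      D(2 * pq,     2 * q + 1) = -ET(pq, q) * st;
      D(2 * pq + 1, 2 * q)     = ET(pq, q) * st;
      D(2 * pq + 1, 2 * q + 1) = ET(pq, q) * ct;
    }
  D(4, 4) = EL(0, 0); D(4, 5) = EL(0, 1);
  D(5, 4) = EL(1, 0); D(5, 5) = EL(1, 1);

  arma::mat R(6, 6, arma::fill::zeros); // rotation about x per pool
  R(0, 0) = 1.0; R(2, 2) = 1.0;
  R(1, 1) = ca; R(1, 4) = -sa; R(4, 1) = sa; R(4, 4) = ca; // myelin pool
  R(3, 3) = ca; R(3, 5) = -sa; R(5, 3) = sa; R(5, 5) = ca; // free pool
  arma::vec b(6, arma::fill::zeros);
  b(4) = bL(0); b(5) = bL(1);

  arma::mat M = arma::eye(6, 6) - D * R;
  arma::vec s;
  if (!arma::solve(s, M, b, arma::solve_opts::no_approx))
    stop("singular bSSFP steady-state system");
  // echo at TE = tr/2: apply the pulse, evolve half a TR; the shared
  // precession phase is global and drops out of the magnitude
  arma::vec sp = R * s;
  arma::mat22 Eh; transverse_block(p, tr / 2.0, Eh);
  const double mxm = Eh(0, 0) * sp(0) + Eh(0, 1) * sp(2);
  const double mym = Eh(0, 0) * sp(1) + Eh(0, 1) * sp(3);
  const double mxf = Eh(1, 0) * sp(0) + Eh(1, 1) * sp(2);
  const double myf = Eh(1, 0) * sp(1) + Eh(1, 1) * sp(3);
  return std::hypot(mxm + mxf, mym + myf);
}

// IR-SPGR: per-pool closed form (exchange during the inversion delay is
// neglected in this forward model), summed over pools
static double irspgr_two_pool(const TwoPool& p, double ti, double alpha_deg,
                              double tr_total, double inv_eff) {
  const double a = p.kappa * alpha_deg * DEG;
  const double m0m = p.m0 * p.f_m, m0f = p.m0 * (1.0 - p.f_m);
  const double sm = m0m * (1.0 - 2.0 * inv_eff * std::exp(-ti / p.t1_m) +
                           std::exp(-tr_total / p.t1_m));
  const double sf = m0f * (1.0 - 2.0 * inv_eff * std::exp(-ti / p.t1_f) +
                           std::exp(-tr_total / p.t1_f));
  return std::fabs(std::sin(a) * (sm + sf));
}

static TwoPool unpack(const NumericVector& pv) {
  TwoPool p;
  p.m0 = pv["m0"]; p.f_m = pv["f_m"];
  p.t1_m = pv["t1_m"]; p.t1_f = pv["t1_f"];
  p.t2_m = pv["t2_m"]; p.t2_f = pv["t2_f"];
  p.k_mf = pv["k_mf"]; p.df0 = pv["delta_f0"]; p.kappa = pv["b1_scale"];
  return p;
}

// full signal set: 7 SPGR, 7 bSSFP (cycle 1), 7 bSSFP (cycle 2), 1 IR-SPGR
// [[Rcpp::export]]
NumericVector cpp_two_pool_signals(NumericVector params, double spgr_tr,
                                   NumericVector spgr_alphas, double bssfp_tr,
                                   NumericVector bssfp_alphas,
                                   NumericVector cycles, double ir_ti,
                                   double ir_alpha, double ir_tr_total,
                                   double inv_eff) {
  TwoPool p = unpack(params);
  const int ns = spgr_alphas.size(), nb = bssfp_alphas.size(),
      nc = cycles.size();
  NumericVector out(ns + nb * nc + 1);
  int k = 0;
  for (int i = 0; i < ns; ++i) out[k++] = spgr_two_pool(p, spgr_tr,
                                                        spgr_alphas[i]);
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < nb; ++i)
      out[k++] = bssfp_two_pool(p, bssfp_tr, bssfp_alphas[i], cycles[c]);
  out[k] = irspgr_two_pool(p, ir_ti, ir_alpha, ir_tr_total, inv_eff);
  return out;
}

// --- fast path used inside SRC ------------------------------------------
// per-candidate blocks are computed once and reused across flip angles

static void solve6(double A[6][6], double b[6], double x[6]) {
  int piv[6];
  for (int i = 0; i < 6; ++i) piv[i] = i;
  for (int col = 0; col < 6; ++col) {
    int pr = col;
    double amax = std::fabs(A[piv[col]][col]);
    for (int r = col + 1; r < 6; ++r) {
      double v = std::fabs(A[piv[r]][col]);
      if (v > amax) { amax = v; pr = r; }
    }
    std::swap(piv[col], piv[pr]);
    const double d = A[piv[col]][col];
    for (int r = col + 1; r < 6; ++r) {
      const double f = A[piv[r]][col] / d;
      if (f != 0.0) {
        for (int c = col + 1; c < 6; ++c) A[piv[r]][c] -= f * A[piv[col]][c];
        b[piv[r]] -= f * b[piv[col]];
        A[piv[r]][col] = 0.0;
      }
    }
  }
  for (int r = 5; r >= 0; --r) {
    double s = b[piv[r]];
    for (int c = r + 1; c < 6; ++c) s -= A[piv[r]][c] * x[c];
    x[r] = s / A[piv[r]][r];
  }
}

// scalar 2x2 helpers (no heap traffic in the hot loop)
struct M2 { double a, b, c, d; };   // [[a, b], [c, d]]

static inline M2 expm2s(double a, double b, double c, double d, double t) {
  const double tr = a + d, det = a * d - b * c;
  double disc = tr * tr - 4.0 * det;
  disc = disc > 0.0 ? std::sqrt(disc) : 0.0;
  if (disc < 1e-9 * std::max(1.0, std::fabs(tr))) {
    const double lm = 0.5 * tr, elm = std::exp(lm * t);
    return M2{elm * (1.0 + t * (a - lm)), elm * t * b,
              elm * t * c, elm * (1.0 + t * (d - lm))};
  }
  const double l1 = 0.5 * (tr + disc), l2 = 0.5 * (tr - disc);
  const double e1 = std::exp(l1 * t), e2 = std::exp(l2 * t);
  const double s = 1.0 / (l1 - l2);
  return M2{(e1 * (a - l2) - e2 * (a - l1)) * s, (e1 - e2) * b * s,
            (e1 - e2) * c * s, (e1 * (d - l2) - e2 * (d - l1)) * s};
}

struct CandidateBlocks {
  M2 EL, ET, ETh;       // bSSFP evolution blocks
  M2 ELs;               // SPGR longitudinal block
  double bL0, bL1;      // bSSFP longitudinal inhomogeneous term
  double bLs0, bLs1;    // SPGR version
};

// b = A^{-1} (E - I) C for the longitudinal block
static inline void long_b(const M2& E, double a, double b, double c, double d,
                          double C0, double C1, double& b0, double& b1) {
  const double r0 = (E.a - 1.0) * C0 + E.b * C1;
  const double r1 = E.c * C0 + (E.d - 1.0) * C1;
  const double det = a * d - b * c;
  b0 = (d * r0 - b * r1) / det;
  b1 = (a * r1 - c * r0) / det;
}

static void make_blocks(const TwoPool& p, double spgr_tr, double bssfp_tr,
                        CandidateBlocks& cb) {
  const double kmf = p.k_mf / 1000.0;
  const double kfm = p.f_m >= 1.0 ? 0.0 : kmf * p.f_m / (1.0 - p.f_m);
  const double La = -1.0 / p.t1_m - kmf, Lb = kfm, Lc = kmf,
      Ld = -1.0 / p.t1_f - kfm;
  const double Ta = -1.0 / p.t2_m - kmf, Tb = kfm, Tc = kmf,
      Td = -1.0 / p.t2_f - kfm;
  const double C0 = p.m0 * p.f_m / p.t1_m;
  const double C1 = p.m0 * (1.0 - p.f_m) / p.t1_f;
  cb.ELs = expm2s(La, Lb, Lc, Ld, spgr_tr);
  long_b(cb.ELs, La, Lb, Lc, Ld, C0, C1, cb.bLs0, cb.bLs1);
  cb.EL = expm2s(La, Lb, Lc, Ld, bssfp_tr);
  long_b(cb.EL, La, Lb, Lc, Ld, C0, C1, cb.bL0, cb.bL1);
  cb.ET = expm2s(Ta, Tb, Tc, Td, bssfp_tr);
  cb.ETh = expm2s(Ta, Tb, Tc, Td, bssfp_tr / 2.0);
}

static inline double spgr_fast(const CandidateBlocks& cb, double ca,
                               double sa) {
  const double m00 = 1.0 - cb.ELs.a * ca, m01 = -cb.ELs.b * ca;
  const double m10 = -cb.ELs.c * ca, m11 = 1.0 - cb.ELs.d * ca;
  const double det = m00 * m11 - m01 * m10;
  const double z0 = (m11 * cb.bLs0 - m01 * cb.bLs1) / det;
  const double z1 = (m00 * cb.bLs1 - m10 * cb.bLs0) / det;
  return std::fabs(sa * (z0 + z1));
}

static double bssfp_fast(const CandidateBlocks& cb, double ca, double sa,
                         double ct, double st) {
  // M = I - D R, state (mxm, mym, mxf, myf, mzm, mzf)
  double A[6][6], b[6] = {0, 0, 0, 0, cb.bL0, cb.bL1}, x[6];
  const double ET[2][2] = {{cb.ET.a, cb.ET.b}, {cb.ET.c, cb.ET.d}};
  const double EL[2][2] = {{cb.EL.a, cb.EL.b}, {cb.EL.c, cb.EL.d}};
  for (int p = 0; p < 2; ++p)
    for (int q = 0; q < 2; ++q) {
      const double e = ET[p][q];
      A[2 * p][2 * q] = -e * ct;
      A[2 * p][2 * q + 1] = e * st * ca;
      A[2 * p][4 + q] = -e * st * sa;
      A[2 * p + 1][2 * q] = -e * st;
      A[2 * p + 1][2 * q + 1] = -e * ct * ca;
      A[2 * p + 1][4 + q] = e * ct * sa;
    }
  for (int p = 0; p < 2; ++p) {
    A[4 + p][0] = 0.0; A[4 + p][2] = 0.0;
    for (int q = 0; q < 2; ++q) {
      A[4 + p][2 * q + 1] = -EL[p][q] * sa;
      A[4 + p][4 + q] = -EL[p][q] * ca;
    }
  }
  for (int i = 0; i < 6; ++i) A[i][i] += 1.0;
  solve6(A, b, x);
  // pulse, then half-TR transverse evolution (shared phase drops out)
  const double mym = x[1] * ca - x[4] * sa, myf = x[3] * ca - x[5] * sa;
  const double mxm = cb.ETh.a * x[0] + cb.ETh.b * x[2];
  const double mxf = cb.ETh.c * x[0] + cb.ETh.d * x[2];
  const double mym2 = cb.ETh.a * mym + cb.ETh.b * myf;
  const double myf2 = cb.ETh.c * mym + cb.ETh.d * myf;
  return std::hypot(mxm + mxf, mym2 + myf2);
}

// Block-normalized model vector: SPGR block and joint bSSFP block (both
// phase cycles together, preserving their amplitude ratio), each divided by
// its mean to remove the m0 scale.  IR-SPGR is not used by SRC.
struct TrigCache {
  std::vector<double> cas, sas, cab, sab;  // cos/sin of kappa*alpha
  double ct[2], st[2];                     // cos/sin of theta per cycle
};

static TrigCache make_trig(double kappa, double df0,
                           const arma::vec& spgr_alphas,
                           const arma::vec& bssfp_alphas,
                           const arma::vec& cycles, double bssfp_tr) {
  TrigCache t;
  for (arma::uword i = 0; i < spgr_alphas.n_elem; ++i) {
    const double a = kappa * spgr_alphas(i) * DEG;
    t.cas.push_back(std::cos(a)); t.sas.push_back(std::sin(a));
  }
  for (arma::uword i = 0; i < bssfp_alphas.n_elem; ++i) {
    const double a = kappa * bssfp_alphas(i) * DEG;
    t.cab.push_back(std::cos(a)); t.sab.push_back(std::sin(a));
  }
  for (int c = 0; c < 2; ++c) {
    const double theta = 2.0 * M_PI * df0 * (bssfp_tr / 1000.0) +
        cycles(c) * DEG;
    t.ct[c] = std::cos(theta); t.st[c] = std::sin(theta);
  }
  return t;
}

static void src_model(const TwoPool& p, double spgr_tr, double bssfp_tr,
                      const TrigCache& tg, arma::vec& m) {
  const int ns = tg.cas.size(), nb = tg.cab.size();
  CandidateBlocks cb;
  make_blocks(p, spgr_tr, bssfp_tr, cb);
  for (int i = 0; i < ns; ++i)
    m(i) = spgr_fast(cb, tg.cas[i], tg.sas[i]);
  for (int c = 0; c < 2; ++c)
    for (int i = 0; i < nb; ++i)
      m(ns + c * nb + i) = bssfp_fast(cb, tg.cab[i], tg.sab[i],
                                      tg.ct[c], tg.st[c]);
  double mu = arma::mean(m.subvec(0, ns - 1));
  if (mu > 0) m.subvec(0, ns - 1) /= mu;
  mu = arma::mean(m.subvec(ns, ns + 2 * nb - 1));
  if (mu > 0) m.subvec(ns, ns + 2 * nb - 1) /= mu;
}

static void normalize_blocks(arma::vec& y, int ns, int nb) {
  double mu = arma::mean(y.subvec(0, ns - 1));
  if (mu > 0) y.subvec(0, ns - 1) /= mu;
  mu = arma::mean(y.subvec(ns, ns + 2 * nb - 1));
  if (mu > 0) y.subvec(ns, ns + 2 * nb - 1) /= mu;
}

static double src_score(const TwoPool& p, double spgr_tr, double bssfp_tr,
                        const TrigCache& tg, const arma::vec& ynorm) {
  arma::vec m(ynorm.n_elem);
  src_model(p, spgr_tr, bssfp_tr, tg, m);
  arma::vec r = m - ynorm;
  return arma::dot(r, r);
}

// bounded Levenberg-Marquardt polish on the 6 free parameters; the mcDESPOT
// objective has long flat valleys that plain box contraction cannot descend
static void lm_polish(arma::vec& theta, double& fval, const arma::mat& bounds,
                      const TwoPool& base, double spgr_tr, double bssfp_tr,
                      const TrigCache& tg, const arma::vec& ynorm,
                      int max_iter) {
  const int npar = 6, nobs = ynorm.n_elem;
  auto model = [&](const arma::vec& th, arma::vec& m) {
    TwoPool p = base;
    p.f_m = th(0); p.t1_m = th(1); p.t1_f = th(2);
    p.t2_m = th(3); p.t2_f = th(4); p.k_mf = th(5);
    src_model(p, spgr_tr, bssfp_tr, tg, m);
  };
  arma::vec m(nobs), mp(nobs), r(nobs);
  model(theta, m);
  r = m - ynorm;
  double f = arma::dot(r, r);
  double lambda = 1e-3;
  arma::mat J(nobs, npar);
  const arma::vec scale = bounds.col(1) - bounds.col(0);
  for (int it = 0; it < max_iter; ++it) {
    for (int j = 0; j < npar; ++j) {
      double h = 1e-6 * std::max(scale(j), 1e-8);
      arma::vec th = theta;
      th(j) = std::min(bounds(j, 1), th(j) + h);
      double hj = th(j) - theta(j);
      if (hj == 0.0) { th(j) = theta(j) - h; hj = -h; }
      model(th, mp);
      J.col(j) = (mp - m) / hj;
    }
    arma::mat H = J.t() * J;
    arma::vec g = J.t() * r;
    bool stepped = false;
    for (int tries = 0; tries < 8; ++tries) {
      arma::mat Hl = H;
      Hl.diag() += lambda * (H.diag() + 1e-12);
      arma::vec delta;
      if (!arma::solve(delta, Hl, -g, arma::solve_opts::no_approx)) { lambda *= 10.0; continue; }
      arma::vec th(npar);
      for (int j = 0; j < npar; ++j)
        th(j) = std::min(bounds(j, 1), std::max(bounds(j, 0),
                                                theta(j) + delta(j)));
      model(th, mp);
      arma::vec rp = mp - ynorm;
      double fp = arma::dot(rp, rp);
      if (fp < f) {
        theta = th; f = fp; m = mp; r = rp;
        lambda = std::max(lambda / 3.0, 1e-12);
        stepped = true;
        break;
      }
      lambda *= 10.0;
    }
    if (!stepped || f < 1e-24) break;
  }
  fval = f;
}

// fast-path signal set exposed for cross-validation against the reference
// implementation above
// [[Rcpp::export]]
NumericVector cpp_two_pool_signals_fast(NumericVector params, double spgr_tr,
                                        NumericVector spgr_alphas,
                                        double bssfp_tr,
                                        NumericVector bssfp_alphas,
                                        NumericVector cycles) {
  TwoPool p = unpack(params);
  CandidateBlocks cb;
  make_blocks(p, spgr_tr, bssfp_tr, cb);
  const int ns = spgr_alphas.size(), nb = bssfp_alphas.size();
  NumericVector out(ns + nb * cycles.size());
  int k = 0;
  for (int i = 0; i < ns; ++i) {
    const double a = p.kappa * spgr_alphas[i] * DEG;
    out[k++] = spgr_fast(cb, std::cos(a), std::sin(a));
  }
  for (int c = 0; c < cycles.size(); ++c) {
    const double theta = 2.0 * M_PI * p.df0 * (bssfp_tr / 1000.0) +
        cycles[c] * DEG;
    const double ct = std::cos(theta), st = std::sin(theta);
    for (int i = 0; i < nb; ++i) {
      const double a = p.kappa * bssfp_alphas[i] * DEG;
      out[k++] = bssfp_fast(cb, std::cos(a), std::sin(a), ct, st);
    }
  }
  return out;
}

// Stochastic region contraction over (f_m, t1_m, t1_f, t2_m, t2_f, k_mf).
// Y columns: per-voxel [SPGR(ns); bSSFP cycle1(nb); bSSFP cycle2(nb)].
// Uses the R RNG, so results follow set.seed().
// [[Rcpp::export]]
List cpp_src_fit_many(const arma::mat& Y, const arma::vec& kappa,
                      const arma::vec& df0, const arma::mat& bounds,
                      double spgr_tr, const arma::vec& spgr_alphas,
                      double bssfp_tr, const arma::vec& bssfp_alphas,
                      const arma::vec& cycles, int n_samples, int n_retain,
                      int n_iterations, double contraction_tol, bool polish,
                      int polish_iter) {
  const arma::uword nvox = Y.n_cols;
  const int ns = spgr_alphas.n_elem, nb = bssfp_alphas.n_elem;
  if ((int)Y.n_rows != ns + 2 * nb) stop("signal matrix has wrong row count");
  if (n_retain >= n_samples) stop("n_retain must be < n_samples");
  const int npar = 6;
  arma::mat est(npar, nvox, arma::fill::zeros);
  arma::vec score(nvox, arma::fill::zeros);
  const arma::vec width0 = bounds.col(1) - bounds.col(0);

  for (arma::uword v = 0; v < nvox; ++v) {
    arma::vec y = Y.col(v);
    normalize_blocks(y, ns, nb); // block-normalize the data once
    TwoPool base;
    base.m0 = 1.0; base.df0 = df0(v); base.kappa = kappa(v);
    const TrigCache tg = make_trig(base.kappa, base.df0, spgr_alphas,
                                   bssfp_alphas, cycles, bssfp_tr);
    auto eval = [&](const arma::vec& th) {
      TwoPool p = base;
      p.f_m = th(0); p.t1_m = th(1); p.t1_f = th(2);
      p.t2_m = th(3); p.t2_f = th(4); p.k_mf = th(5);
      return src_score(p, spgr_tr, bssfp_tr, tg, y);
    };
    arma::vec lo = bounds.col(0), hi = bounds.col(1);
    arma::vec best(npar);
    double best_f = arma::datum::inf;
    if (arma::max(hi - lo) <= 0.0) { // degenerate box: return the point
      est.col(v) = lo; score(v) = eval(lo); continue;
    }
    arma::mat samp(npar, n_samples);
    arma::vec f(n_samples);
    for (int it = 0; it < n_iterations; ++it) {
      for (int s = 0; s < n_samples; ++s) {
        for (int j = 0; j < npar; ++j)
          samp(j, s) = lo(j) + unif_rand() * (hi(j) - lo(j));
        f(s) = eval(samp.col(s));
      }
      arma::uvec ord = arma::sort_index(f);
      if (f(ord(0)) < best_f) { best_f = f(ord(0)); best = samp.col(ord(0)); }
      arma::mat keep = samp.cols(ord.head(n_retain));
      arma::vec nlo = arma::min(keep, 1), nhi = arma::max(keep, 1);
      arma::vec w = nhi - nlo;
      nlo -= 0.01 * w; nhi += 0.01 * w; // 1% re-expansion
      lo = arma::max(bounds.col(0), nlo);
      hi = arma::min(bounds.col(1), nhi);
      if (arma::all((hi - lo) < contraction_tol * width0)) break;
    }
    if (polish)
      lm_polish(best, best_f, bounds, base, spgr_tr, bssfp_tr, tg, y,
                polish_iter);
    est.col(v) = best;
    score(v) = best_f;
  }
  return List::create(_["estimates"] = est, _["score"] = score);
}
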