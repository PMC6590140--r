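// Multi-echo T2 core: extended phase graph (EPG) echo amplitudes for a CPMG
// train with imperfect refocusing, Lawson-Hanson non-negative least squares,
// and the voxelwise regularized spectrum fitter built on both.
#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// EPG configuration-state recursion for a 90x - (te/2 - beta_y - te/2 - echo)^etl
// train.  States are kept real (refocusing about y, real initial condition).
// Longitudinal states decay with T1 but do not regrow (TR >> T2 assumption of
// the decay-fitting model).  Echo i is |F_0| after the i-th refocusing pulse
// and te/2 of evolution.
static arma::vec epg_echoes(double t2, double t1, double te, int etl,
                            double beta_deg) {
  const int nk = 2 * etl + 2;       // max dephasing order reachable
  arma::vec Fp(nk, arma::fill::zeros), Fm(nk, arma::fill::zeros),
      Z(nk, arma::fill::zeros);
  Fp(0) = 1.0;                      // unit transverse magnetization after 90x
  Fm(0) = 1.0;                      // F_0 and its conjugate coincide (real)
  const double e2 = std::exp(-0.5 * te / t2);
  const double e1 = std::exp(-0.5 * te / t1);
  const double b = beta_deg * M_PI / 180.0;
  const double c2 = std::cos(b / 2.0) * std::cos(b / 2.0);
  const double s2 = std::sin(b / 2.0) * std::sin(b / 2.0);
  const double sb = std::sin(b);
  arma::vec echoes(etl);

  auto relax_shift = [&]() {
    Fp *= e2; Fm *= e2; Z *= e1;
    // dephasing shift: F_k -> F_{k+1}
    for (int k = nk - 1; k >= 1; --k) Fp(k) = Fp(k - 1);
    Fp(0) = Fm(1);                  // F_0 <- F_{-1} (real states: conj = id)
    for (int k = 0; k < nk - 1; ++k) Fm(k) = Fm(k + 1);
    Fm(nk - 1) = 0.0;
    Fm(0) = Fp(0);                  // keep the k = 0 pair consistent
  };

  for (int i = 0; i < etl; ++i) {
    relax_shift();
    // refocusing rotation about y by beta, mixing (F+_k, F-_k, Z_k)
    for (int k = 0; k < nk; ++k) {
      const double fp = Fp(k), fm = Fm(k), z = Z(k);
      Fp(k) = c2 * fp + s2 * fm + sb * z;
      Fm(k) = s2 * fp + c2 * fm - sb * z;
      Z(k) = -0.5 * sb * fp + 0.5 * sb * fm + std::cos(b) * z;
    }
    Fm(0) = Fp(0) = 0.5 * (Fp(0) + Fm(0)); // numerical symmetry guard
    relax_shift();
    echoes(i) = std::fabs(Fp(0));
  }
  return echoes;
}

// [[Rcpp::export]]
arma::vec cpp_epg_cpmg(double t2, double t1, double te, int etl,
                       double beta_deg) {
  if (beta_deg <= 0.0 || beta_deg > 180.0)
    stop("refocusing angle must be in (0, 180] degrees");
  if (t2 <= 0.0 || t1 <= 0.0 || te <= 0.0 || etl < 1)
    stop("t2, t1, te must be positive and etl >= 1");
  return epg_echoes(t2, t1, te, etl, beta_deg);
}

// Design matrix A(beta): column j = EPG decay of grid T2_j.
// [[Rcpp::export]]
arma::mat cpp_epg_basis(const arma::vec& t2_grid, double t1, double te,
                        int etl, double beta_deg) {
  arma::mat A(etl, t2_grid.n_elem);
  for (arma::uword j = 0; j < t2_grid.n_elem; ++j)
    A.col(j) = epg_echoes(t2_grid(j), t1, te, etl, beta_deg);
  return A;
}

// Lawson-Hanson active-set NNLS: min ||Ax - b||^2 s.t. x >= 0.
static arma::vec nnls_lh(const arma::mat& A, const arma::vec& b,
                         double* rss_out = nullptr) {
  const arma::uword n = A.n_cols;
  arma::vec x(n, arma::fill::zeros);
  std::vector<bool> passive(n, false);
  arma::vec w = A.t() * (b - A * x);
  const double tol = 10.0 * arma::datum::eps *
      arma::norm(A, 1) * static_cast<double>(A.n_rows);
  arma::uvec pidx;
  int outer = 0, outer_max = 3 * static_cast<int>(n);

  while (outer++ < outer_max) {
    double wmax = -1.0; arma::sword jmax = -1;
    for (arma::uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
    if (jmax < 0 || wmax <= tol) break;
    passive[jmax] = true;

    for (int inner = 0; inner < outer_max; ++inner) {
      arma::uvec p = arma::uvec();
      std::vector<arma::uword> pv;
      for (arma::uword j = 0; j < n; ++j) if (passive[j]) pv.push_back(j);
      p = arma::uvec(pv);
      arma::vec s;
      if (!arma::solve(s, A.cols(p), b)) { passive[jmax] = false; break; }
      if (s.min() > 0.0) {
        x.zeros();
        for (arma::uword i = 0; i < p.n_elem; ++i) x(p(i)) = s(i);
        break;
      }
      // step back to the feasibility boundary, drop zeroed variables
      double alpha = arma::datum::inf;
      for (arma::uword i = 0; i < p.n_elem; ++i) {
        if (s(i) <= 0.0) {
          double a = x(p(i)) / (x(p(i)) - s(i));
          if (a < alpha) alpha = a;
        }
      }
      for (arma::uword i = 0; i < p.n_elem; ++i)
        x(p(i)) += alpha * (s(i) - x(p(i)));
      for (arma::uword i = 0; i < p.n_elem; ++i)
        if (x(p(i)) <= tol) { x(p(i)) = 0.0; passive[p(i)] = false; }
    }
    w = A.t() * (b - A * x);
  }
  if (rss_out) {
    arma::vec r = b - A * x;
    *rss_out = arma::dot(r, r);
  }
  return x;
}

// [[Rcpp::export]]
arma::vec cpp_nnls(const arma::mat& A, const arma::vec& b) {
  if (A.n_rows != b.n_elem) stop("dimension mismatch in nnls");
  return nnls_lh(A, b);
}

// Lawson-Hanson on the normal equations with a precomputed Gram matrix:
// min ||Ax-y||^2 + mu ||x||^2 given G = A'A, aty = A'y, yty = y'y.
// Used in the hot search loops; the data-term chi^2 is returned via rss_out.
static arma::vec nnls_gram(const arma::mat& G, const arma::vec& aty,
                           double mu, double yty, double* rss_out) {
  const arma::uword n = G.n_cols;
  arma::vec x(n, arma::fill::zeros);
  std::vector<bool> passive(n, false);
  arma::vec w = aty;                       // A'(y - Ax) - mu x at x = 0
  const double tol = 1e-10 * std::max(1.0, yty);
  int outer = 0, outer_max = 3 * static_cast<int>(n);
  while (outer++ < outer_max) {
    double wmax = -1.0; arma::sword jmax = -1;
    for (arma::uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
    if (jmax < 0 || wmax <= tol) break;
    passive[jmax] = true;
    for (int inner = 0; inner < outer_max; ++inner) {
      std::vector<arma::uword> pv;
      for (arma::uword j = 0; j < n; ++j) if (passive[j]) pv.push_back(j);
      arma::uvec p(pv);
      arma::mat Gpp = G.submat(p, p);
      Gpp.diag() += mu + 1e-12 * Gpp.diag().max();
      arma::vec s;
      if (!arma::solve(s, Gpp, aty(p), arma::solve_opts::likely_sympd +
                                       arma::solve_opts::no_approx)) {
        passive[jmax] = false; break;
      }
      if (s.min() > 0.0) {
        x.zeros();
        for (arma::uword i = 0; i < p.n_elem; ++i) x(p(i)) = s(i);
        break;
      }
      double alpha = arma::datum::inf;
      for (arma::uword i = 0; i < p.n_elem; ++i)
        if (s(i) <= 0.0) {
          double a = x(p(i)) / (x(p(i)) - s(i));
          if (a < alpha) alpha = a;
        }
      for (arma::uword i = 0; i < p.n_elem; ++i)
        x(p(i)) += alpha * (s(i) - x(p(i)));
      for (arma::uword i = 0; i < p.n_elem; ++i)
        if (x(p(i)) <= 0.0) { x(p(i)) = 0.0; passive[p(i)] = false; }
    }
    w = aty - G * x - mu * x;
  }
  if (rss_out)
    *rss_out = std::max(0.0, yty - 2.0 * arma::dot(x, aty) +
                        arma::dot(x, G * x));
  return x;
}

// basis cache over quantized beta so the golden-section search reuses
// design matrices (and their Gram matrices) across voxels
struct BasisCache {
  struct Entry { arma::mat A, G; };
  std::map<long, Entry> store;
  const arma::vec& grid; double t1, te; int etl; double quant;
  BasisCache(const arma::vec& g, double t1_, double te_, int etl_, double q)
      : grid(g), t1(t1_), te(te_), etl(etl_), quant(q) {}
  double snap(double beta) const {
    double b = std::round(beta / quant) * quant;
    return std::min(180.0, std::max(1.0, b));
  }
  const Entry& get(double beta) {
    long key = std::lround(beta / quant);
    auto it = store.find(key);
    if (it != store.end()) return it->second;
    Entry e;
    e.A = cpp_epg_basis(grid, t1, te, etl, snap(beta));
    e.G = e.A.t() * e.A;
    return store.emplace(key, std::move(e)).first->second;
  }
};

static double nnls_rss_at(BasisCache& cache, double beta, const arma::vec& y,
                          double yty) {
  const BasisCache::Entry& e = cache.get(beta);
  double rss = 0.0;
  nnls_gram(e.G, e.A.t() * y, 0.0, yty, &rss);
  return rss;
}

// golden-section over beta in [lo, hi]; ties broken toward the upper end by
// the <= comparison (physical preference for 180 degrees).
static double golden_beta(BasisCache& cache, const arma::vec& y, double yty,
                          double lo, double hi, double tol) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = nnls_rss_at(cache, c, y, yty), fd = nnls_rss_at(cache, d, y, yty);
  while (b - a > tol) {
    if (fc < fd) { b = d; d = c; fd = fc; c = b - gr * (b - a);
      fc = nnls_rss_at(cache, c, y, yty); }
    else { a = c; c = d; fc = fd; d = a + gr * (b - a);
      fd = nnls_rss_at(cache, d, y, yty); }
  }
  // endpoint check keeps exact 180 reachable
  double mid = cache.snap(0.5 * (a + b));
  double fm = nnls_rss_at(cache, mid, y, yty);
  double fhi = nnls_rss_at(cache, hi, y, yty);
  return (fhi <= fm) ? hi : mid;
}

// Tikhonov: augment A with sqrt(mu) I, bisect log-mu until the data-term
// chi^2 lands inside [lo, hi] x chi2_unreg.
static arma::vec tikhonov_fit(const arma::mat& G, const arma::vec& aty,
                              double yty, double chi2_unreg, double lo,
                              double hi, int max_iter, double* mu_out,
                              double* chi2_out, bool* ok, double* warm_lmu) {
  const double scale2 = arma::trace(G);    // = ||A||_F^2
  arma::vec x;
  double chi2 = chi2_unreg, mu = 0.0;
  *ok = false;
  auto eval = [&](double lmu) {
    mu = std::pow(10.0, lmu) * scale2;
    x = nnls_gram(G, aty, mu, yty, &chi2);
    return chi2;
  };
  const double target_lo = lo * chi2_unreg, target_hi = hi * chi2_unreg;
  double lmu_lo = -12.0, lmu_hi = 2.0; // log10(mu / ||A||_F^2)
  // warm start: neighbouring voxels have nearly the same noise level, so the
  // previous solution usually lands inside (or very near) the chi2 band
  if (std::isfinite(*warm_lmu)) {
    double c = eval(*warm_lmu);
    if (c >= target_lo && c <= target_hi) {
      *ok = true; *mu_out = mu; *chi2_out = chi2;
      return x;
    }
    double wlo = *warm_lmu - 1.0, whi = *warm_lmu + 1.0;
    if (c > target_hi) { whi = *warm_lmu; wlo = *warm_lmu - 2.0; }
    else { wlo = *warm_lmu; whi = *warm_lmu + 2.0; }
    if (eval(wlo) < target_hi && eval(whi) > target_lo) {
      lmu_lo = wlo; lmu_hi = whi;
    }
  }
  if (eval(lmu_lo) > target_hi) { *mu_out = mu; *chi2_out = chi2; return x; }
  if (eval(lmu_hi) < target_lo) { *mu_out = mu; *chi2_out = chi2; return x; }
  for (int i = 0; i < max_iter; ++i) {
    double lmid = 0.5 * (lmu_lo + lmu_hi);
    double c = eval(lmid);
    if (c >= target_lo && c <= target_hi) {
      *ok = true; *warm_lmu = lmid;
      break;
    }
    if (c > target_hi) lmu_hi = lmid; else lmu_lo = lmid;
  }
  *mu_out = mu; *chi2_out = chi2;
  return x;
}

// Voxelwise fitter: columns of Y are echo decays.  Returns spectra, the
// refocusing-angle estimates and residuals.  reg_mode: 0 none, 1 tikhonov.
// [[Rcpp::export]]
List cpp_fit_t2_many(const arma::mat& Y, const arma::vec& t2_grid, double te,
                     double t1, double beta_lo, double beta_hi,
                     double beta_tol, double beta_quant, int reg_mode,
                     double chi2_lo, double chi2_hi, int mu_max_iter) {
  const int etl = Y.n_rows;
  const arma::uword nvox = Y.n_cols;
  BasisCache cache(t2_grid, t1, te, etl, beta_quant);
  arma::mat W(t2_grid.n_elem, nvox, arma::fill::zeros);
  arma::vec beta(nvox, arma::fill::zeros), resid(nvox, arma::fill::zeros),
      mu(nvox, arma::fill::zeros);
  IntegerVector reg_ok(nvox);
  double warm_lmu = arma::datum::nan;
  for (arma::uword v = 0; v < nvox; ++v) {
    arma::vec y = Y.col(v);
    const double yty = arma::dot(y, y);
    if (yty <= 0.0) stop("all-zero decay at voxel %d", (int)v + 1);
    double bhat = golden_beta(cache, y, yty, beta_lo, beta_hi, beta_tol);
    const BasisCache::Entry& e = cache.get(bhat);
    double rss0 = 0.0;
    arma::vec x = nnls_lh(e.A, y, &rss0);
    double chi2 = rss0, m = 0.0;
    bool ok = true;
    if (reg_mode == 1 && rss0 > 1e-12 * yty) {
      arma::vec aty = e.A.t() * y;
      x = tikhonov_fit(e.G, aty, yty, rss0, chi2_lo, chi2_hi, mu_max_iter,
                       &m, &chi2, &ok, &warm_lmu);
      if (!ok) { x = nnls_lh(e.A, y, &rss0); chi2 = rss0; m = 0.0; }
    }
    W.col(v) = x;
    beta(v) = cache.snap(bhat);
    resid(v) = chi2;
    mu(v) = m;
    reg_ok[v] = ok ? 1 : 0;
  }
  return List::create(_["weights"] = W, _["beta"] = beta,
                      _["residual"] = resid, _["mu"] = mu,
                      _["reg_converged"] = reg_ok);
}
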