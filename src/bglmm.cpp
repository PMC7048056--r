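// Binomial logit GLMM with crossed random intercepts (animal, sampling day),
// fitted by Laplace approximation: the inner problem maximizes the penalized
// joint log-likelihood over (beta, u, v) by Newton iterations; the outer
// problem minimizes the Laplace deviance over the two SDs by Nelder-Mead.
// A weak Gaussian penalty (sd `beta_sd`) on the fixed effects guards against
// separation. Designed for repeated refits inside permutation tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct Model {
  vec y, n;
  uvec niche, dog, day;   // 0-based indices
  int kn, kd, kt;         // numbers of levels (kd/kt may be 0)
  double beta_prec;
  int p() const { return kn + kd + kt; }
};

struct Blocks {
  bool dog_on, day_on;
  double prec_dog, prec_day;
};

static vec make_eta(const Model& M, const vec& th) {
  const int N = M.y.n_elem;
  vec eta(N);
  for (int i = 0; i < N; ++i) {
    double e = th(M.niche(i));
    if (M.kd > 0) e += th(M.kn + M.dog(i));
    if (M.kt > 0) e += th(M.kn + M.kd + M.day(i));
    eta(i) = e;
  }
  return eta;
}

// penalized joint log-likelihood (no normalizing constants)
static double pen_ll(const Model& M, const Blocks& B, const vec& th) {
  vec eta = make_eta(M, th);
  double ll = 0.0;
  for (unsigned i = 0; i < M.y.n_elem; ++i)
    ll += M.y(i) * eta(i) - M.n(i) * softplus(eta(i));
  for (int j = 0; j < M.kn; ++j) ll -= 0.5 * M.beta_prec * th(j) * th(j);
  if (B.dog_on)
    for (int j = 0; j < M.kd; ++j) {
      double t = th(M.kn + j);
      ll -= 0.5 * B.prec_dog * t * t;
    }
  if (B.day_on)
    for (int j = 0; j < M.kt; ++j) {
      double t = th(M.kn + M.kd + j);
      ll -= 0.5 * B.prec_day * t * t;
    }
  return ll;
}

// Newton maximization of pen_ll over the active parameters; returns
// convergence flag, fills H (active Hessian) and act (active positions).
static bool newton(const Model& M, const Blocks& B, vec& th, mat& H,
                   uvec& act, int maxit, double tol) {
  const int p = M.p();
  std::vector<int> slot(p, -1);
  std::vector<unsigned> actv;
  for (int j = 0; j < M.kn; ++j) { slot[j] = actv.size(); actv.push_back(j); }
  if (B.dog_on)
    for (int j = 0; j < M.kd; ++j) { slot[M.kn + j] = actv.size(); actv.push_back(M.kn + j); }
  else
    for (int j = 0; j < M.kd; ++j) th(M.kn + j) = 0.0;
  if (B.day_on)
    for (int j = 0; j < M.kt; ++j) { slot[M.kn + M.kd + j] = actv.size(); actv.push_back(M.kn + M.kd + j); }
  else
    for (int j = 0; j < M.kt; ++j) th(M.kn + M.kd + j) = 0.0;
  const int na = actv.size();
  act = uvec(actv.size());
  for (size_t k = 0; k < actv.size(); ++k) act(k) = actv[k];

  vec prec(na, fill::zeros);
  for (int k = 0; k < na; ++k) {
    int j = act(k);
    if (j < M.kn) prec(k) = M.beta_prec;
    else if (j < M.kn + M.kd) prec(k) = B.prec_dog;
    else prec(k) = B.prec_day;
  }

  double f = pen_ll(M, B, th);
  if (!std::isfinite(f)) return false;
  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    vec eta = make_eta(M, th);
    vec g_full(p, fill::zeros);
    H.zeros(na, na);
    for (unsigned i = 0; i < M.y.n_elem; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-eta(i)));
      double r = M.y(i) - M.n(i) * pi;
      double w = M.n(i) * pi * (1.0 - pi);
      int a1 = slot[M.niche(i)];
      int a2 = (M.kd > 0) ? slot[M.kn + M.dog(i)] : -1;
      int a3 = (M.kt > 0) ? slot[M.kn + M.kd + M.day(i)] : -1;
      g_full(M.niche(i)) += r;
      if (a2 >= 0) g_full(M.kn + M.dog(i)) += r;
      if (a3 >= 0) g_full(M.kn + M.kd + M.day(i)) += r;
      H(a1, a1) += w;
      if (a2 >= 0) { H(a2, a2) += w; H(a1, a2) += w; H(a2, a1) += w; }
      if (a3 >= 0) {
        H(a3, a3) += w; H(a1, a3) += w; H(a3, a1) += w;
        if (a2 >= 0) { H(a2, a3) += w; H(a3, a2) += w; }
      }
    }
    vec g(na);
    for (int k = 0; k < na; ++k) g(k) = g_full(act(k)) - prec(k) * th(act(k));
    H.diag() += prec;

    vec step;
    bool ok = solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) {
      mat Hr = H; Hr.diag() += 1e-8 * (1.0 + H.diag().max());
      if (!solve(step, Hr, g, solve_opts::likely_sympd)) return false;
    }
    // line search (step halving on the penalized log-likelihood)
    double t = 1.0, fnew = -datum::inf;
    vec th_new;
    for (int h = 0; h < 30; ++h) {
      th_new = th;
      for (int k = 0; k < na; ++k) th_new(act(k)) += t * step(k);
      fnew = pen_ll(M, B, th_new);
      if (std::isfinite(fnew) && fnew >= f - 1e-10) break;
      t *= 0.5;
    }
    if (!std::isfinite(fnew)) return false;
    double dstep = t * arma::abs(step).max();
    th = th_new;
    f = fnew;
    if (dstep < tol || arma::abs(g).max() < 1e-6) { conv = true; break; }
  }
  // refresh H at the optimum
  {
    vec eta = make_eta(M, th);
    H.zeros(na, na);
    for (unsigned i = 0; i < M.y.n_elem; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-eta(i)));
      double w = M.n(i) * pi * (1.0 - pi);
      int a1 = slot[M.niche(i)];
      int a2 = (M.kd > 0) ? slot[M.kn + M.dog(i)] : -1;
      int a3 = (M.kt > 0) ? slot[M.kn + M.kd + M.day(i)] : -1;
      H(a1, a1) += w;
      if (a2 >= 0) { H(a2, a2) += w; H(a1, a2) += w; H(a2, a1) += w; }
      if (a3 >= 0) {
        H(a3, a3) += w; H(a1, a3) += w; H(a3, a1) += w;
        if (a2 >= 0) { H(a2, a3) += w; H(a3, a2) += w; }
      }
    }
    H.diag() += prec;
  }
  return conv;
}

static const double SD_TOL = 1e-6;
static const double LOG2PI = 1.8378770664093453;

// Laplace deviance at (sd_dog, sd_day); th is the warm start (updated in place)
static double laplace_dev(const Model& M, double sd_dog, double sd_day,
                          vec& th, mat& H, uvec& act, bool& conv,
                          int newton_maxit) {
  Blocks B;
  B.dog_on = (M.kd > 0) && (sd_dog > SD_TOL);
  B.day_on = (M.kt > 0) && (sd_day > SD_TOL);
  B.prec_dog = B.dog_on ? 1.0 / (sd_dog * sd_dog) : 0.0;
  B.prec_day = B.day_on ? 1.0 / (sd_day * sd_day) : 0.0;
  conv = newton(M, B, th, H, act, newton_maxit, 1e-9);
  if (!conv && !th.is_finite()) { th.zeros(); return 1e10; }
  double ll = pen_ll(M, B, th);
  // prior normalizers (so the deviance is continuous as an SD -> 0);
  // the beta-penalty normalizer is constant across evaluations and dropped
  if (B.dog_on) ll -= M.kd * std::log(sd_dog) + 0.5 * M.kd * LOG2PI;
  if (B.day_on) ll -= M.kt * std::log(sd_day) + 0.5 * M.kt * LOG2PI;
  double ld, sign;
  if (!log_det(ld, sign, H) || sign <= 0) return 1e10;
  double logml = ll + 0.5 * act.n_elem * LOG2PI - 0.5 * ld;
  double dev = -2.0 * logml;
  if (!std::isfinite(dev)) return 1e10;
  return dev;
}

// [[Rcpp::export(name = ".bglmm_fit_cpp")]]
Rcpp::List bglmm_fit_cpp(const arma::vec& y, const arma::vec& n,
                         const arma::uvec& niche, const arma::uvec& dog,
                         const arma::uvec& day,
                         int kn, int kd, int kt,
                         double beta_sd,
                         arma::vec sd_init, bool fix_sd, arma::vec sd_fixed,
                         int nm_maxit, double nm_reltol, int newton_maxit) {
  Model M;
  M.y = y; M.n = n; M.niche = niche; M.dog = dog; M.day = day;
  M.kn = kn; M.kd = kd; M.kt = kt;
  M.beta_prec = 1.0 / (beta_sd * beta_sd);

  vec th(M.p(), fill::zeros);
  mat H;
  uvec act;
  bool conv = false;
  double sd_d, sd_t;
  bool nm_conv = true;
  int n_eval = 0;

  if (fix_sd || (kd == 0 && kt == 0)) {
    sd_d = fix_sd ? sd_fixed(0) : 0.0;
    sd_t = fix_sd ? sd_fixed(1) : 0.0;
    laplace_dev(M, sd_d, sd_t, th, H, act, conv, newton_maxit);
  } else {
    // Nelder-Mead over (s1, s2), SDs taken as |s|
    auto f = [&](double a, double b) {
      bool c;
      double d = laplace_dev(M, std::abs(a), std::abs(b), th, H, act, c, newton_maxit);
      ++n_eval;
      return d;
    };
    double s1 = sd_init(0), s2 = sd_init(1);
    double h1 = std::max(0.25, 0.5 * s1), h2 = std::max(0.25, 0.5 * s2);
    mat S = { {s1, s2}, {s1 + h1, s2}, {s1, s2 + h2} };  // 3 x 2 simplex
    vec fv(3);
    for (int i = 0; i < 3; ++i) fv(i) = f(S(i, 0), S(i, 1));
    const double alpha = 1.0, gamma2 = 2.0, rho = 0.5, sigma = 0.5;
    while (n_eval < nm_maxit) {
      uvec ord = sort_index(fv);
      S = S.rows(ord); fv = fv(ord);
      if (std::abs(fv(2) - fv(0)) < nm_reltol * (std::abs(fv(0)) + 1e-8)) break;
      rowvec cen = (S.row(0) + S.row(1)) / 2.0;
      rowvec xr = cen + alpha * (cen - S.row(2));
      double fr = f(xr(0), xr(1));
      if (fr < fv(0)) {
        rowvec xe = cen + gamma2 * (xr - cen);
        double fe = f(xe(0), xe(1));
        if (fe < fr) { S.row(2) = xe; fv(2) = fe; }
        else { S.row(2) = xr; fv(2) = fr; }
      } else if (fr < fv(1)) {
        S.row(2) = xr; fv(2) = fr;
      } else {
        rowvec xc = cen + rho * (S.row(2) - cen);
        double fc = f(xc(0), xc(1));
        if (fc < fv(2)) { S.row(2) = xc; fv(2) = fc; }
        else {
          S.row(1) = S.row(0) + sigma * (S.row(1) - S.row(0));
          S.row(2) = S.row(0) + sigma * (S.row(2) - S.row(0));
          fv(1) = f(S(1, 0), S(1, 1));
          fv(2) = f(S(2, 0), S(2, 1));
        }
      }
    }
    nm_conv = n_eval < nm_maxit;
    uvec ord = sort_index(fv);
    sd_d = std::abs(S(ord(0), 0));
    sd_t = std::abs(S(ord(0), 1));
    if (sd_d <= SD_TOL) sd_d = 0.0;
    if (sd_t <= SD_TOL) sd_t = 0.0;
  }

  bool final_conv;
  double dev = laplace_dev(M, sd_d, sd_t, th, H, act, final_conv, newton_maxit);

  // Wald covariance of the fixed effects: beta block of the inverse active
  // Hessian (conditional on the estimated SDs)
  mat Hi;
  bool inv_ok = inv_sympd(Hi, H);
  if (!inv_ok) inv_ok = inv(Hi, H);
  mat vcov_beta(kn, kn, fill::value(datum::nan));
  if (inv_ok) vcov_beta = Hi.submat(0, 0, kn - 1, kn - 1);

  return Rcpp::List::create(
    Rcpp::Named("beta") = th.subvec(0, kn - 1),
    Rcpp::Named("vcov_beta") = vcov_beta,
    Rcpp::Named("u") = (kd > 0) ? th.subvec(kn, kn + kd - 1) : vec(),
    Rcpp::Named("v") = (kt > 0) ? th.subvec(kn + kd, kn + kd + kt - 1) : vec(),
    Rcpp::Named("sd_dog") = sd_d,
    Rcpp::Named("sd_day") = sd_t,
    Rcpp::Named("deviance") = dev,
    Rcpp::Named("converged") = final_conv && nm_conv,
    Rcpp::Named("n_eval") = n_eval);
}
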