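// Block Gibbs sampler core.  All randomness comes from R's RNG so runs are
// reproducible from set.seed(); the R-level step functions implement the same
// conditionals and serve as the tested reference kernels.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- small numeric helpers -------------------------------------------------

// symmetrize + inverse with escalating ridge near the SPD boundary
static arma::mat inv_spd_guarded(const arma::mat& M) {
  arma::mat S = 0.5 * (M + M.t());
  arma::mat out;
  if (arma::inv_sympd(out, S)) return 0.5 * (out + out.t());
  const double d = arma::mean(arma::abs(S.diag())) + 1e-300;
  for (int k = -10; k <= -1; ++k) {
    arma::mat Sr = S + std::pow(10.0, k) * d *
      arma::eye<arma::mat>(S.n_rows, S.n_rows);
    if (arma::inv_sympd(out, Sr)) return 0.5 * (out + out.t());
  }
  stop("matrix is numerically indefinite beyond repair");
}

static arma::mat chol_lower_guarded(const arma::mat& M) {
  arma::mat S = 0.5 * (M + M.t());
  arma::mat L;
  if (arma::chol(L, S, "lower")) return L;
  const double d = arma::mean(arma::abs(S.diag())) + 1e-300;
  for (int k = -10; k <= -1; ++k) {
    arma::mat Sr = S + std::pow(10.0, k) * d *
      arma::eye<arma::mat>(S.n_rows, S.n_rows);
    if (arma::chol(L, Sr, "lower")) return L;
  }
  stop("matrix is numerically indefinite beyond repair");
}

static arma::vec rnorm_vec(int n) {
  arma::vec v(n);
  for (int i = 0; i < n; ++i) v[i] = norm_rand();
  return v;
}

// inverse-Gaussian draw, Michael-Schucany-Haas
static double rinvgauss1(double mean, double shape) {
  double y = norm_rand(); y *= y;
  double x = mean + mean * mean * y / (2.0 * shape) -
    mean / (2.0 * shape) *
    std::sqrt(4.0 * mean * shape * y + mean * mean * y * y);
  if (x < DBL_MIN) x = DBL_MIN;
  return (unif_rand() <= mean / (mean + x)) ? x : mean * mean / x;
}

// inverse-Wishart draw via Bartlett on the inverse scale
static arma::mat rinvwishart1(double df, const arma::mat& S) {
  const int p = S.n_rows;
  arma::mat L = chol_lower_guarded(inv_spd_guarded(S));
  arma::mat A(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) A(j, j) = std::sqrt(R::rchisq(df - j));
  for (int j = 0; j < p; ++j)
    for (int i = j + 1; i < p; ++i) A(i, j) = norm_rand();
  arma::mat LA = L * A;
  return inv_spd_guarded(LA * LA.t());
}

// ---- truncated normal (shared with the exported rtnorm) ---------------------

static double rtnorm_std(double a, double b) {
  const bool lo = R_finite(a), hi = R_finite(b);
  if (!lo && !hi) return norm_rand();
  if (!hi) {                                   // (a, Inf)
    if (a < -8.0) {
      double x; do { x = norm_rand(); } while (x <= a);
      return x;
    }
    double lpa = R::pnorm(a, 0.0, 1.0, 0, 1);  // log upper tail
    double u = unif_rand();
    double x = R::qnorm(lpa + std::log(u), 0.0, 1.0, 0, 1);
    return (x > a) ? x : a + 1e-14 * (1.0 + std::fabs(a));
  }
  if (!lo) return -rtnorm_std(-b, R_PosInf);
  if (b <= 0.0) return -rtnorm_std(-b, -a);
  if (a >= 0.0) {                              // right-tail interval
    double lpa = R::pnorm(a, 0.0, 1.0, 0, 1);
    double lpb = R::pnorm(b, 0.0, 1.0, 0, 1);
    double r = std::exp(lpb - lpa);
    if (1.0 - r > 1e-12) {
      double u = unif_rand();
      double lt = lpa + std::log1p(-u * (1.0 - r));
      double x = R::qnorm(lt, 0.0, 1.0, 0, 1);
      if (x > a && x < b) return x;
    }
    for (int it = 0; it < 1000; ++it) {        // interval mass underflow
      double x = a + unif_rand() * (b - a);
      if (std::log(unif_rand()) <= -(x * x - a * a) / 2.0) return x;
    }
    return a + 0.5 * (b - a);
  }
  double pa = R::pnorm(a, 0.0, 1.0, 1, 0);     // straddles the mode
  double pb = R::pnorm(b, 0.0, 1.0, 1, 0);
  if (pb - pa > 1e-14) {
    double x = R::qnorm(pa + unif_rand() * (pb - pa), 0.0, 1.0, 1, 0);
    if (x > a && x < b) return x;
  }
  return a + unif_rand() * (b - a);
}

static double rtnorm1(double mean, double sd, double lb, double ub) {
  double a = R_finite(lb) ? (lb - mean) / sd : R_NegInf;
  double b = R_finite(ub) ? (ub - mean) / sd : R_PosInf;
  return mean + sd * rtnorm_std(a, b);
}

// [[Rcpp::export]]
NumericVector rtnorm_cpp(int n, NumericVector mean, NumericVector sd,
                         NumericVector lb, NumericVector ub) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double m = mean[i % mean.size()], s = sd[i % sd.size()];
    double l = lb[i % lb.size()], u = ub[i % ub.size()];
    if (!(l < u)) stop("lower bound must be strictly below upper bound");
    out[i] = rtnorm1(m, s, l, u);
  }
  return out;
}

// ---- latent sweep -----------------------------------------------------------

// One sweep over column l: observed cells in increasing level order with
// bounds from the current latent values, then untruncated missing cells.
static void sweep_column(arma::mat& Z, int l, const arma::ivec& cluster,
                         const arma::mat& B, const arma::mat& W,
                         double sd, const IntegerVector& o,
                         const IntegerVector& st, const IntegerVector& ms) {
  const int p = Z.n_cols;
  const int nlev = st.size() - 1;
  std::vector<double> sufmin(nlev + 1, R_PosInf);
  for (int g = nlev - 1; g >= 0; --g) {
    double mn = R_PosInf;
    for (int k = st[g]; k < st[g + 1]; ++k) mn = std::min(mn, Z(o[k], l));
    sufmin[g] = std::min(mn, sufmin[g + 1]);
  }
  double lb = R_NegInf;
  for (int g = 0; g < nlev; ++g) {
    const double ub = sufmin[g + 1];
    double newmax = R_NegInf;
    for (int k = st[g]; k < st[g + 1]; ++k) {
      const int i = o[k], c = cluster[i];
      double mean = B(c, l);
      for (int j = 0; j < p; ++j)
        if (j != l) mean += W(l, j) * (Z(i, j) - B(c, j));
      if (!(lb < ub)) stop("rank invariant violated: lb >= ub in latent sweep");
      double d = rtnorm1(mean, sd, lb, ub);
      Z(i, l) = d;
      newmax = std::max(newmax, d);
    }
    if (R_finite(newmax)) lb = std::max(lb, newmax);
  }
  for (int k = 0; k < ms.size(); ++k) {
    const int i = ms[k], c = cluster[i];
    double mean = B(c, l);
    for (int j = 0; j < p; ++j)
      if (j != l) mean += W(l, j) * (Z(i, j) - B(c, j));
    Z(i, l) = mean + sd * norm_rand();
  }
}

static void sweep_all(arma::mat& Z, const arma::ivec& cluster,
                      const arma::mat& B, const arma::mat& Omega,
                      const List& ord, const List& starts, const List& miss) {
  const int p = Z.n_cols;
  arma::mat W(p, p, arma::fill::zeros);
  for (int l = 0; l < p; ++l)
    for (int j = 0; j < p; ++j)
      if (j != l) W(l, j) = -Omega(l, j) / Omega(l, l);
  for (int l = 0; l < p; ++l) {
    double sd = std::sqrt(1.0 / Omega(l, l));
    sweep_column(Z, l, cluster, B, W, sd, ord[l], starts[l], miss[l]);
  }
}

// [[Rcpp::export]]
arma::mat latent_sweep_cpp(arma::mat z, IntegerVector cluster,
                           arma::mat b, arma::mat w, NumericVector v,
                           List ord, List starts, List miss) {
  const int p = z.n_cols;
  arma::ivec cl(cluster.size());
  for (int i = 0; i < cluster.size(); ++i) cl[i] = cluster[i];
  for (int l = 0; l < p; ++l)
    sweep_column(z, l, cl, b, w, std::sqrt(v[l]), ord[l], starts[l], miss[l]);
  return z;
}

// ---- full chain -------------------------------------------------------------

// Runs the block Gibbs chain.  Z0 is the initialized latent matrix; the
// rescaled state is stored and carried forward (identified copula scale).
// [[Rcpp::export]]
List run_chain_cpp(arma::mat Z0, IntegerVector cluster, int m,
                   double s, double t, double lambda_diag,
                   double nu, arma::mat Lambda,
                   int n_iter, int thin, int burn,
                   bool store_z, bool latent_update,
                   List ord, List starts, List miss,
                   arma::mat Omega0) {
  const int N = Z0.n_rows, p = Z0.n_cols;
  arma::mat Z = Z0;
  arma::ivec cl(cluster.size());
  arma::uvec clu(cluster.size());
  for (int i = 0; i < cluster.size(); ++i) { cl[i] = cluster[i]; clu[i] = cluster[i]; }
  arma::vec nc(m, arma::fill::zeros);
  for (int i = 0; i < N; ++i) nc[cl[i]] += 1.0;

  arma::mat Omega = Omega0, Psi = arma::eye<arma::mat>(p, p);
  arma::mat B(m, p, arma::fill::zeros);
  arma::mat lam(p, p, arma::fill::ones), tau(p, p, arma::fill::zeros);

  const int K = (n_iter - burn) / thin + (((n_iter - burn) % thin) ? 1 : 0);
  int Kact = 0;
  for (int it = 1; it <= n_iter; ++it)
    if (it > burn && (it - burn) % thin == 0) ++Kact;
  arma::cube sGamma(p, p, Kact), sOmega(p, p, Kact), sPsi(p, p, Kact);
  arma::cube sB(m, p, Kact);
  arma::cube sZ;
  if (store_z) sZ.set_size(N, p, Kact);
  (void)K;

  int kk = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // step 1: cluster random effects
    arma::mat psi_inv = inv_spd_guarded(Psi);
    arma::mat zsum(m, p, arma::fill::zeros);
    for (int i = 0; i < N; ++i) zsum.row(cl[i]) += Z.row(i);
    for (int c = 0; c < m; ++c) {
      arma::mat V = inv_spd_guarded(psi_inv + nc[c] * Omega);
      arma::vec mu = V * (Omega * zsum.row(c).t());
      B.row(c) = (mu + chol_lower_guarded(V) * rnorm_vec(p)).t();
    }
    // step 2: random-effect covariance
    arma::mat Psi_t = rinvwishart1(nu + m, Lambda + B.t() * B);
    // step 4: shrinkage parameters (adaptive off-diagonal, fixed diagonal)
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < j; ++i) {
        double draw = R::rgamma(1.0 + s, 1.0 / (std::fabs(Omega(i, j)) + t));
        lam(i, j) = lam(j, i) = draw;
      }
      lam(j, j) = lambda_diag;
    }
    // step 5: Laplace scale-mixture variances
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < j; ++i) {
        double ao = std::max(std::fabs(Omega(i, j)), 1e-10);
        double u = rinvgauss1(lam(i, j) / ao, lam(i, j) * lam(i, j));
        tau(i, j) = tau(j, i) = 1.0 / u;
      }
    // step 3 + 6: column-wise precision update
    arma::mat resid = Z - B.rows(clu);
    arma::mat S = resid.t() * resid;
    for (int l = 0; l < p; ++l) {
      double s22 = S(l, l), lam22 = lam(l, l);
      double gam = R::rgamma(N / 2.0 + 1.0, 2.0 / (s22 + lam22));
      if (p == 1) { Omega(0, 0) = gam; continue; }
      arma::uvec rest(p - 1);
      int q = 0;
      for (int j = 0; j < p; ++j) if (j != l) rest[q++] = j;
      arma::mat O11_inv = inv_spd_guarded(Omega.submat(rest, rest));
      arma::vec s12(p - 1), itau(p - 1);
      for (int j = 0; j < p - 1; ++j) {
        s12[j] = S(rest[j], l);
        itau[j] = 1.0 / tau(rest[j], l);
      }
      arma::mat C = inv_spd_guarded((s22 + lam22) * O11_inv +
                                    arma::diagmat(itau));
      arma::vec beta = -C * s12 + chol_lower_guarded(C) * rnorm_vec(p - 1);
      for (int j = 0; j < p - 1; ++j) {
        Omega(rest[j], l) = beta[j];
        Omega(l, rest[j]) = beta[j];
      }
      Omega(l, l) = gam + arma::as_scalar(beta.t() * O11_inv * beta);
    }
    // step 7: pin the unidentified copula scale (total variance 1)
    arma::mat Gamma_t = inv_spd_guarded(Omega);
    arma::vec d = Gamma_t.diag() + Psi_t.diag();
    if (d.min() <= 0) stop("total marginal variances must be positive");
    arma::vec sc = 1.0 / arma::sqrt(d);
    arma::mat D = sc * sc.t();
    arma::mat Gamma = Gamma_t % D;
    Psi = Psi_t % D;
    B.each_row() %= sc.t();
    Omega = inv_spd_guarded(Gamma);
    // step 8: latent sweep
    if (latent_update) sweep_all(Z, cl, B, Omega, ord, starts, miss);

    if (it > burn && (it - burn) % thin == 0) {
      sGamma.slice(kk) = Gamma;
      sOmega.slice(kk) = Omega;
      sPsi.slice(kk) = Psi;
      sB.slice(kk) = B;
      if (store_z) sZ.slice(kk) = Z;
      ++kk;
    }
  }
  List out = List::create(_["Gamma"] = sGamma, _["Omega"] = sOmega,
                          _["Psi"] = sPsi, _["B"] = sB);
  if (store_z) out["Z"] = sZ;
  return out;
}
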