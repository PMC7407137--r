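// Autoregressive latent log-rate model with Student-t drift and
// negative-binomial observations, plus a No-U-Turn HMC sampler
// (slice-variant with dual-averaging step-size adaptation and diagonal
// mass-matrix warmup windows). Gradients are analytic; the latent path is
// non-centered (standardised innovations), which is distributionally
// identical to the centered model.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Model {
  virtual int dim() const = 0;
  // returns unnormalised log posterior; fills grad (same length as q)
  virtual double logp_grad(const std::vector<double>& q,
                           std::vector<double>& grad) const = 0;
  virtual ~Model() {}
};

// ---------------------------------------------------------------------------
// Full model. Unconstrained parameter layout (dim = n + 3 fixed + 1):
//   q[0]            lambda_1
//   q[1 .. n-1]     eta_2 .. eta_n   (standardised t innovations)
//   q[n]            rho
//   q[n+1]          s = log sigma
//   q[n+2]          m = log nu
//   q[n+3]          w = log(1/phi)
// lambda_i = rho * lambda_{i-1} + sigma * eta_i.
// ---------------------------------------------------------------------------
struct FlowModel : public Model {
  std::vector<int> y;        // counts
  std::vector<double> lgyf;  // lgamma(y_i + 1)
  std::vector<int> uy;       // sorted unique counts
  std::vector<int> uidx;     // index of y_i in uy
  // prior hyperparameters
  double c_u, c_sig, a_nu, b_nu, sd_rho, c_l1;
  int n;
  // workspace (reused across gradient evaluations)
  mutable std::vector<double> lam, mu_w, ldenom_w, l1p_w, aw, glw, lg_u, dg_u;

  FlowModel(const IntegerVector& y_, const List& pr) {
    n = y_.size();
    y.assign(y_.begin(), y_.end());
    lgyf.resize(n);
    for (int i = 0; i < n; ++i) lgyf[i] = R::lgammafn(y[i] + 1.0);
    uy.assign(y.begin(), y.end());
    std::sort(uy.begin(), uy.end());
    uy.erase(std::unique(uy.begin(), uy.end()), uy.end());
    uidx.resize(n);
    for (int i = 0; i < n; ++i)
      uidx[i] = std::lower_bound(uy.begin(), uy.end(), y[i]) - uy.begin();
    c_u   = as<double>(pr["inv_phi_scale"]);
    c_sig = as<double>(pr["sigma_scale"]);
    a_nu  = as<double>(pr["nu_shape"]);
    b_nu  = as<double>(pr["nu_rate"]);
    sd_rho = as<double>(pr["rho_sd"]);
    c_l1  = as<double>(pr["lambda1_scale"]);
    lam.resize(n); mu_w.resize(n); ldenom_w.resize(n); l1p_w.resize(n);
    aw.resize(n); glw.resize(n);
    lg_u.resize(uy.size()); dg_u.resize(uy.size());
  }

  int dim() const { return n + 4 - 1 + 1; }  // n + 4 slots: see layout

  double logp_grad(const std::vector<double>& q,
                   std::vector<double>& grad) const {
    const int d = dim();
    std::fill(grad.begin(), grad.end(), 0.0);
    const double lam1 = q[0], rho = q[n], s = q[n + 1], m = q[n + 2],
                 w = q[n + 3];
    if (std::fabs(s) > 200 || std::fabs(m) > 200 || std::fabs(w) > 200 ||
        std::fabs(lam1) > 200 || std::fabs(rho) > 200)
      return NEG_INF;
    const double sigma = std::exp(s), nu = std::exp(m), u = std::exp(w),
                 phi = std::exp(-w);

    // forward latent path
    lam[0] = lam1;
    for (int i = 1; i < n; ++i) {
      lam[i] = rho * lam[i - 1] + sigma * q[i];
      if (std::fabs(lam[i]) > 200) return NEG_INF;
    }

    // caches over unique counts
    const int nu_y = uy.size();
    for (int k = 0; k < nu_y; ++k) {
      lg_u[k] = R::lgammafn(uy[k] + phi);
      dg_u[k] = R::digamma(uy[k] + phi);
    }
    const double lgphi = R::lgammafn(phi), dgphi = R::digamma(phi),
                 logphi = -w;  // log(phi) = -w exactly

    // transcendental-heavy loops kept separate and branch-free
    for (int i = 0; i < n; ++i) mu_w[i] = std::exp(lam[i]);
    for (int i = 0; i < n; ++i) ldenom_w[i] = std::log(phi + mu_w[i]);
    const double inv_nu = 1.0 / nu;
    for (int i = 1; i < n; ++i) l1p_w[i] = std::log1p(q[i] * q[i] * inv_nu);

    double logp = 0.0, dphi_obs = 0.0;
    for (int i = 0; i < n; ++i) {
      const double inv_denom = 1.0 / (phi + mu_w[i]);
      const double yphi = y[i] + phi;
      logp += lg_u[uidx[i]] - lgphi - lgyf[i] + phi * (logphi - ldenom_w[i]) +
              y[i] * (lam[i] - ldenom_w[i]);
      aw[i] = y[i] - yphi * mu_w[i] * inv_denom;
      dphi_obs += dg_u[uidx[i]] - dgphi + logphi + 1.0 - ldenom_w[i] -
                  yphi * inv_denom;
    }

    // innovations: eta_i ~ t_nu(0, 1), i = 2..n  (q[1..n-1])
    const double lgt_const = R::lgammafn(0.5 * (nu + 1.0)) -
                             R::lgammafn(0.5 * nu) -
                             0.5 * std::log(nu * M_PI);
    const double dg_half = 0.5 * R::digamma(0.5 * (nu + 1.0)) -
                           0.5 * R::digamma(0.5 * nu) - 0.5 / nu;
    double dnu_innov = 0.0, l1p_sum = 0.0;
    for (int i = 1; i < n; ++i) {
      const double e2 = q[i] * q[i];
      l1p_sum += l1p_w[i];
      dnu_innov += (nu + 1.0) * e2 / (2.0 * nu * (nu + e2));
    }
    dnu_innov += (n - 1) * dg_half - 0.5 * l1p_sum;
    logp += (n - 1) * lgt_const - 0.5 * (nu + 1.0) * l1p_sum;

    // priors (on the unconstrained scale, Jacobians included)
    logp += -std::log(M_PI * c_l1) - std::log1p((lam1 / c_l1) * (lam1 / c_l1));
    logp += -0.5 * rho * rho / (sd_rho * sd_rho) - std::log(sd_rho) -
            0.5 * std::log(2.0 * M_PI);
    logp += std::log(2.0) - std::log(M_PI * c_sig) -
            std::log1p((sigma / c_sig) * (sigma / c_sig)) + s;
    logp += std::log(2.0) - std::log(M_PI * c_u) -
            std::log1p((u / c_u) * (u / c_u)) + w;
    logp += a_nu * std::log(b_nu) - R::lgammafn(a_nu) + a_nu * m - b_nu * nu;
    if (!std::isfinite(logp)) return NEG_INF;

    // backprop through lambda recursion: g_i = dL/dlambda_i (total)
    std::vector<double>& gl = glw;
    gl[n - 1] = aw[n - 1];
    for (int i = n - 2; i >= 0; --i) gl[i] = aw[i] + rho * gl[i + 1];

    grad[0] = gl[0] - 2.0 * lam1 / (c_l1 * c_l1 + lam1 * lam1);
    double drho = 0.0, ds_path = 0.0;
    for (int i = 1; i < n; ++i) {
      const double e = q[i];
      grad[i] = sigma * gl[i] - (nu + 1.0) * e / (nu + e * e);
      drho += gl[i] * lam[i - 1];
      ds_path += gl[i] * e;
    }
    grad[n] = drho - rho / (sd_rho * sd_rho);
    grad[n + 1] = sigma * (ds_path - 2.0 * sigma /
                           (c_sig * c_sig + sigma * sigma)) + 1.0;
    grad[n + 2] = nu * (dnu_innov + (a_nu - 1.0) / nu - b_nu) + 1.0;
    grad[n + 3] = -phi * dphi_obs - 2.0 * u * u / (c_u * c_u + u * u) + 1.0;

    for (int k = 0; k < d; ++k)
      if (!std::isfinite(grad[k])) return NEG_INF;
    return logp;
  }
};

// ---------------------------------------------------------------------------
// Conditional model for rho with the latent path, sigma and nu fixed:
// p(rho | lambda, sigma, nu) ∝ N(rho; 0, sd) * prod t_nu(lambda_i;
// rho lambda_{i-1}, sigma). Used for the quadrature cross-check.
// ---------------------------------------------------------------------------
struct RhoModel : public Model {
  std::vector<double> lam;
  double sigma, nu, sd_rho;

  RhoModel(const NumericVector& lam_, double sigma_, double nu_,
           double sd_rho_)
      : lam(lam_.begin(), lam_.end()), sigma(sigma_), nu(nu_),
        sd_rho(sd_rho_) {}

  int dim() const { return 1; }

  double logp_grad(const std::vector<double>& q,
                   std::vector<double>& grad) const {
    const double rho = q[0];
    if (std::fabs(rho) > 200) return NEG_INF;
    const int n = lam.size();
    double logp = -0.5 * rho * rho / (sd_rho * sd_rho);
    double g = -rho / (sd_rho * sd_rho);
    for (int i = 1; i < n; ++i) {
      const double e = (lam[i] - rho * lam[i - 1]) / sigma;
      logp += -0.5 * (nu + 1.0) * std::log1p(e * e / nu) - std::log(sigma);
      g += (nu + 1.0) * e * lam[i - 1] / (sigma * (nu + e * e));
    }
    grad[0] = g;
    return logp;
  }
};

// ---------------------------------------------------------------------------
// NUTS engine (slice variant) with dual averaging and diagonal mass matrix
// ---------------------------------------------------------------------------
struct State {
  std::vector<double> q, p, g;
  double logp;
};

struct Engine {
  const Model& model;
  int d;
  std::vector<double> inv_mass;  // diagonal inverse mass (posterior var)
  double eps;
  int max_depth;
  double delta;  // target acceptance
  long n_grad;

  Engine(const Model& m, double delta_, int max_depth_)
      : model(m), d(m.dim()), inv_mass(m.dim(), 1.0), eps(0.1),
        max_depth(max_depth_), delta(delta_), n_grad(0) {}

  double kinetic(const std::vector<double>& p) const {
    double k = 0.0;
    for (int i = 0; i < d; ++i) k += inv_mass[i] * p[i] * p[i];
    return 0.5 * k;
  }

  void sample_momentum(std::vector<double>& p) const {
    for (int i = 0; i < d; ++i)
      p[i] = norm_rand() / std::sqrt(inv_mass[i]);
  }

  // one leapfrog step in direction v (+1/-1); returns log joint H = logp - K
  double leapfrog(State& z, int v) {
    const double e = v * eps;
    for (int i = 0; i < d; ++i) z.p[i] += 0.5 * e * z.g[i];
    for (int i = 0; i < d; ++i) z.q[i] += e * inv_mass[i] * z.p[i];
    z.logp = model.logp_grad(z.q, z.g);
    ++n_grad;
    for (int i = 0; i < d; ++i) z.p[i] += 0.5 * e * z.g[i];
    if (!std::isfinite(z.logp)) return NEG_INF;
    return z.logp - kinetic(z.p);
  }

  bool no_uturn(const State& minus, const State& plus) const {
    double dot_m = 0.0, dot_p = 0.0;
    for (int i = 0; i < d; ++i) {
      const double dq = plus.q[i] - minus.q[i];
      dot_m += dq * inv_mass[i] * minus.p[i];
      dot_p += dq * inv_mass[i] * plus.p[i];
    }
    return dot_m >= 0.0 && dot_p >= 0.0;
  }

  struct TreeResult {
    State minus, plus, prop;
    int n_valid;
    bool keep_going;
    bool divergent;
    double alpha;
    int n_alpha;
  };

  void build_tree(const State& z, double logu, int v, int depth, double H0,
                  TreeResult& out) {
    if (depth == 0) {
      State z1 = z;
      const double H = leapfrog(z1, v);
      out.minus = z1;
      out.plus = z1;
      out.prop = z1;
      out.n_valid = (logu <= H) ? 1 : 0;
      out.divergent = (H - logu) < -1000.0;
      out.keep_going = !out.divergent;
      const double da = H - H0;
      out.alpha = std::isfinite(da) ? std::min(1.0, std::exp(da)) : 0.0;
      out.n_alpha = 1;
      return;
    }
    build_tree(z, logu, v, depth - 1, H0, out);
    if (!out.keep_going) return;
    TreeResult sub;
    if (v == -1) {
      build_tree(out.minus, logu, v, depth - 1, H0, sub);
      out.minus = sub.minus;
    } else {
      build_tree(out.plus, logu, v, depth - 1, H0, sub);
      out.plus = sub.plus;
    }
    if (sub.keep_going && sub.n_valid > 0 &&
        unif_rand() * (out.n_valid + sub.n_valid) < sub.n_valid)
      out.prop = sub.prop;
    out.n_valid += sub.n_valid;
    out.divergent = out.divergent || sub.divergent;
    out.keep_going = sub.keep_going && no_uturn(out.minus, out.plus);
    out.alpha += sub.alpha;
    out.n_alpha += sub.n_alpha;
  }

  // one NUTS transition; returns average acceptance statistic, sets
  // divergent flag and tree depth
  double transition(State& z, bool& divergent, int& depth_out) {
    sample_momentum(z.p);
    const double H0 = z.logp - kinetic(z.p);
    const double logu = H0 + std::log(unif_rand());
    State minus = z, plus = z, current = z;
    int n_valid = 1, depth = 0;
    bool keep_going = true;
    divergent = false;
    double alpha = 0.0;
    int n_alpha = 0;
    while (keep_going && depth < max_depth) {
      const int v = (unif_rand() < 0.5) ? -1 : 1;
      TreeResult sub;
      if (v == -1) {
        build_tree(minus, logu, v, depth, H0, sub);
        minus = sub.minus;
      } else {
        build_tree(plus, logu, v, depth, H0, sub);
        plus = sub.plus;
      }
      if (sub.keep_going && sub.n_valid > 0 &&
          unif_rand() * n_valid < sub.n_valid)
        current = sub.prop;
      n_valid += sub.n_valid;
      divergent = divergent || sub.divergent;
      keep_going = sub.keep_going && no_uturn(minus, plus);
      alpha = sub.alpha;
      n_alpha = sub.n_alpha;
      ++depth;
    }
    z.q = current.q;
    z.g = current.g;
    z.logp = current.logp;
    depth_out = depth;
    return n_alpha > 0 ? alpha / n_alpha : 0.0;
  }

  void find_reasonable_epsilon(const State& z0) {
    eps = 1.0;
    State z = z0;
    sample_momentum(z.p);
    const double H0 = z.logp - kinetic(z.p);
    State z1 = z;
    double H = leapfrog(z1, 1);
    int tries = 0;
    while (!std::isfinite(H) && tries++ < 50) {
      eps *= 0.5;
      z1 = z;
      H = leapfrog(z1, 1);
    }
    if (!std::isfinite(H)) { eps = 1e-3; return; }
    const double a = (H - H0 > std::log(0.5)) ? 1.0 : -1.0;
    tries = 0;
    while (a * (H - H0) > -a * std::log(2.0) && tries++ < 60) {
      eps *= std::pow(2.0, a);
      z1 = z;
      H = leapfrog(z1, 1);
      if (!std::isfinite(H)) { eps *= 0.5; break; }
    }
    eps = std::min(std::max(eps, 1e-8), 10.0);
  }
};

// Welford accumulator for the diagonal mass matrix
struct Welford {
  int n = 0;
  std::vector<double> mean, m2;
  explicit Welford(int d) : mean(d, 0.0), m2(d, 0.0) {}
  void add(const std::vector<double>& x) {
    ++n;
    for (size_t i = 0; i < mean.size(); ++i) {
      const double delta = x[i] - mean[i];
      mean[i] += delta / n;
      m2[i] += delta * (x[i] - mean[i]);
    }
  }
  void reset() { n = 0; std::fill(mean.begin(), mean.end(), 0.0);
                 std::fill(m2.begin(), m2.end(), 0.0); }
};

static List run_nuts(const Model& model, const NumericVector& init,
                     int n_warmup, int n_draws, double target_accept,
                     int max_depth) {
  const int d = model.dim();
  if (init.size() != d) stop("init has wrong length");
  Engine eng(model, target_accept, max_depth);

  State z;
  z.q.assign(init.begin(), init.end());
  z.p.assign(d, 0.0);
  z.g.assign(d, 0.0);
  z.logp = model.logp_grad(z.q, z.g);
  if (!std::isfinite(z.logp)) stop("initial point has non-finite density");

  eng.find_reasonable_epsilon(z);

  // dual averaging state
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  double mu = std::log(10.0 * eng.eps), log_eps_bar = 0.0, h_bar = 0.0;
  int da_count = 0;

  // Stan-style warmup windows for mass adaptation
  int init_buf = 75, term_buf = 50, base_win = 25;
  if (init_buf + term_buf + base_win > n_warmup) {
    init_buf = (int)(0.15 * n_warmup);
    term_buf = (int)(0.10 * n_warmup);
    base_win = std::max(0, n_warmup - init_buf - term_buf);
  }
  std::vector<int> window_ends;
  {
    int pos = init_buf, win = base_win;
    while (base_win > 0 && pos + win < n_warmup - term_buf) {
      window_ends.push_back(pos + win);
      pos += win;
      win *= 2;
    }
    if (base_win > 0) window_ends.push_back(n_warmup - term_buf);
  }
  Welford wf(d);

  NumericMatrix draws(n_draws, d);
  IntegerVector divergences(n_warmup + n_draws);
  IntegerVector depths(n_warmup + n_draws);
  size_t wi = 0;

  for (int it = 0; it < n_warmup + n_draws; ++it) {
    bool divergent = false;
    int depth = 0;
    const double alpha = eng.transition(z, divergent, depth);
    divergences[it] = divergent ? 1 : 0;
    depths[it] = depth;

    if (it < n_warmup) {
      // dual averaging
      ++da_count;
      const double frac = 1.0 / (da_count + t0);
      h_bar = (1.0 - frac) * h_bar + frac * (target_accept - alpha);
      const double log_eps = mu - std::sqrt((double)da_count) / gamma * h_bar;
      const double eta = std::pow((double)da_count, -kappa);
      log_eps_bar = eta * log_eps + (1.0 - eta) * log_eps_bar;
      eng.eps = std::exp(log_eps);

      // mass-matrix accumulation in the middle windows
      if (it >= init_buf && it < n_warmup - term_buf) wf.add(z.q);
      if (wi < window_ends.size() && it + 1 == window_ends[wi]) {
        if (wf.n > 1) {
          for (int k = 0; k < d; ++k) {
            const double var = wf.m2[k] / (wf.n - 1);
            eng.inv_mass[k] = (double)wf.n / (wf.n + 5.0) * var +
                              1e-3 * 5.0 / (wf.n + 5.0);
          }
        }
        wf.reset();
        ++wi;
        // restart step-size adaptation around the current value
        eng.find_reasonable_epsilon(z);
        mu = std::log(10.0 * eng.eps);
        h_bar = 0.0;
        log_eps_bar = std::log(eng.eps);
        da_count = 0;
      }
      if (it + 1 == n_warmup) eng.eps = std::exp(log_eps_bar);
    } else {
      std::copy(z.q.begin(), z.q.end(), draws(it - n_warmup, _).begin());
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws,
                      _["divergences"] = divergences,
                      _["treedepth"] = depths,
                      _["step_size"] = eng.eps,
                      _["n_grad"] = (double)eng.n_grad);
}

// [[Rcpp::export(name = ".flow_logp_grad")]]
List flow_logp_grad(NumericVector theta, IntegerVector y, List priors) {
  FlowModel m(y, priors);
  if (theta.size() != m.dim()) stop("theta has wrong length");
  std::vector<double> q(theta.begin(), theta.end()), g(m.dim(), 0.0);
  const double lp = m.logp_grad(q, g);
  return List::create(_["logp"] = lp, _["grad"] = NumericVector(g.begin(),
                                                                g.end()));
}

// [[Rcpp::export(name = ".nuts_flow_chain")]]
List nuts_flow_chain(IntegerVector y, List priors, NumericVector init,
                     int n_warmup, int n_draws, double target_accept,
                     int max_treedepth) {
  FlowModel m(y, priors);
  return run_nuts(m, init, n_warmup, n_draws, target_accept, max_treedepth);
}

// [[Rcpp::export(name = ".nuts_rho_chain")]]
List nuts_rho_chain(NumericVector lambda, double sigma, double nu,
                    double rho_sd, NumericVector init, int n_warmup,
                    int n_draws, double target_accept, int max_treedepth) {
  RhoModel m(lambda, sigma, nu, rho_sd);
  return run_nuts(m, init, n_warmup, n_draws, target_accept, max_treedepth);
}

// [[Rcpp::export(name = ".rho_logp_grad")]]
List rho_logp_grad(double rho, NumericVector lambda, double sigma, double nu,
                   double rho_sd) {
  RhoModel m(lambda, sigma, nu, rho_sd);
  std::vector<double> q(1, rho), g(1, 0.0);
  const double lp = m.logp_grad(q, g);
  return List::create(_["logp"] = lp, _["grad"] = g[0]);
}
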