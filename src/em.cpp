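// EM for univariate heteroscedastic Gaussian mixtures: the inner loop of the
// per-gene expression partitioning. Restart seeding stays on the R side (a
// matrix of pre-drawn uniforms), so results are fully reproducible from the
// R random number generator; the only randomness consumed here is inverse-CDF
// sampling of those uniforms for k-means++ style center picks.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093453;

// inverse-CDF pick from unnormalized weights
static int weighted_pick(const std::vector<double>& wgt, double total, double u) {
  double acc = 0.0;
  for (size_t i = 0; i < wgt.size(); ++i) {
    acc += wgt[i];
    if (u * total <= acc) return (int)i;
  }
  return (int)wgt.size() - 1;
}

// k-means++ seeding over x using one row of uniforms
static std::vector<double> seed_centers(const NumericVector& x, int k,
                                        const NumericVector& u) {
  int n = x.size();
  std::vector<double> centers(k);
  int first = std::min((int)(u[0] * n), n - 1);
  centers[0] = x[first];
  std::vector<double> d2(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = x[i] - centers[0];
    d2[i] = d * d;
    total += d2[i];
  }
  for (int j = 1; j < k; ++j) {
    int pick = total > 0 ? weighted_pick(d2, total, u[j])
                         : std::min((int)(u[j] * n), n - 1);
    centers[j] = x[pick];
    total = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = x[i] - centers[j];
      double dd = d * d;
      if (dd < d2[i]) d2[i] = dd;
      total += d2[i];
    }
  }
  return centers;
}

struct EmResult {
  std::vector<double> mu, sigma2, w;
  double loglik;
  int iters;
};

// one EM run; a collapsed component is re-seeded at the data point farthest
// from the surviving means (deterministic)
static EmResult em_run(const NumericVector& x, int k, std::vector<double> mu,
                       double var0, double var_floor, double tol,
                       int max_iter,
                       const std::vector<double>* sigma2_init = nullptr,
                       const std::vector<double>* w_init = nullptr) {
  int n = x.size();
  std::vector<double> sigma2 = sigma2_init ? *sigma2_init
    : std::vector<double>(k, std::max(var0, var_floor));
  std::vector<double> w = w_init ? *w_init : std::vector<double>(k, 1.0 / k);
  std::vector<double> resp(n * k);
  double ll = -INFINITY, ll_old = -INFINITY;
  int iter = 0;
  std::vector<double> lconst(k), inv2s(k);
  for (iter = 1; iter <= max_iter; ++iter) {
    // E step with log-sum-exp; per-component constants hoisted out of the
    // point loop (the transcendental calls dominate the running time)
    for (int j = 0; j < k; ++j) {
      lconst[j] = std::log(w[j]) - 0.5 * (LOG_2PI + std::log(sigma2[j]));
      inv2s[j] = 0.5 / sigma2[j];
    }
    ll = 0.0;
    std::vector<double> nk(k, 0.0);
    for (int i = 0; i < n; ++i) {
      double mx = -INFINITY;
      for (int j = 0; j < k; ++j) {
        double d = x[i] - mu[j];
        double ld = lconst[j] - d * d * inv2s[j];
        resp[i * k + j] = ld;
        if (ld > mx) mx = ld;
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += std::exp(resp[i * k + j] - mx);
      double lse = mx + std::log(s);
      ll += lse;
      for (int j = 0; j < k; ++j) {
        resp[i * k + j] = std::exp(resp[i * k + j] - lse);
        nk[j] += resp[i * k + j];
      }
    }
    // collapsed component: re-seed at the farthest point and restart stats
    bool dead = false;
    for (int j = 0; j < k; ++j) {
      if (nk[j] < 1e-8) {
        int far_i = 0; double far_d = -1.0;
        for (int i = 0; i < n; ++i) {
          double mind = INFINITY;
          for (int jj = 0; jj < k; ++jj) {
            if (jj == j) continue;
            double d = std::fabs(x[i] - mu[jj]);
            if (d < mind) mind = d;
          }
          if (mind > far_d) { far_d = mind; far_i = i; }
        }
        mu[j] = x[far_i];
        sigma2[j] = std::max(var0, var_floor);
        w[j] = 1.0 / n;
        dead = true;
      }
    }
    if (dead) {
      double sw = 0.0;
      for (int j = 0; j < k; ++j) sw += w[j];
      for (int j = 0; j < k; ++j) w[j] /= sw;
      ll_old = -INFINITY;
      continue;
    }
    // M step
    for (int j = 0; j < k; ++j) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += resp[i * k + j] * x[i];
      m /= nk[j];
      double v = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - m;
        v += resp[i * k + j] * d * d;
      }
      v /= nk[j];
      mu[j] = m;
      sigma2[j] = std::max(v, var_floor);
      w[j] = nk[j] / n;
    }
    if (std::isfinite(ll_old) &&
        std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + tol)) break;
    ll_old = ll;
  }
  // log-likelihood consistent with the returned (post-M-step) parameters
  double ll_final = 0.0;
  for (int j = 0; j < k; ++j) {
    lconst[j] = std::log(w[j]) - 0.5 * (LOG_2PI + std::log(sigma2[j]));
    inv2s[j] = 0.5 / sigma2[j];
  }
  std::vector<double> ld(k);
  for (int i = 0; i < n; ++i) {
    double mx = -INFINITY;
    for (int j = 0; j < k; ++j) {
      double d = x[i] - mu[j];
      ld[j] = lconst[j] - d * d * inv2s[j];
      if (ld[j] > mx) mx = ld[j];
    }
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::exp(ld[j] - mx);
    ll_final += mx + std::log(s);
  }
  EmResult out;
  out.mu = mu; out.sigma2 = sigma2; out.w = w;
  out.loglik = ll_final; out.iters = iter;
  return out;
}

// [[Rcpp::export(name = ".gmm_em_best")]]
List gmm_em_best(NumericVector x, int k, NumericMatrix u, double var0,
                 double var_floor, double tol, int max_iter) {
  // restarts run at a coarser tolerance to find the basin; only the best
  // restart is polished to the full convergence tolerance
  double coarse = tol * 100.0;
  EmResult best;
  best.loglik = -INFINITY;
  for (int r = 0; r < u.nrow(); ++r) {
    NumericVector row = u(r, _);
    std::vector<double> centers = seed_centers(x, k, row);
    EmResult res = em_run(x, k, centers, var0, var_floor, coarse, max_iter);
    if (res.loglik > best.loglik) best = res;
  }
  EmResult polished = em_run(x, k, best.mu, var0, var_floor, tol, max_iter,
                             &best.sigma2, &best.w);
  if (polished.loglik < best.loglik) polished = best;  // never lose ground
  return List::create(_["mu"] = polished.mu, _["sigma2"] = polished.sigma2,
                      _["w"] = polished.w, _["loglik"] = polished.loglik,
                      _["iters"] = polished.iters);
}
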