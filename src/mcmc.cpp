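// Metropolis-within-Gibbs sampler for the autologistic dynamic occupancy
// model: Gibbs updates for the latent occupancy lattice z (cells x years),
// adaptive random-walk Metropolis for every coefficient block. Uses R's RNG
// so chains are reproducible from R-side seeds.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logplogis(double x) {
  // log(plogis(x)), stable for large |x|
  if (x < -33.0) return x;
  return -log1p(std::exp(-x));
}
static inline double plogis_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Sampler {
  int n, T, J;
  std::vector<int> adj_ptr, adj_idx;
  // observations grouped by cell-year q = i + n*t
  std::vector<int> obs_ptr, obs_week, obs_y;
  // observations grouped by week-year key j + J*t (for alpha_p updates)
  std::vector<int> wobs_ptr, wobs_cell, wobs_y;
  std::vector<int> surveyed, has_det;
  std::vector<double> count_std, pdsi, cu, herb, dev, hay;
  bool dyn_auto, det_weekly;
  double coef_sd, sig_sd;

  // parameter state
  double a_psi, bp, sigp;
  std::vector<double> b_psi, ae, be, ag, bg, ap; // ap: J*T (weekly) or 1
  std::vector<int> z;       // n*T
  std::vector<double> ll1;  // detection loglik per cell-year given z = 1
  std::vector<double> th;   // cached neighbor counts, valid after recompute_theta

  double ap_of(int j, int t) const { return det_weekly ? ap[j + J * t] : ap[0]; }

  double eta_psi(int i) const {
    return a_psi + b_psi[0] * herb[i] + b_psi[1] * dev[i] + b_psi[2] * hay[i] +
           b_psi[3] * cu[i];
  }
  // origin-year index t0 in 0..T-2; PDSI of the destination year t0+1
  double logit_eps(int i, int t0, double theta) const {
    double e = ae[t0];
    if (dyn_auto)
      e += be[0] * theta + be[1] * pdsi[i + n * (t0 + 1)] + be[2] * cu[i];
    return e;
  }
  double logit_gam(int i, int t0, double theta) const {
    double g = ag[t0];
    if (dyn_auto)
      g += bg[0] * theta + bg[1] * pdsi[i + n * (t0 + 1)] + bg[2] * cu[i];
    return g;
  }
  double theta_at(int i, int t) const {
    double s = 0;
    for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) s += z[adj_idx[k] + n * t];
    return s;
  }
  void recompute_theta() {
    for (int t = 0; t < T; ++t)
      for (int i = 0; i < n; ++i) th[i + n * t] = theta_at(i, t);
  }
  void update_ll1() {
    for (int t = 0; t < T; ++t)
      for (int i = 0; i < n; ++i) {
        int q = i + n * t;
        if (!surveyed[q]) { ll1[q] = 0; continue; }
        double s = 0;
        for (int k = obs_ptr[q]; k < obs_ptr[q + 1]; ++k) {
          double eta = ap_of(obs_week[k], t) + bp * count_std[q];
          s += obs_y[k] ? logplogis(eta) : logplogis(-eta);
        }
        ll1[q] = s;
      }
  }

  double fullcond_logodds(int i, int t) {
    int q = i + n * t;
    double lo = 0;
    if (t == 0) {
      lo += eta_psi(i);
    } else {
      double thv = theta_at(i, t - 1);
      if (z[i + n * (t - 1)]) {
        double e = logit_eps(i, t - 1, thv);
        lo += logplogis(-e) - logplogis(e);      // log(1-eps) - log(eps)
      } else {
        double g = logit_gam(i, t - 1, thv);
        lo += logplogis(g) - logplogis(-g);      // log(gam) - log(1-gam)
      }
    }
    if (t < T - 1) {
      double thv = theta_at(i, t);
      int zn = z[i + n * (t + 1)];
      double e = logit_eps(i, t, thv), g = logit_gam(i, t, thv);
      double l1 = zn ? logplogis(-e) : logplogis(e);
      double l0 = zn ? logplogis(g) : logplogis(-g);
      lo += l1 - l0;
      if (dyn_auto) {
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
          int nb = adj_idx[k];
          double thex = theta_at(nb, t) - z[q];
          int znb = z[nb + n * t], znn = z[nb + n * (t + 1)];
          double la, lb;
          if (znb) {
            double e1 = logit_eps(nb, t, thex + 1), e0 = logit_eps(nb, t, thex);
            la = znn ? logplogis(-e1) : logplogis(e1);
            lb = znn ? logplogis(-e0) : logplogis(e0);
          } else {
            double g1 = logit_gam(nb, t, thex + 1), g0 = logit_gam(nb, t, thex);
            la = znn ? logplogis(g1) : logplogis(-g1);
            lb = znn ? logplogis(g0) : logplogis(-g0);
          }
          lo += la - lb;
        }
      }
    }
    if (surveyed[q]) lo += ll1[q]; // detection contributes 0 when z = 0
    return lo;
  }

  // likelihood pieces for Metropolis updates ------------------------------
  double ll_init() const {
    double s = 0;
    for (int i = 0; i < n; ++i) {
      double eta = eta_psi(i);
      s += z[i] ? logplogis(eta) : logplogis(-eta);
    }
    return s;
  }
  double ll_eps_year(int t0) const {
    double s = 0;
    for (int i = 0; i < n; ++i) {
      if (!z[i + n * t0]) continue;
      double e = logit_eps(i, t0, th[i + n * t0]);
      s += z[i + n * (t0 + 1)] ? logplogis(-e) : logplogis(e);
    }
    return s;
  }
  double ll_gam_year(int t0) const {
    double s = 0;
    for (int i = 0; i < n; ++i) {
      if (z[i + n * t0]) continue;
      double g = logit_gam(i, t0, th[i + n * t0]);
      s += z[i + n * (t0 + 1)] ? logplogis(g) : logplogis(-g);
    }
    return s;
  }
  double ll_eps_all() const {
    double s = 0;
    for (int t0 = 0; t0 < T - 1; ++t0) s += ll_eps_year(t0);
    return s;
  }
  double ll_gam_all() const {
    double s = 0;
    for (int t0 = 0; t0 < T - 1; ++t0) s += ll_gam_year(t0);
    return s;
  }
  double ll_det_all() const {
    double s = 0;
    for (int t = 0; t < T; ++t)
      for (int i = 0; i < n; ++i) {
        int q = i + n * t;
        if (!surveyed[q] || !z[q]) continue;
        for (int k = obs_ptr[q]; k < obs_ptr[q + 1]; ++k) {
          double eta = ap_of(obs_week[k], t) + bp * count_std[q];
          s += obs_y[k] ? logplogis(eta) : logplogis(-eta);
        }
      }
    return s;
  }
  double ll_det_week(int j, int t) const {
    double s = 0;
    int key = j + J * t;
    for (int k = wobs_ptr[key]; k < wobs_ptr[key + 1]; ++k) {
      int i = wobs_cell[k], q = i + n * t;
      if (!z[q]) continue;
      double eta = ap_of(j, t) + bp * count_std[q];
      s += wobs_y[k] ? logplogis(eta) : logplogis(-eta);
    }
    return s;
  }
};

struct Adapt {
  std::vector<double> scale;
  std::vector<double> acc_sum;
  std::vector<int> acc_n;
  double target;
  bool on;
  void bump(int k, double acc, int iter) {
    acc_sum[k] += acc; acc_n[k] += 1;
    if (!on) return;
    double step = 2.0 * std::pow(iter + 10.0, -0.6);
    scale[k] *= std::exp(step * (acc - target));
    if (scale[k] < 1e-4) scale[k] = 1e-4;
    if (scale[k] > 50.0) scale[k] = 50.0;
  }
};

// generic scalar RW step: delta = (new - old) log likelihood + prior delta
template <typename LL>
static void rw_step(double &par, int k, Adapt &ad, int iter, LL loglik,
                    double prior_sd) {
  double l0 = loglik();
  double old = par;
  par = old + ad.scale[k] * norm_rand();
  double d = loglik() - l0 - 0.5 * (par * par - old * old) / (prior_sd * prior_sd);
  double acc = d >= 0 ? 1.0 : std::exp(d);
  if (unif_rand() >= acc) par = old;
  ad.bump(k, acc, iter);
}

static Sampler build_sampler(const List &data) {
  Sampler S;
  S.n = as<int>(data["n"]); S.T = as<int>(data["T"]); S.J = as<int>(data["J"]);
  S.adj_ptr = as<std::vector<int>>(data["adj_ptr"]);
  S.adj_idx = as<std::vector<int>>(data["adj_idx"]);
  S.obs_ptr = as<std::vector<int>>(data["obs_ptr"]);
  S.obs_week = as<std::vector<int>>(data["obs_week"]);
  S.obs_y = as<std::vector<int>>(data["obs_y"]);
  S.wobs_ptr = as<std::vector<int>>(data["wobs_ptr"]);
  S.wobs_cell = as<std::vector<int>>(data["wobs_cell"]);
  S.wobs_y = as<std::vector<int>>(data["wobs_y"]);
  S.surveyed = as<std::vector<int>>(data["surveyed"]);
  S.has_det = as<std::vector<int>>(data["has_det"]);
  S.count_std = as<std::vector<double>>(data["count_std"]);
  S.pdsi = as<std::vector<double>>(data["pdsi"]);
  S.cu = as<std::vector<double>>(data["cu"]);
  S.herb = as<std::vector<double>>(data["herb"]);
  S.dev = as<std::vector<double>>(data["dev"]);
  S.hay = as<std::vector<double>>(data["hay"]);
  S.dyn_auto = as<bool>(data["dyn_auto"]);
  S.det_weekly = as<bool>(data["det_weekly"]);
  S.coef_sd = as<double>(data["coef_sd"]);
  S.sig_sd = as<double>(data["sig_sd"]);
  S.th.assign(S.n * S.T, 0.0);
  S.ll1.assign(S.n * S.T, 0.0);
  return S;
}

static void set_params(Sampler &S, const NumericVector &par) {
  int T = S.T, J = S.J, k = 0;
  S.a_psi = par[k++];
  S.b_psi.assign(4, 0.0);
  for (int i = 0; i < 4; ++i) S.b_psi[i] = par[k++];
  S.ae.assign(std::max(T - 1, 0), 0.0);
  for (int t = 0; t < T - 1; ++t) S.ae[t] = par[k++];
  S.be.assign(3, 0.0);
  for (int i = 0; i < 3; ++i) S.be[i] = par[k++];
  S.ag.assign(std::max(T - 1, 0), 0.0);
  for (int t = 0; t < T - 1; ++t) S.ag[t] = par[k++];
  S.bg.assign(3, 0.0);
  for (int i = 0; i < 3; ++i) S.bg[i] = par[k++];
  S.bp = par[k++];
  S.sigp = par[k++];
  int nap = S.det_weekly ? J * T : 1;
  S.ap.assign(nap, 0.0);
  for (int i = 0; i < nap; ++i) S.ap[i] = par[k++];
}

static int n_par(const Sampler &S) {
  return 1 + 4 + 2 * std::max(S.T - 1, 0) + 6 + 2 + (S.det_weekly ? S.J * S.T : 1);
}

static void get_params(const Sampler &S, double *row) {
  int k = 0;
  row[k++] = S.a_psi;
  for (int i = 0; i < 4; ++i) row[k++] = S.b_psi[i];
  for (int t = 0; t < S.T - 1; ++t) row[k++] = S.ae[t];
  for (int i = 0; i < 3; ++i) row[k++] = S.be[i];
  for (int t = 0; t < S.T - 1; ++t) row[k++] = S.ag[t];
  for (int i = 0; i < 3; ++i) row[k++] = S.bg[i];
  row[k++] = S.bp;
  row[k++] = S.sigp;
  for (size_t i = 0; i < S.ap.size(); ++i) row[k++] = S.ap[i];
}

// [[Rcpp::export]]
List run_chain_cpp(List data, NumericVector init_params, IntegerVector init_z,
                   List cfg) {
  RNGScope scope;
  Sampler S = build_sampler(data);
  set_params(S, init_params);
  S.z = as<std::vector<int>>(init_z);

  int n_iter = as<int>(cfg["n_iter"]), n_burnin = as<int>(cfg["n_burnin"]);
  int stride = as<int>(cfg["stride"]), n_keep = as<int>(cfg["n_keep"]);
  bool adapt = as<bool>(cfg["adapt"]), fix_params = as<bool>(cfg["fix_params"]);
  double target = as<double>(cfg["target_accept"]);
  double init_scale = as<double>(cfg["init_scale"]);

  int np = n_par(S);
  Adapt ad;
  ad.target = target;
  ad.scale.assign(np, init_scale);
  ad.acc_sum.assign(np, 0.0);
  ad.acc_n.assign(np, 0);

  // updatable z entries (not pinned by a detection)
  std::vector<int> order;
  for (int q = 0; q < S.n * S.T; ++q) {
    if (S.has_det[q]) S.z[q] = 1; else order.push_back(q);
  }

  NumericMatrix par_out(n_keep, np);
  IntegerMatrix z_out(n_keep, S.n * S.T);
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    ad.on = adapt && iter <= n_burnin;
    S.update_ll1();

    // random-order Gibbs sweep over latent states
    for (int m = (int)order.size() - 1; m > 0; --m) {
      int r = (int)std::floor(unif_rand() * (m + 1));
      std::swap(order[m], order[r]);
    }
    for (size_t m = 0; m < order.size(); ++m) {
      int q = order[m], i = q % S.n, t = q / S.n;
      double lo = S.fullcond_logodds(i, t);
      S.z[q] = (unif_rand() < plogis_(lo)) ? 1 : 0;
    }
    S.recompute_theta();

    if (!fix_params) {
      int k = 0;
      rw_step(S.a_psi, k++, ad, iter, [&] { return S.ll_init(); }, S.coef_sd);
      for (int c = 0; c < 4; ++c)
        rw_step(S.b_psi[c], k++, ad, iter, [&] { return S.ll_init(); }, S.coef_sd);
      for (int t0 = 0; t0 < S.T - 1; ++t0)
        rw_step(S.ae[t0], k++, ad, iter, [&] { return S.ll_eps_year(t0); }, S.coef_sd);
      for (int c = 0; c < 3; ++c) {
        if (S.dyn_auto)
          rw_step(S.be[c], k++, ad, iter, [&] { return S.ll_eps_all(); }, S.coef_sd);
        else k++;
      }
      for (int t0 = 0; t0 < S.T - 1; ++t0)
        rw_step(S.ag[t0], k++, ad, iter, [&] { return S.ll_gam_year(t0); }, S.coef_sd);
      for (int c = 0; c < 3; ++c) {
        if (S.dyn_auto)
          rw_step(S.bg[c], k++, ad, iter, [&] { return S.ll_gam_all(); }, S.coef_sd);
        else k++;
      }
      rw_step(S.bp, k++, ad, iter, [&] { return S.ll_det_all(); }, S.coef_sd);

      // sigma_p: random walk on log scale (weekly model only)
      if (S.det_weekly) {
        double l0 = 0, lsig = std::log(S.sigp);
        for (int t = 0; t < S.T; ++t)
          for (int j = 1; j < S.J; ++j)
            l0 += R::dnorm(S.ap[j + S.J * t], S.ap[j - 1 + S.J * t], S.sigp, 1);
        double lnew = lsig + ad.scale[k] * norm_rand();
        double snew = std::exp(lnew), l1 = 0;
        for (int t = 0; t < S.T; ++t)
          for (int j = 1; j < S.J; ++j)
            l1 += R::dnorm(S.ap[j + S.J * t], S.ap[j - 1 + S.J * t], snew, 1);
        double d = l1 - l0 -
                   0.5 * (snew * snew - S.sigp * S.sigp) / (S.sig_sd * S.sig_sd) +
                   (lnew - lsig); // half-normal prior + log-scale Jacobian
        double acc = d >= 0 ? 1.0 : std::exp(d);
        if (unif_rand() < acc) S.sigp = snew;
        ad.bump(k, acc, iter);
      }
      k++;

      // weekly detection intercepts with AR(1) prior along weeks
      if (S.det_weekly) {
        for (int t = 0; t < S.T; ++t)
          for (int j = 0; j < S.J; ++j) {
            int idx = j + S.J * t;
            double prior0 = (j == 0)
              ? R::dnorm(S.ap[idx], 0.0, S.coef_sd, 1)
              : R::dnorm(S.ap[idx], S.ap[idx - 1], S.sigp, 1);
            if (j + 1 < S.J) prior0 += R::dnorm(S.ap[idx + 1], S.ap[idx], S.sigp, 1);
            double l0 = S.ll_det_week(j, t) + prior0;
            double old = S.ap[idx];
            S.ap[idx] = old + ad.scale[k] * norm_rand();
            double prior1 = (j == 0)
              ? R::dnorm(S.ap[idx], 0.0, S.coef_sd, 1)
              : R::dnorm(S.ap[idx], S.ap[idx - 1], S.sigp, 1);
            if (j + 1 < S.J) prior1 += R::dnorm(S.ap[idx + 1], S.ap[idx], S.sigp, 1);
            double d = S.ll_det_week(j, t) + prior1 - l0;
            double acc = d >= 0 ? 1.0 : std::exp(d);
            if (unif_rand() >= acc) S.ap[idx] = old;
            ad.bump(k, acc, iter);
            k++;
          }
      } else {
        rw_step(S.ap[0], k++, ad, iter, [&] { return S.ll_det_all(); }, S.coef_sd);
      }
    }

    if (iter > n_burnin && stride > 0 && (iter - n_burnin) % stride == 0 &&
        kept < n_keep) {
      std::vector<double> rowbuf(np);
      get_params(S, rowbuf.data());
      for (int c = 0; c < np; ++c) par_out(kept, c) = rowbuf[c];
      for (int q = 0; q < S.n * S.T; ++q) z_out(kept, q) = S.z[q];
      ++kept;
    }
    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_rate(np);
  for (int k = 0; k < np; ++k)
    acc_rate[k] = ad.acc_n[k] ? ad.acc_sum[k] / ad.acc_n[k] : NA_REAL;

  return List::create(_["params"] = par_out, _["z"] = z_out, _["kept"] = kept,
                      _["accept"] = acc_rate,
                      _["scales"] = NumericVector(ad.scale.begin(), ad.scale.end()));
}

// [[Rcpp::export]]
double fullcond_z_cpp(List data, NumericVector params, IntegerVector z, int cell,
                      int year) {
  Sampler S = build_sampler(data);
  set_params(S, params);
  S.z = as<std::vector<int>>(z);
  int q = (cell - 1) + S.n * (year - 1);
  if (S.has_det[q]) return 1.0;
  S.update_ll1();
  return plogis_(S.fullcond_logodds(cell - 1, year - 1));
}
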