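// Adaptive Metropolis-within-Gibbs sampler for convolution (BYM) regression:
//   logistic or cumulative-logit outcome,
//   exchangeable Normal neighborhood effect u,
//   intrinsic CAR (ICAR) neighborhood effect v with sum-to-zero recentering,
//   optional extra exchangeable random intercept w (second grouping level,
//   used by the 3-level ecometric model where it indexes individuals).
//
// Priors: beta, cutpoints ~ N(0, beta_prior_sd^2); SD parameters half-Normal.
// Proposal scales adapt toward 0.44 acceptance during burn-in only.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log1p_exp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double plogis_c(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

struct Model {
  const IntegerVector &y;   // binary 0/1 or ordinal 1..K
  bool ordinal;
  int K;
  std::vector<double> kappa; // K-1 cutpoints (ordinal only)

  Model(const IntegerVector &y_, bool ord_, int K_) : y(y_), ordinal(ord_), K(K_) {}

  // log-likelihood of observation i at linear predictor eta
  double ll(int i, double eta) const {
    if (!ordinal) {
      return (y[i] == 1 ? eta : 0.0) - log1p_exp(eta);
    }
    int c = y[i]; // 1..K
    if (c == 1) {
      return -log1p_exp(eta - kappa[0]); // log F(kappa_1 - eta)
    }
    if (c == K) {
      return -log1p_exp(kappa[K - 2] - eta); // log (1 - F(kappa_{K-1} - eta))
    }
    double b = kappa[c - 1] - eta;
    double a = kappa[c - 2] - eta;
    double p = plogis_c(b) - plogis_c(a);
    if (p < 1e-300) p = 1e-300;
    return std::log(p);
  }
};

// batch adaptation of a log proposal scale toward 0.44 acceptance
struct Adapt {
  std::vector<double> ls;      // log scales
  std::vector<int> acc, tot;
  int batch_size, batch_no;
  Adapt(int k, double init_ls = 0.0)
      : ls(k, init_ls), acc(k, 0), tot(k, 0), batch_size(50), batch_no(0) {}
  double scale(int k) const { return std::exp(ls[k]); }
  void record(int k, bool accepted) {
    tot[k]++;
    if (accepted) acc[k]++;
  }
  void maybe_adapt() {
    if (tot.empty() || tot[0] < batch_size) return;
    batch_no++;
    double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
    for (size_t k = 0; k < ls.size(); ++k) {
      double rate = tot[k] > 0 ? (double)acc[k] / tot[k] : 0.44;
      ls[k] += (rate > 0.44 ? delta : -delta);
      if (ls[k] > 5) ls[k] = 5;
      if (ls[k] < -8) ls[k] = -8;
      acc[k] = 0;
      tot[k] = 0;
    }
  }
};

// group membership index lists
static void build_members(const IntegerVector &g, int G,
                          std::vector<int> &idx, std::vector<int> &start) {
  int n = g.size();
  std::vector<int> cnt(G, 0);
  for (int i = 0; i < n; ++i) cnt[g[i]]++;
  start.assign(G + 1, 0);
  for (int j = 0; j < G; ++j) start[j + 1] = start[j] + cnt[j];
  idx.assign(n, 0);
  std::vector<int> pos(start.begin(), start.end() - 1);
  for (int i = 0; i < n; ++i) idx[pos[g[i]]++] = i;
}

// [[Rcpp::export]]
List bym_mcmc_cpp(IntegerVector y, NumericMatrix X, IntegerVector nbhd, int J,
                  IntegerVector indiv, int M, IntegerVector adj,
                  IntegerVector adj_start, bool ordinal, int K, bool use_u,
                  bool use_v, bool use_w, int intercept_col,
                  double beta_prior_sd, double sigma_u_scale,
                  double tau_v_scale, double sigma_w_scale, int n_iter,
                  int n_burnin, int thin) {
  RNGScope scope;
  const int n = y.size();
  const int p = X.ncol();
  const int n_kappa = ordinal ? K - 1 : 0;

  Model mod(y, ordinal, K);

  // state
  std::vector<double> beta(p, 0.0), b(J, 0.0), v(J, 0.0), w(M, 0.0);
  double sigma_u = use_u ? 0.5 * sigma_u_scale : 0.0;
  double tau_v = use_v ? 0.5 * tau_v_scale : 0.0;
  double sigma_w = use_w ? 0.5 * sigma_w_scale : 0.0;
  if (use_u && sigma_u <= 0) sigma_u = 0.1;
  if (use_v && tau_v <= 0) tau_v = 0.1;
  if (use_w && sigma_w <= 0) sigma_w = 0.1;

  // initialize cutpoints from empirical cumulative proportions
  if (ordinal) {
    std::vector<double> cum(K, 0.0);
    for (int i = 0; i < n; ++i) cum[y[i] - 1] += 1.0;
    double acc = 0;
    mod.kappa.resize(n_kappa);
    for (int c = 0; c < n_kappa; ++c) {
      acc += cum[c];
      double pr = std::min(std::max(acc / n, 1e-3), 1.0 - 1e-3);
      mod.kappa[c] = std::log(pr / (1.0 - pr));
      if (c > 0 && mod.kappa[c] <= mod.kappa[c - 1])
        mod.kappa[c] = mod.kappa[c - 1] + 1e-3;
    }
  }

  // linear predictor
  std::vector<double> eta(n, 0.0);

  std::vector<int> memb_idx, memb_start;   // by neighborhood
  build_members(nbhd, J, memb_idx, memb_start);
  std::vector<int> wmemb_idx, wmemb_start; // by individual (second grouping)
  if (use_w) build_members(indiv, M, wmemb_idx, wmemb_start);

  // degrees
  std::vector<int> deg(J, 0);
  for (int j = 0; j < J; ++j) deg[j] = adj_start[j + 1] - adj_start[j];

  // adaptation
  Adapt a_beta(p, std::log(0.1));
  Adapt a_kappa(std::max(n_kappa, 1), std::log(0.05));
  Adapt a_u(use_u ? J : 1, std::log(0.3));
  Adapt a_v(use_v ? J : 1, std::log(0.3));
  Adapt a_w(use_w ? M : 1, std::log(0.5));
  Adapt a_sig(3, std::log(0.3));  // sigma_u, tau_v, sigma_w on log scale
  Adapt a_resc(3, std::log(0.2)); // interweaving rescale moves

  const int n_save = (n_iter - n_burnin) / thin;
  NumericMatrix beta_draws(n_save, p);
  NumericMatrix kappa_draws(n_save, std::max(n_kappa, 1));
  NumericVector sigma_u_draws(n_save), tau_v_draws(n_save), sigma_w_draws(n_save);
  NumericMatrix u_draws(n_save, use_u ? J : 1);
  NumericMatrix v_draws(n_save, use_v ? J : 1);
  std::vector<double> w_mean(M, 0.0), u_mean(J, 0.0);
  int saved = 0;

  const double beta_prec = 1.0 / (beta_prior_sd * beta_prior_sd);

  // per-category observation lists (ordinal cutpoint updates)
  std::vector<std::vector<int> > by_cat;
  if (ordinal) {
    by_cat.assign(K, std::vector<int>());
    for (int i = 0; i < n; ++i) by_cat[y[i] - 1].push_back(i);
  }

  for (int iter = 0; iter < n_iter; ++iter) {
    bool adapting = iter < n_burnin;

    // ---- fixed effects ----
    for (int k = 0; k < p; ++k) {
      double d = norm_rand() * a_beta.scale(k);
      double lr = 0.0;
      for (int i = 0; i < n; ++i) {
        double xd = X(i, k) * d;
        if (xd != 0.0) lr += mod.ll(i, eta[i] + xd) - mod.ll(i, eta[i]);
      }
      double b0 = beta[k], b1 = beta[k] + d;
      lr += -0.5 * beta_prec * (b1 * b1 - b0 * b0);
      bool ok = std::log(unif_rand()) < lr;
      if (ok) {
        beta[k] = b1;
        for (int i = 0; i < n; ++i) eta[i] += X(i, k) * d;
      }
      if (adapting) a_beta.record(k, ok);
    }

    // ---- cutpoints ----
    if (ordinal) {
      for (int c = 0; c < n_kappa; ++c) {
        double prop = mod.kappa[c] + norm_rand() * a_kappa.scale(c);
        bool valid = (c == 0 || prop > mod.kappa[c - 1]) &&
                     (c == n_kappa - 1 || prop < mod.kappa[c + 1]);
        bool ok = false;
        if (valid) {
          double old = mod.kappa[c];
          double lr = -0.5 * beta_prec * (prop * prop - old * old);
          // only categories c+1 and c+2 (1-based) involve kappa_c
          for (size_t s = 0; s < by_cat[c].size(); ++s) {
            int i = by_cat[c][s];
            lr -= mod.ll(i, eta[i]);
          }
          for (size_t s = 0; s < by_cat[c + 1].size(); ++s) {
            int i = by_cat[c + 1][s];
            lr -= mod.ll(i, eta[i]);
          }
          mod.kappa[c] = prop;
          for (size_t s = 0; s < by_cat[c].size(); ++s) {
            int i = by_cat[c][s];
            lr += mod.ll(i, eta[i]);
          }
          for (size_t s = 0; s < by_cat[c + 1].size(); ++s) {
            int i = by_cat[c + 1][s];
            lr += mod.ll(i, eta[i]);
          }
          ok = std::log(unif_rand()) < lr;
          if (!ok) mod.kappa[c] = old;
        }
        if (adapting) a_kappa.record(c, ok);
      }
    }

    // ---- neighborhood effects: hierarchically centered convolution ----
    // The total effect b_j = u_j + v_j faces the likelihood with prior
    // N(v_j, sigma_u^2); the ICAR field v_j is then conjugate given b and is
    // drawn exactly. This parametrization avoids the slow u/v mixing of the
    // non-centered convolution model.
    if (use_u || use_v) {
      double su2 = sigma_u * sigma_u;
      double tv2 = tau_v * tau_v;
      for (int j = 0; j < J; ++j) {
        double d = norm_rand() * a_u.scale(j);
        double b0 = b[j], b1 = b[j] + d;
        double lr;
        if (use_u) {
          double mu = use_v ? v[j] : 0.0;
          lr = -0.5 * ((b1 - mu) * (b1 - mu) - (b0 - mu) * (b0 - mu)) / su2;
        } else {
          // pure ICAR: b coincides with v, ICAR conditional prior
          if (deg[j] == 0) continue;
          double nbar = 0.0;
          for (int s = adj_start[j]; s < adj_start[j + 1]; ++s)
            nbar += b[adj[s]];
          nbar /= deg[j];
          lr = -0.5 * deg[j] *
               ((b1 - nbar) * (b1 - nbar) - (b0 - nbar) * (b0 - nbar)) / tv2;
        }
        for (int s = memb_start[j]; s < memb_start[j + 1]; ++s) {
          int i = memb_idx[s];
          lr += mod.ll(i, eta[i] + d) - mod.ll(i, eta[i]);
        }
        bool ok = std::log(unif_rand()) < lr;
        if (ok) {
          b[j] = b1;
          for (int s = memb_start[j]; s < memb_start[j + 1]; ++s)
            eta[memb_idx[s]] += d;
        }
        if (adapting) a_u.record(j, ok);
      }

      // exact Gibbs draw of the ICAR field given b (likelihood untouched)
      if (use_u && use_v) {
        for (int j = 0; j < J; ++j) {
          if (deg[j] == 0) { v[j] = 0.0; continue; }
          double nbar = 0.0;
          for (int s = adj_start[j]; s < adj_start[j + 1]; ++s)
            nbar += v[adj[s]];
          nbar /= deg[j];
          double prec = deg[j] / tv2 + 1.0 / su2;
          double mean = (deg[j] / tv2 * nbar + b[j] / su2) / prec;
          v[j] = mean + norm_rand() / std::sqrt(prec);
        }
      } else if (use_v) {
        for (int j = 0; j < J; ++j) v[j] = b[j];
      }

      // recenter the ICAR field; the shift moves through b into the
      // intercept (binary) or the cutpoints (ordinal), leaving u = b - v
      // and the likelihood unchanged
      if (use_v) {
        double m = 0.0;
        for (int j = 0; j < J; ++j) m += v[j];
        m /= J;
        if (m != 0.0) {
          for (int j = 0; j < J; ++j) {
            v[j] -= m;
            b[j] -= m;
          }
          if (ordinal) {
            for (int c = 0; c < n_kappa; ++c) mod.kappa[c] -= m;
            for (int i = 0; i < n; ++i) eta[i] -= m;
          } else if (intercept_col >= 0) {
            beta[intercept_col] += m; // eta unchanged: +m via intercept, -m via b
          } else {
            for (int i = 0; i < n; ++i) eta[i] -= m;
          }
        }
      }
    }

    // ---- second-level exchangeable effects w ----
    if (use_w) {
      double sw2 = sigma_w * sigma_w;
      for (int m2 = 0; m2 < M; ++m2) {
        double d = norm_rand() * a_w.scale(m2);
        double w1 = w[m2] + d;
        double lr = -0.5 * (w1 * w1 - w[m2] * w[m2]) / sw2;
        for (int s = wmemb_start[m2]; s < wmemb_start[m2 + 1]; ++s) {
          int i = wmemb_idx[s];
          lr += mod.ll(i, eta[i] + d) - mod.ll(i, eta[i]);
        }
        bool ok = std::log(unif_rand()) < lr;
        if (ok) {
          w[m2] = w1;
          for (int s = wmemb_start[m2]; s < wmemb_start[m2 + 1]; ++s)
            eta[wmemb_idx[s]] += d;
        }
        if (adapting) a_w.record(m2, ok);
      }
    }

    // ---- variance parameters (log-scale random walks) ----
    if (use_u) {
      double ls0 = std::log(sigma_u);
      double ls1 = ls0 + norm_rand() * a_sig.scale(0);
      double s0 = sigma_u, s1 = std::exp(ls1);
      double ssu = 0.0;
      for (int j = 0; j < J; ++j) {
        double uj = b[j] - (use_v ? v[j] : 0.0);
        ssu += uj * uj;
      }
      double lr = -J * (ls1 - ls0) - 0.5 * ssu * (1.0 / (s1 * s1) - 1.0 / (s0 * s0)) -
                  0.5 * (s1 * s1 - s0 * s0) / (sigma_u_scale * sigma_u_scale) +
                  (ls1 - ls0); // Jacobian
      bool ok = std::log(unif_rand()) < lr;
      if (ok) sigma_u = s1;
      if (adapting) a_sig.record(0, ok);
    }
    if (use_v) {
      double sv = 0.0; // pairwise-difference sum, each edge twice
      for (int j = 0; j < J; ++j)
        for (int s = adj_start[j]; s < adj_start[j + 1]; ++s) {
          double dvi = v[j] - v[adj[s]];
          sv += dvi * dvi;
        }
      sv *= 0.5;
      double lt0 = std::log(tau_v);
      double lt1 = lt0 + norm_rand() * a_sig.scale(1);
      double t0 = tau_v, t1 = std::exp(lt1);
      double lr = -(J - 1) * (lt1 - lt0) -
                  0.5 * sv * (1.0 / (t1 * t1) - 1.0 / (t0 * t0)) -
                  0.5 * (t1 * t1 - t0 * t0) / (tau_v_scale * tau_v_scale) +
                  (lt1 - lt0);
      bool ok = std::log(unif_rand()) < lr;
      if (ok) tau_v = t1;
      if (adapting) a_sig.record(1, ok);
    }
    if (use_w) {
      double ls0 = std::log(sigma_w);
      double ls1 = ls0 + norm_rand() * a_sig.scale(2);
      double s0 = sigma_w, s1 = std::exp(ls1);
      double ssw = 0.0;
      for (int m2 = 0; m2 < M; ++m2) ssw += w[m2] * w[m2];
      double lr = -M * (ls1 - ls0) - 0.5 * ssw * (1.0 / (s1 * s1) - 1.0 / (s0 * s0)) -
                  0.5 * (s1 * s1 - s0 * s0) / (sigma_w_scale * sigma_w_scale) +
                  (ls1 - ls0);
      bool ok = std::log(unif_rand()) < lr;
      if (ok) sigma_w = s1;
      if (adapting) a_sig.record(2, ok);
    }

    // ---- interweaving rescale moves ----
    // Jointly scale a variance parameter and its whole effect field; this
    // crosses the funnel between a small SD and small effects that
    // single-site updates cannot traverse. Prior density and transformation
    // Jacobian cancel for the scaled field, leaving the likelihood (or
    // dependent-prior) ratio, the half-Normal prior ratio, and the log-scale
    // Jacobian of the SD itself.
    if (use_u) {
      double r = std::exp(norm_rand() * a_resc.scale(0));
      double s0 = sigma_u, s1 = sigma_u * r;
      double lr = -0.5 * (s1 * s1 - s0 * s0) /
                      (sigma_u_scale * sigma_u_scale) +
                  std::log(r);
      for (int j = 0; j < J; ++j) {
        double vj = use_v ? v[j] : 0.0;
        double shift = (r - 1.0) * (b[j] - vj);
        if (shift == 0.0) continue;
        for (int s = memb_start[j]; s < memb_start[j + 1]; ++s) {
          int i = memb_idx[s];
          lr += mod.ll(i, eta[i] + shift) - mod.ll(i, eta[i]);
        }
      }
      bool ok = std::log(unif_rand()) < lr;
      if (ok) {
        sigma_u = s1;
        for (int j = 0; j < J; ++j) {
          double vj = use_v ? v[j] : 0.0;
          double shift = (r - 1.0) * (b[j] - vj);
          b[j] += shift;
          for (int s = memb_start[j]; s < memb_start[j + 1]; ++s)
            eta[memb_idx[s]] += shift;
        }
      }
      if (adapting) a_resc.record(0, ok);
    }
    if (use_v) {
      double r = std::exp(norm_rand() * a_resc.scale(1));
      double t0 = tau_v, t1 = tau_v * r;
      double lr = -0.5 * (t1 * t1 - t0 * t0) / (tau_v_scale * tau_v_scale) +
                  std::log(r);
      if (use_u) {
        // v scales with tau while b stays: only the N(v, sigma_u^2) prior of
        // b reacts; the likelihood is untouched
        double su2 = sigma_u * sigma_u;
        for (int j = 0; j < J; ++j) {
          double r0 = b[j] - v[j];
          double r1 = b[j] - r * v[j];
          lr += -0.5 * (r1 * r1 - r0 * r0) / su2;
        }
        bool ok = std::log(unif_rand()) < lr;
        if (ok) {
          tau_v = t1;
          for (int j = 0; j < J; ++j) v[j] *= r;
        }
        if (adapting) a_resc.record(1, ok);
      } else {
        // pure ICAR: b coincides with v, so the likelihood moves
        for (int j = 0; j < J; ++j) {
          double shift = (r - 1.0) * b[j];
          if (shift == 0.0) continue;
          for (int s = memb_start[j]; s < memb_start[j + 1]; ++s) {
            int i = memb_idx[s];
            lr += mod.ll(i, eta[i] + shift) - mod.ll(i, eta[i]);
          }
        }
        bool ok = std::log(unif_rand()) < lr;
        if (ok) {
          tau_v = t1;
          for (int j = 0; j < J; ++j) {
            double shift = (r - 1.0) * b[j];
            b[j] += shift;
            v[j] = b[j];
            for (int s = memb_start[j]; s < memb_start[j + 1]; ++s)
              eta[memb_idx[s]] += shift;
          }
        }
        if (adapting) a_resc.record(1, ok);
      }
    }
    if (use_w) {
      double r = std::exp(norm_rand() * a_resc.scale(2));
      double s0 = sigma_w, s1 = sigma_w * r;
      double lr = -0.5 * (s1 * s1 - s0 * s0) /
                      (sigma_w_scale * sigma_w_scale) +
                  std::log(r);
      for (int m2 = 0; m2 < M; ++m2) {
        double shift = (r - 1.0) * w[m2];
        if (shift == 0.0) continue;
        for (int s = wmemb_start[m2]; s < wmemb_start[m2 + 1]; ++s) {
          int i = wmemb_idx[s];
          lr += mod.ll(i, eta[i] + shift) - mod.ll(i, eta[i]);
        }
      }
      bool ok = std::log(unif_rand()) < lr;
      if (ok) {
        sigma_w = s1;
        for (int m2 = 0; m2 < M; ++m2) {
          double shift = (r - 1.0) * w[m2];
          w[m2] += shift;
          for (int s = wmemb_start[m2]; s < wmemb_start[m2 + 1]; ++s)
            eta[wmemb_idx[s]] += shift;
        }
      }
      if (adapting) a_resc.record(2, ok);
    }

    if (adapting) {
      a_beta.maybe_adapt();
      a_kappa.maybe_adapt();
      a_u.maybe_adapt();
      a_v.maybe_adapt();
      a_w.maybe_adapt();
      a_sig.maybe_adapt();
      a_resc.maybe_adapt();
    }

    // ---- save ----
    if (iter >= n_burnin && (iter - n_burnin) % thin == 0 && saved < n_save) {
      for (int k = 0; k < p; ++k) beta_draws(saved, k) = beta[k];
      if (ordinal)
        for (int c = 0; c < n_kappa; ++c) kappa_draws(saved, c) = mod.kappa[c];
      sigma_u_draws[saved] = sigma_u;
      tau_v_draws[saved] = tau_v;
      sigma_w_draws[saved] = sigma_w;
      if (use_u)
        for (int j = 0; j < J; ++j) u_draws(saved, j) = b[j] - (use_v ? v[j] : 0.0);
      if (use_v)
        for (int j = 0; j < J; ++j) v_draws(saved, j) = v[j];
      for (int j = 0; j < J; ++j) u_mean[j] += b[j] - (use_v ? v[j] : 0.0);
      for (int m2 = 0; m2 < M; ++m2) w_mean[m2] += w[m2];
      saved++;
    }
  }

  if (saved > 0) {
    for (int j = 0; j < J; ++j) u_mean[j] /= saved;
    for (int m2 = 0; m2 < M; ++m2) w_mean[m2] /= saved;
  }

  return List::create(
      _["beta"] = beta_draws, _["kappa"] = kappa_draws,
      _["sigma_u"] = sigma_u_draws, _["tau_v"] = tau_v_draws,
      _["sigma_w"] = sigma_w_draws, _["u"] = u_draws, _["v"] = v_draws,
      _["u_mean"] = NumericVector(u_mean.begin(), u_mean.end()),
      _["w_mean"] = NumericVector(w_mean.begin(), w_mean.end()),
      _["n_saved"] = saved);
}
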