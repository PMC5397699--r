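#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(eta)) without overflow
static inline double log1p_exp(double eta) {
  return (eta > 0.0) ? eta + std::log1p(std::exp(-eta))
                     : std::log1p(std::exp(eta));
}

// Bernoulli log-pmf of one record under the 3PL curve, stable at the
// asymptotes: P = c + (1-c)*logistic(eta)
static inline double ll_record(int y, double eta, double c) {
  double l1pe = log1p_exp(eta);
  if (y == 1) {
    double psi = std::exp(eta - l1pe);
    return std::log(c + (1.0 - c) * psi);
  }
  // log(1-P) = log(1-c) + log(1 - psi)
  return std::log(1.0 - c) - l1pe;
}

// [[Rcpp::export]]
double loglik_3pl_cpp(IntegerVector y, NumericVector theta,
                      double a, double b, double c) {
  int n = y.size();
  double ll = 0.0;
  for (int j = 0; j < n; ++j) ll += ll_record(y[j], a * theta[j] - b, c);
  return ll;
}

struct Block {
  double log_scale;
  int acc_batch, try_batch;   // current adaptation batch
  long acc_post, try_post;    // post-burn-in bookkeeping
  int batch_no;
  Block(double s) : log_scale(std::log(s)), acc_batch(0), try_batch(0),
                    acc_post(0), try_post(0), batch_no(0) {}
  double scale() const { return std::exp(log_scale); }
  void tally(bool acc, bool post) {
    ++try_batch; if (acc) ++acc_batch;
    if (post) { ++try_post; if (acc) ++acc_post; }
  }
  // Robbins-Monro drift toward the target rate, burn-in only
  void adapt(double target) {
    if (try_batch >= 50) {
      ++batch_no;
      double rate = (double)acc_batch / try_batch;
      log_scale += (rate - target) / std::sqrt((double)batch_no);
      if (log_scale < -10.0) log_scale = -10.0;
      if (log_scale > 5.0) log_scale = 5.0;
      acc_batch = try_batch = 0;
    }
  }
  double rate_post() const {
    return try_post > 0 ? (double)acc_post / try_post : NA_REAL;
  }
};

// One MCMC chain for the 3PL treatment-seeking model.
// variant: 1 = M1, 2 = M2 (b > 0), 3 = M3 (random intercepts),
//          4 = M4 (correlated random slope + intercept, Wishart precision).
// init: a, b, c, alpha, beta [, log_sigma_re (M3)]
// Uses R's RNG; seed with set.seed() before calling.
// [[Rcpp::export]]
List run_chain_cpp(IntegerVector y, NumericVector x, int variant,
                   List priors, int n_iter, int burn_in, int thin,
                   NumericVector init, bool use_likelihood, bool adapt) {
  int n = y.size();
  const double a_mean = priors["a_mean"], a_var = priors["a_var"];
  const double b_mean = priors["b_mean"], b_var = priors["b_var"];
  const double c_kappa = priors["c_kappa"], c_tau = priors["c_tau"];
  const double al_mean = priors["alpha_mean"], al_var = priors["alpha_var"];
  const double be_mean = priors["beta_mean"], be_var = priors["beta_var"];
  const double re_sd_scale = priors["re_sd_scale"];
  NumericMatrix wishart_scale = priors["wishart_scale"];
  const double wishart_df = priors["wishart_df"];

  // state
  double a = init[0], b = init[1], c = init[2];
  double alpha = init[3], beta = init[4];
  double sigma_re = (variant == 3) ? std::exp(init[5]) : 1.0;
  std::vector<double> re_a(n, alpha), re_b(n, beta);
  // M4 precision matrix of the random effects, start at identity
  double P11 = 1.0, P12 = 0.0, P22 = 1.0;

  std::vector<double> theta(n);
  auto theta_j = [&](int j) -> double {
    if (variant <= 2) return alpha + beta * x[j];
    if (variant == 3) return re_a[j] + beta * x[j];
    return re_a[j] + re_b[j] * x[j];
  };
  auto refresh_theta = [&]() { for (int j = 0; j < n; ++j) theta[j] = theta_j(j); };
  refresh_theta();

  auto loglik_at = [&](double aa, double bb, double cc) -> double {
    if (!use_likelihood) return 0.0;
    double ll = 0.0;
    for (int j = 0; j < n; ++j) ll += ll_record(y[j], aa * theta[j] - bb, cc);
    return ll;
  };
  double cur_ll = loglik_at(a, b, c);

  Block bl_a(0.5), bl_b(0.5), bl_c(0.5), bl_al(0.3), bl_be(0.3),
        bl_re(0.5), bl_sg(0.5), bl_rg(0.3);

  int n_keep = (n_iter - burn_in) / thin;
  int n_par = (variant == 3) ? 6 : (variant == 4 ? 9 : 5);
  NumericMatrix draws(n_keep, n_par);
  NumericVector deviance(n_keep);
  std::vector<double> re_a_sum(n, 0.0), re_b_sum(n, 0.0), p_sum(n, 0.0);
  int kept = 0;

  for (int t = 1; t <= n_iter; ++t) {
    bool post = t > burn_in;

    // --- a (truncated-normal prior, reject outside support) ---
    {
      double prop = a + bl_a.scale() * R::norm_rand();
      bool acc = false;
      if (prop > 0.0) {
        double ll_new = loglik_at(prop, b, c);
        double lr = ll_new - cur_ll
          - (prop - a_mean) * (prop - a_mean) / (2.0 * a_var)
          + (a - a_mean) * (a - a_mean) / (2.0 * a_var);
        if (std::log(R::unif_rand()) < lr) { a = prop; cur_ll = ll_new; acc = true; }
      }
      bl_a.tally(acc, post);
      if (adapt && !post) bl_a.adapt(0.44);
    }

    // --- b (normal prior; M2 truncated at 0) ---
    {
      double prop = b + bl_b.scale() * R::norm_rand();
      bool acc = false;
      if (!(variant == 2 && prop <= 0.0)) {
        double ll_new = loglik_at(a, prop, c);
        double lr = ll_new - cur_ll
          - (prop - b_mean) * (prop - b_mean) / (2.0 * b_var)
          + (b - b_mean) * (b - b_mean) / (2.0 * b_var);
        if (std::log(R::unif_rand()) < lr) { b = prop; cur_ll = ll_new; acc = true; }
      }
      bl_b.tally(acc, post);
      if (adapt && !post) bl_b.adapt(0.44);
    }

    // --- c, random walk on logit(c) with Jacobian correction ---
    {
      double z = std::log(c / (1.0 - c));
      double zp = z + bl_c.scale() * R::norm_rand();
      double cp = 1.0 / (1.0 + std::exp(-zp));
      bool acc = false;
      if (cp > 0.0 && cp < 1.0) {
        double ll_new = loglik_at(a, b, cp);
        double lr = ll_new - cur_ll
          + (c_kappa - 1.0) * (std::log(cp) - std::log(c))
          + (c_tau - 1.0) * (std::log1p(-cp) - std::log1p(-c))
          + std::log(cp) + std::log1p(-cp)   // Jacobian dz -> dc
          - std::log(c) - std::log1p(-c);
        if (std::log(R::unif_rand()) < lr) { c = cp; cur_ll = ll_new; acc = true; }
      }
      bl_c.tally(acc, post);
      if (adapt && !post) bl_c.adapt(0.44);
    }

    // --- alpha ---
    {
      double prop = alpha + bl_al.scale() * R::norm_rand();
      double lr = -(prop - al_mean) * (prop - al_mean) / (2.0 * al_var)
                  + (alpha - al_mean) * (alpha - al_mean) / (2.0 * al_var);
      double ll_new = cur_ll;
      if (variant <= 2) {
        if (use_likelihood) {
          ll_new = 0.0;
          for (int j = 0; j < n; ++j)
            ll_new += ll_record(y[j], a * (prop + beta * x[j]) - b, c);
        }
        lr += ll_new - cur_ll;
      } else if (variant == 3) {
        double ss_new = 0.0, ss_old = 0.0;
        for (int j = 0; j < n; ++j) {
          ss_new += (re_a[j] - prop) * (re_a[j] - prop);
          ss_old += (re_a[j] - alpha) * (re_a[j] - alpha);
        }
        lr += (ss_old - ss_new) / (2.0 * sigma_re * sigma_re);
      } else {
        double q_new = 0.0, q_old = 0.0;
        for (int j = 0; j < n; ++j) {
          double dn = re_a[j] - prop, db2 = re_b[j] - beta;
          double doa = re_a[j] - alpha;
          q_new += P11 * dn * dn + 2.0 * P12 * dn * db2;
          q_old += P11 * doa * doa + 2.0 * P12 * doa * db2;
        }
        lr += 0.5 * (q_old - q_new);
      }
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) {
        alpha = prop;
        if (variant <= 2) { refresh_theta(); cur_ll = ll_new; }
      }
      bl_al.tally(acc, post);
      if (adapt && !post) bl_al.adapt(0.44);
    }

    // --- beta ---
    {
      double prop = beta + bl_be.scale() * R::norm_rand();
      double lr = -(prop - be_mean) * (prop - be_mean) / (2.0 * be_var)
                  + (beta - be_mean) * (beta - be_mean) / (2.0 * be_var);
      double ll_new = cur_ll;
      if (variant <= 3) {
        if (use_likelihood) {
          ll_new = 0.0;
          for (int j = 0; j < n; ++j) {
            double base = (variant == 3) ? re_a[j] : alpha;
            ll_new += ll_record(y[j], a * (base + prop * x[j]) - b, c);
          }
        }
        lr += ll_new - cur_ll;
      } else {
        double q_new = 0.0, q_old = 0.0;
        for (int j = 0; j < n; ++j) {
          double da = re_a[j] - alpha;
          double dn = re_b[j] - prop, dold = re_b[j] - beta;
          q_new += P22 * dn * dn + 2.0 * P12 * da * dn;
          q_old += P22 * dold * dold + 2.0 * P12 * da * dold;
        }
        lr += 0.5 * (q_old - q_new);
      }
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) {
        beta = prop;
        if (variant <= 3) { refresh_theta(); cur_ll = ll_new; }
      }
      bl_be.tally(acc, post);
      if (adapt && !post) bl_be.adapt(0.44);
    }

    // --- likelihood-invariant rescaling along the a*theta ridge ---
    // (a, alpha, beta) -> (a s, alpha/s, beta/s) leaves every linear
    // predictor unchanged; only the priors and the Jacobian |J| = 1/s
    // enter the ratio. Greatly improves mixing of the weakly identified
    // single-item scale.
    if (variant <= 2) {
      double eps = bl_rg.scale() * R::norm_rand();
      double s = std::exp(eps);
      double ap = a * s, alp = alpha / s, bep = beta / s;
      double lr =
        - (ap - a_mean) * (ap - a_mean) / (2.0 * a_var)
        + (a - a_mean) * (a - a_mean) / (2.0 * a_var)
        - (alp - al_mean) * (alp - al_mean) / (2.0 * al_var)
        + (alpha - al_mean) * (alpha - al_mean) / (2.0 * al_var)
        - (bep - be_mean) * (bep - be_mean) / (2.0 * be_var)
        + (beta - be_mean) * (beta - be_mean) / (2.0 * be_var)
        - eps;
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) {
        a = ap; alpha = alp; beta = bep;
        refresh_theta();
        cur_ll = loglik_at(a, b, c);  // re-anchor against FP drift
      }
      bl_rg.tally(acc, post);
      if (adapt && !post) bl_rg.adapt(0.44);
    }

    // --- person-level random effects ---
    if (variant == 3) {
      int acc_cnt = 0;
      double s = bl_re.scale();
      for (int j = 0; j < n; ++j) {
        double prop = re_a[j] + s * R::norm_rand();
        double th_new = prop + beta * x[j];
        double lr = -(prop - alpha) * (prop - alpha) /
                      (2.0 * sigma_re * sigma_re)
                    + (re_a[j] - alpha) * (re_a[j] - alpha) /
                      (2.0 * sigma_re * sigma_re);
        double dll = 0.0;
        if (use_likelihood) {
          dll = ll_record(y[j], a * th_new - b, c)
              - ll_record(y[j], a * theta[j] - b, c);
          lr += dll;
        }
        if (std::log(R::unif_rand()) < lr) {
          re_a[j] = prop; theta[j] = th_new; cur_ll += dll; ++acc_cnt;
        }
      }
      if (adapt && !post) {
        ++bl_re.batch_no;
        double rate = (double)acc_cnt / n;
        bl_re.log_scale += (rate - 0.44) / std::sqrt((double)bl_re.batch_no);
      } else if (post) {
        bl_re.acc_post += acc_cnt; bl_re.try_post += n;
      }
      // --- sigma_re, random walk on log scale, half-normal prior ---
      {
        double lz = std::log(sigma_re);
        double lzp = lz + bl_sg.scale() * R::norm_rand();
        double sp = std::exp(lzp);
        double ss = 0.0;
        for (int j = 0; j < n; ++j)
          ss += (re_a[j] - alpha) * (re_a[j] - alpha);
        double lr = -n * (lzp - lz)
                    - ss / (2.0 * sp * sp) + ss / (2.0 * sigma_re * sigma_re)
                    - sp * sp / (2.0 * re_sd_scale * re_sd_scale)
                    + sigma_re * sigma_re / (2.0 * re_sd_scale * re_sd_scale)
                    + (lzp - lz);  // Jacobian of the log transform
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) sigma_re = sp;
        bl_sg.tally(acc, post);
        if (adapt && !post) bl_sg.adapt(0.44);
      }
    } else if (variant == 4) {
      int acc_cnt = 0;
      double s = bl_re.scale();
      for (int j = 0; j < n; ++j) {
        double pa = re_a[j] + s * R::norm_rand();
        double pb = re_b[j] + s * R::norm_rand();
        double th_new = pa + pb * x[j];
        double dan = pa - alpha, dbn = pb - beta;
        double dao = re_a[j] - alpha, dbo = re_b[j] - beta;
        double lr = -0.5 * (P11 * dan * dan + 2.0 * P12 * dan * dbn +
                            P22 * dbn * dbn)
                    + 0.5 * (P11 * dao * dao + 2.0 * P12 * dao * dbo +
                             P22 * dbo * dbo);
        double dll = 0.0;
        if (use_likelihood) {
          dll = ll_record(y[j], a * th_new - b, c)
              - ll_record(y[j], a * theta[j] - b, c);
          lr += dll;
        }
        if (std::log(R::unif_rand()) < lr) {
          re_a[j] = pa; re_b[j] = pb; theta[j] = th_new; cur_ll += dll;
          ++acc_cnt;
        }
      }
      if (adapt && !post) {
        ++bl_re.batch_no;
        double rate = (double)acc_cnt / n;
        bl_re.log_scale += (rate - 0.30) / std::sqrt((double)bl_re.batch_no);
      } else if (post) {
        bl_re.acc_post += acc_cnt; bl_re.try_post += n;
      }
      // --- Gibbs update of the precision matrix: Wishart conjugacy ---
      {
        double S11 = 0.0, S12 = 0.0, S22 = 0.0;
        for (int j = 0; j < n; ++j) {
          double da = re_a[j] - alpha, db2 = re_b[j] - beta;
          S11 += da * da; S12 += da * db2; S22 += db2 * db2;
        }
        // posterior scale = (Omega^-1 + S)^-1, df = wishart_df + n
        double O11 = wishart_scale(0, 0), O12 = wishart_scale(0, 1),
               O22 = wishart_scale(1, 1);
        double od = O11 * O22 - O12 * O12;
        double A11 = O22 / od + S11, A12 = -O12 / od + S12,
               A22 = O11 / od + S22;
        double ad = A11 * A22 - A12 * A12;
        double V11 = A22 / ad, V12 = -A12 / ad, V22 = A11 / ad;
        double df = wishart_df + n;
        // Bartlett decomposition with Cholesky of V
        double L11 = std::sqrt(V11), L21 = V12 / L11,
               L22 = std::sqrt(V22 - L21 * L21);
        double c11 = std::sqrt(R::rchisq(df));
        double c22 = std::sqrt(R::rchisq(df - 1.0));
        double z21 = R::norm_rand();
        // W = L A (L A)^T with A lower-triangular Bartlett factor
        double B11 = L11 * c11;
        double B21 = L21 * c11 + L22 * z21;
        double B22 = L22 * c22;
        P11 = B11 * B11;
        P12 = B11 * B21;
        P22 = B21 * B21 + B22 * B22;
      }
    }

    if (post && (t - burn_in) % thin == 0) {
      draws(kept, 0) = a; draws(kept, 1) = b; draws(kept, 2) = c;
      draws(kept, 3) = alpha; draws(kept, 4) = beta;
      if (variant == 3) draws(kept, 5) = sigma_re;
      if (variant == 4) {
        double pd = P11 * P22 - P12 * P12;
        double s11 = P22 / pd, s12 = -P12 / pd, s22 = P11 / pd;
        draws(kept, 5) = s11; draws(kept, 6) = s22; draws(kept, 7) = s12;
        draws(kept, 8) = s12 / std::sqrt(s11 * s22);
      }
      deviance[kept] = -2.0 * cur_ll;
      for (int j = 0; j < n; ++j) {
        re_a_sum[j] += re_a[j]; re_b_sum[j] += re_b[j];
        double e = a * theta[j] - b;
        p_sum[j] += c + (1.0 - c) / (1.0 + std::exp(-e));
      }
      ++kept;
    }
  }

  NumericVector re_a_mean(n), re_b_mean(n), p_mean(n);
  if (kept > 0) {
    for (int j = 0; j < n; ++j) {
      re_a_mean[j] = re_a_sum[j] / kept;
      re_b_mean[j] = re_b_sum[j] / kept;
      p_mean[j] = p_sum[j] / kept;
    }
  }
  NumericVector acc = NumericVector::create(
    _["a"] = bl_a.rate_post(), _["b"] = bl_b.rate_post(),
    _["c"] = bl_c.rate_post(), _["alpha"] = bl_al.rate_post(),
    _["beta"] = bl_be.rate_post());
  if (variant <= 2) {
    acc.push_back(bl_rg.rate_post(), "rescale");
  }
  if (variant == 3) {
    acc.push_back(bl_re.rate_post(), "random_effects");
    acc.push_back(bl_sg.rate_post(), "sigma_re");
  }
  if (variant == 4) {
    acc.push_back(bl_re.rate_post(), "random_effects");
  }
  return List::create(_["draws"] = draws, _["deviance"] = deviance,
                      _["re_a_mean"] = re_a_mean, _["re_b_mean"] = re_b_mean,
                      _["p_mean"] = p_mean, _["accept"] = acc);
}
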