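#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for Bayes B / Bayes C-pi marker-effect models with up to two
// effect classes (additive design Z, dominance design H). Each marker effect
// carries a point mass at zero with probability pi; effect variances follow
// scaled-inverse-chi-square priors (per marker for Bayes B, common per class
// for Bayes C-pi, which additionally samples pi from its Beta posterior).
// Uses R's RNG so results are reproducible under set.seed().

static double scaled_inv_chisq(double df, double scale) {
  // draw from df*scale / chisq_df
  return df * scale / R::rchisq(df);
}

struct EffectClass {
  NumericMatrix X;        // n x m design
  std::vector<double> xtx;
  std::vector<double> eff;
  std::vector<int> incl;
  std::vector<double> var_j;   // per-marker variance (Bayes B)
  double var_common;           // common variance (Bayes C-pi)
  double pi;                   // exclusion probability
  double df, scale;
  std::vector<double> incl_sum, eff_sum;
  std::vector<double> gval;    // n: current X * eff, maintained incrementally
};

static void init_class(EffectClass &c, NumericMatrix X, double pi,
                       double df, double scale, int n) {
  c.X = X;
  int m = X.ncol();
  c.xtx.assign(m, 0.0);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    c.xtx[j] = s;
  }
  c.eff.assign(m, 0.0);
  c.incl.assign(m, 0);
  c.var_j.assign(m, scale);
  c.var_common = scale;
  c.pi = pi;
  c.df = df;
  c.scale = scale;
  c.incl_sum.assign(m, 0.0);
  c.eff_sum.assign(m, 0.0);
  c.gval.assign(n, 0.0);
}

static void update_class(EffectClass &c, std::vector<double> &ycorr,
                         double var_e, bool common_var, int n) {
  int m = c.X.ncol();
  int m_in = 0;
  double ss_eff = 0.0;
  for (int j = 0; j < m; ++j) {
    double cxx = c.xtx[j];
    if (cxx <= 0.0) { c.eff[j] = 0.0; c.incl[j] = 0; continue; }
    double old = c.eff[j];
    // restore ycorr to exclude this marker
    double r = 0.0;
    if (old != 0.0) {
      for (int i = 0; i < n; ++i) {
        double xij = c.X(i, j);
        ycorr[i] += xij * old;
        c.gval[i] -= xij * old;
      }
    }
    for (int i = 0; i < n; ++i) r += c.X(i, j) * ycorr[i];
    double sig2 = common_var ? c.var_common : c.var_j[j];
    double v0 = cxx * var_e;
    double v1 = cxx * cxx * sig2 + cxx * var_e;
    double logBF = 0.5 * (std::log(v0 / v1) + r * r * (1.0 / v0 - 1.0 / v1));
    double p1;
    if (c.pi <= 0.0) p1 = 1.0;
    else if (c.pi >= 1.0) p1 = 0.0;
    else {
      double logodds = std::log((1.0 - c.pi) / c.pi) + logBF;
      p1 = 1.0 / (1.0 + std::exp(-logodds));
    }
    if (R::runif(0.0, 1.0) < p1) {
      double C = cxx + var_e / sig2;
      double mean = r / C;
      double val = R::rnorm(mean, std::sqrt(var_e / C));
      c.eff[j] = val;
      c.incl[j] = 1;
      ++m_in;
      ss_eff += val * val;
      for (int i = 0; i < n; ++i) {
        double xij = c.X(i, j);
        ycorr[i] -= xij * val;
        c.gval[i] += xij * val;
      }
      if (!common_var)
        c.var_j[j] = scaled_inv_chisq(c.df + 1.0,
                                      (c.df * c.scale + val * val) /
                                          (c.df + 1.0));
    } else {
      c.eff[j] = 0.0;
      c.incl[j] = 0;
      if (!common_var)
        c.var_j[j] = scaled_inv_chisq(c.df, c.scale);
    }
  }
  if (common_var) {
    // prior targets the total genetic variance: the per-marker scale
    // adapts to the current inclusion rate so that (1-pi) * m * E(var)
    // stays at the configured prior genetic variance
    double scale_eff = c.scale / std::max(1.0 - c.pi, 1e-3);
    c.var_common = scaled_inv_chisq(c.df + m_in,
                                    (c.df * scale_eff + ss_eff) /
                                        (c.df + m_in));
    // uniform prior on pi -> Beta(#excluded + 1, #included + 1)
    c.pi = R::rbeta((double)(m - m_in) + 1.0, (double)m_in + 1.0);
  }
}

static double vec_var(const std::vector<double> &v) {
  int n = v.size();
  double mean = 0.0;
  for (double x : v) mean += x;
  mean /= n;
  double ss = 0.0;
  for (double x : v) ss += (x - mean) * (x - mean);
  return ss / (n - 1);
}

// [[Rcpp::export(name = ".bayes_sampler_cpp")]]
List bayes_sampler_cpp(NumericVector y, NumericMatrix Z,
                       Nullable<NumericMatrix> H_, int n_iter, int burn_in,
                       int thin, double pi_a, double pi_d, bool common_var,
                       double df_eff, double scale_a, double scale_d,
                       double df_res, double scale_res) {
  int n = y.size();
  bool with_dom = H_.isNotNull();
  EffectClass ca, cd;
  init_class(ca, Z, pi_a, df_eff, scale_a, n);
  if (with_dom) init_class(cd, NumericMatrix(H_), pi_d, df_eff, scale_d, n);

  double mu = mean(y);
  double var_e = scaled_inv_chisq(df_res, scale_res);
  std::vector<double> ycorr(n);
  for (int i = 0; i < n; ++i) ycorr[i] = y[i] - mu;

  int n_keep = 0;
  for (int it = burn_in + 1; it <= n_iter; ++it)
    if ((it - burn_in) % thin == 0) ++n_keep;
  NumericVector ch_va(n_keep), ch_vd(n_keep), ch_vg(n_keep), ch_ve(n_keep),
      ch_pi_a(n_keep), ch_pi_d(n_keep), ch_mu(n_keep);
  double mu_sum = 0.0;
  int keep = 0, n_samples = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept
    double ybar = 0.0;
    for (int i = 0; i < n; ++i) ybar += ycorr[i] + mu;
    ybar /= n;
    double mu_new = R::rnorm(ybar, std::sqrt(var_e / n));
    for (int i = 0; i < n; ++i) ycorr[i] += mu - mu_new;
    mu = mu_new;

    update_class(ca, ycorr, var_e, common_var, n);
    if (with_dom) update_class(cd, ycorr, var_e, common_var, n);

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += ycorr[i] * ycorr[i];
    var_e = scaled_inv_chisq(df_res + n,
                             (df_res * scale_res + sse) / (df_res + n));
    if (!std::isfinite(var_e) || var_e > 1e12)
      stop("residual variance diverged at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++n_samples;
      mu_sum += mu;
      for (int j = 0; j < ca.X.ncol(); ++j) {
        ca.incl_sum[j] += ca.incl[j];
        ca.eff_sum[j] += ca.eff[j];
      }
      double va = vec_var(ca.gval), vd = 0.0, vg = va;
      if (with_dom) {
        for (int j = 0; j < cd.X.ncol(); ++j) {
          cd.incl_sum[j] += cd.incl[j];
          cd.eff_sum[j] += cd.eff[j];
        }
        vd = vec_var(cd.gval);
        std::vector<double> g(n);
        for (int i = 0; i < n; ++i) g[i] = ca.gval[i] + cd.gval[i];
        vg = vec_var(g);
      }
      ch_va[keep] = va;
      ch_vd[keep] = vd;
      ch_vg[keep] = vg;
      ch_ve[keep] = var_e;
      ch_pi_a[keep] = ca.pi;
      ch_pi_d[keep] = with_dom ? cd.pi : NA_REAL;
      ch_mu[keep] = mu;
      ++keep;
    }
  }

  int m = Z.ncol();
  NumericVector a_mean(m), ip_a(m);
  for (int j = 0; j < m; ++j) {
    a_mean[j] = ca.eff_sum[j] / n_samples;
    ip_a[j] = ca.incl_sum[j] / n_samples;
  }
  List out = List::create(
      _["mu"] = mu_sum / n_samples, _["a"] = a_mean, _["incl_a"] = ip_a,
      _["chain_var_a"] = ch_va, _["chain_var_d"] = ch_vd,
      _["chain_var_g"] = ch_vg, _["chain_var_e"] = ch_ve,
      _["chain_pi_a"] = ch_pi_a, _["chain_pi_d"] = ch_pi_d,
      _["chain_mu"] = ch_mu, _["n_samples"] = n_samples);
  if (with_dom) {
    int md = cd.X.ncol();
    NumericVector d_mean(md), ip_d(md);
    for (int j = 0; j < md; ++j) {
      d_mean[j] = cd.eff_sum[j] / n_samples;
      ip_d[j] = cd.incl_sum[j] / n_samples;
    }
    out["d"] = d_mean;
    out["incl_d"] = ip_d;
  }
  return out;
}
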