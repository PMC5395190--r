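#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the hierarchical trait-variance model
//   y_i = a0 + d_ft * s_ft(i) + d_gf * s_gf(i) + d_season * s_season(i)
//         + b_fam(i) + b_spec(i) + b_ind(i) + e_i,  e_i ~ N(0, sig2_res)
// with priors a0 ~ N(0, gm_var), d_* ~ U(-fb, fb) and uniform U(0, sb)
// priors on every standard deviation. Fixed factors are two-level and
// sum-to-zero coded: s(i) = +1 / -1. Absent terms have a zero sign /
// index vector and are skipped.

// Truncated normal on (lo, hi) by inverse CDF; falls back to the nearer
// bound when the conditional mass inside the interval underflows.
static double rtnorm1(double mean, double sd, double lo, double hi) {
  double plo = R::pnorm(lo, mean, sd, 1, 0);
  double phi = R::pnorm(hi, mean, sd, 1, 0);
  if (phi - plo < 1e-14) return (mean < lo) ? lo : ((mean > hi) ? hi : mean);
  double u = R::runif(plo, phi);
  double x = R::qnorm(u, mean, sd, 1, 0);
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

// Draw sig2 given sum of squares S over J deviates, sigma ~ U(0, bound):
// sig2 | S ~ InvGamma((J-1)/2, S/2) truncated to sig2 < bound^2,
// sampled through tau = 1/sig2 ~ Gamma truncated to tau > 1/bound^2.
static double rsig2(double S, double J, double bound) {
  double shape = (J - 1.0) / 2.0;
  if (shape <= 0.0) shape = 0.5;
  double rate = S / 2.0;
  if (rate < 1e-300) rate = 1e-300;
  double scale = 1.0 / rate;
  double tau_min = 1.0 / (bound * bound);
  double pmin = R::pgamma(tau_min, shape, scale, 1, 0);
  if (pmin > 1.0 - 1e-14) pmin = 1.0 - 1e-14;
  double u = R::runif(pmin, 1.0);
  double tau = R::qgamma(u, shape, scale, 1, 0);
  if (tau < tau_min) tau = tau_min;
  return 1.0 / tau;
}

// [[Rcpp::export]]
NumericMatrix gibbs_varcomp(NumericVector y,
                            IntegerVector fam, int n_fam,
                            IntegerVector spec, int n_spec,
                            IntegerVector ind, int n_ind,
                            NumericVector s_ft, NumericVector s_gf,
                            NumericVector s_season,
                            bool has_ft, bool has_gf, bool has_season,
                            bool has_fam, bool has_spec, bool has_ind,
                            int n_iter, int burn_in, int thin,
                            double gm_var, double fixed_bound,
                            double sd_bound) {
  int n = y.size();
  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix out(n_keep, 8);

  double a0 = mean(y);
  double d_ft = 0.0, d_gf = 0.0, d_season = 0.0;
  std::vector<double> b_fam(n_fam, 0.0), b_spec(n_spec, 0.0), b_ind(n_ind, 0.0);
  double v0 = var(y);
  if (v0 < 1e-8) v0 = 1e-8;
  double sig2_fam = v0 / 4, sig2_spec = v0 / 4, sig2_ind = v0 / 4,
         sig2_res = v0 / 2;

  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - a0;

  std::vector<double> gsum(std::max(n_fam, std::max(n_spec, n_ind)), 0.0);
  std::vector<int> gn_fam(n_fam, 0), gn_spec(n_spec, 0), gn_ind(n_ind, 0);
  for (int i = 0; i < n; ++i) {
    if (has_fam) gn_fam[fam[i]]++;
    if (has_spec) gn_spec[spec[i]]++;
    if (has_ind) gn_ind[ind[i]]++;
  }

  // per-species signs of the species-level fixed factors (constant
  // within species by design); used by the translation moves
  std::vector<double> s_ft_spec(n_spec, 0.0), s_gf_spec(n_spec, 0.0);
  if (has_spec) {
    for (int i = 0; i < n; ++i) {
      s_ft_spec[spec[i]] = s_ft[i];
      s_gf_spec[spec[i]] = s_gf[i];
    }
  }

  RNGScope scope;
  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    // grand mean (normal prior)
    {
      double sumr = 0.0;
      for (int i = 0; i < n; ++i) sumr += r[i];
      sumr += n * a0;
      double prec = n / sig2_res + 1.0 / gm_var;
      double m = (sumr / sig2_res) / prec;
      double a_new = R::rnorm(m, std::sqrt(1.0 / prec));
      double shift = a0 - a_new;
      for (int i = 0; i < n; ++i) r[i] += shift;
      a0 = a_new;
    }
    // two-level fixed factors, sum-to-zero: effect = +/- delta
    if (has_ft) {
      double ssr = 0.0;
      for (int i = 0; i < n; ++i) ssr += s_ft[i] * r[i];
      ssr += n * d_ft; // s^2 = 1
      double m = ssr / n;
      double d_new = rtnorm1(m, std::sqrt(sig2_res / n), -fixed_bound, fixed_bound);
      double diff = d_ft - d_new;
      for (int i = 0; i < n; ++i) r[i] += s_ft[i] * diff;
      d_ft = d_new;
    }
    if (has_gf) {
      double ssr = 0.0;
      for (int i = 0; i < n; ++i) ssr += s_gf[i] * r[i];
      ssr += n * d_gf;
      double m = ssr / n;
      double d_new = rtnorm1(m, std::sqrt(sig2_res / n), -fixed_bound, fixed_bound);
      double diff = d_gf - d_new;
      for (int i = 0; i < n; ++i) r[i] += s_gf[i] * diff;
      d_gf = d_new;
    }
    if (has_season) {
      double ssr = 0.0;
      for (int i = 0; i < n; ++i) ssr += s_season[i] * r[i];
      ssr += n * d_season;
      double m = ssr / n;
      double d_new = rtnorm1(m, std::sqrt(sig2_res / n), -fixed_bound, fixed_bound);
      double diff = d_season - d_new;
      for (int i = 0; i < n; ++i) r[i] += s_season[i] * diff;
      d_season = d_new;
    }
    // random-effect blocks
    if (has_fam) {
      std::fill(gsum.begin(), gsum.begin() + n_fam, 0.0);
      for (int i = 0; i < n; ++i) gsum[fam[i]] += r[i] + b_fam[fam[i]];
      double S = 0.0;
      for (int j = 0; j < n_fam; ++j) {
        double prec = gn_fam[j] / sig2_res + 1.0 / sig2_fam;
        double m = (gsum[j] / sig2_res) / prec;
        double b_new = R::rnorm(m, std::sqrt(1.0 / prec));
        gsum[j] = b_fam[j] - b_new; // reuse as shift
        b_fam[j] = b_new;
        S += b_new * b_new;
      }
      for (int i = 0; i < n; ++i) r[i] += gsum[fam[i]];
      sig2_fam = rsig2(S, (double)n_fam, sd_bound);
    }
    if (has_spec) {
      std::fill(gsum.begin(), gsum.begin() + n_spec, 0.0);
      for (int i = 0; i < n; ++i) gsum[spec[i]] += r[i] + b_spec[spec[i]];
      double S = 0.0;
      for (int j = 0; j < n_spec; ++j) {
        double prec = gn_spec[j] / sig2_res + 1.0 / sig2_spec;
        double m = (gsum[j] / sig2_res) / prec;
        double b_new = R::rnorm(m, std::sqrt(1.0 / prec));
        gsum[j] = b_spec[j] - b_new;
        b_spec[j] = b_new;
        S += b_new * b_new;
      }
      for (int i = 0; i < n; ++i) r[i] += gsum[spec[i]];
      sig2_spec = rsig2(S, (double)n_spec, sd_bound);
    }
    if (has_ind) {
      std::fill(gsum.begin(), gsum.begin() + n_ind, 0.0);
      for (int i = 0; i < n; ++i) gsum[ind[i]] += r[i] + b_ind[ind[i]];
      double S = 0.0;
      for (int j = 0; j < n_ind; ++j) {
        double prec = gn_ind[j] / sig2_res + 1.0 / sig2_ind;
        double m = (gsum[j] / sig2_res) / prec;
        double b_new = R::rnorm(m, std::sqrt(1.0 / prec));
        gsum[j] = b_ind[j] - b_new;
        b_ind[j] = b_new;
        S += b_new * b_new;
      }
      for (int i = 0; i < n; ++i) r[i] += gsum[ind[i]];
      sig2_ind = rsig2(S, (double)n_ind, sd_bound);
    }
    // residual variance
    {
      double S = 0.0;
      for (int i = 0; i < n; ++i) S += r[i] * r[i];
      sig2_res = rsig2(S, (double)n, sd_bound);
    }

    // translation moves along likelihood-invariant directions: shifting
    // mass between the grand mean (or a species-level fixed coefficient)
    // and the random-effect block means leaves every residual unchanged
    // but decorrelates the confounded location parameters. Each draw is
    // an exact Gibbs update of the shift under the priors.
    if (has_fam) {
      double sum_b = 0.0;
      for (int j = 0; j < n_fam; ++j) sum_b += b_fam[j];
      double prec = 1.0 / gm_var + n_fam / sig2_fam;
      double m = (-a0 / gm_var + sum_b / sig2_fam) / prec;
      double delta = R::rnorm(m, std::sqrt(1.0 / prec));
      a0 += delta;
      for (int j = 0; j < n_fam; ++j) b_fam[j] -= delta;
    }
    if (has_spec) {
      double sum_b = 0.0;
      for (int j = 0; j < n_spec; ++j) sum_b += b_spec[j];
      double prec = 1.0 / gm_var + n_spec / sig2_spec;
      double m = (-a0 / gm_var + sum_b / sig2_spec) / prec;
      double delta = R::rnorm(m, std::sqrt(1.0 / prec));
      a0 += delta;
      for (int j = 0; j < n_spec; ++j) b_spec[j] -= delta;
    }
    if (has_ind) {
      double sum_b = 0.0;
      for (int j = 0; j < n_ind; ++j) sum_b += b_ind[j];
      double prec = 1.0 / gm_var + n_ind / sig2_ind;
      double m = (-a0 / gm_var + sum_b / sig2_ind) / prec;
      double delta = R::rnorm(m, std::sqrt(1.0 / prec));
      a0 += delta;
      for (int j = 0; j < n_ind; ++j) b_ind[j] -= delta;
    }
    // fixed species-level coefficients vs species effects: d -> d + delta,
    // b_spec[j] -> b_spec[j] - s_j * delta with s_j the block's sign
    if (has_spec && (has_ft || has_gf)) {
      if (has_ft) {
        double sum_sb = 0.0;
        for (int j = 0; j < n_spec; ++j) sum_sb += s_ft_spec[j] * b_spec[j];
        double prec = n_spec / sig2_spec; // s_j^2 = 1
        double m = (sum_sb / sig2_spec) / prec;
        double delta = rtnorm1(m, std::sqrt(1.0 / prec),
                               -fixed_bound - d_ft, fixed_bound - d_ft);
        d_ft += delta;
        for (int j = 0; j < n_spec; ++j) b_spec[j] -= s_ft_spec[j] * delta;
      }
      if (has_gf) {
        double sum_sb = 0.0;
        for (int j = 0; j < n_spec; ++j) sum_sb += s_gf_spec[j] * b_spec[j];
        double prec = n_spec / sig2_spec;
        double m = (sum_sb / sig2_spec) / prec;
        double delta = rtnorm1(m, std::sqrt(1.0 / prec),
                               -fixed_bound - d_gf, fixed_bound - d_gf);
        d_gf += delta;
        for (int j = 0; j < n_spec; ++j) b_spec[j] -= s_gf_spec[j] * delta;
      }
    }

    if (it >= burn_in && (it - burn_in) % thin == 0 && keep < n_keep) {
      out(keep, 0) = a0;
      out(keep, 1) = has_ft ? d_ft : NA_REAL;
      out(keep, 2) = has_gf ? d_gf : NA_REAL;
      out(keep, 3) = has_season ? d_season : NA_REAL;
      out(keep, 4) = has_fam ? std::sqrt(sig2_fam) : NA_REAL;
      out(keep, 5) = has_spec ? std::sqrt(sig2_spec) : NA_REAL;
      out(keep, 6) = has_ind ? std::sqrt(sig2_ind) : NA_REAL;
      out(keep, 7) = std::sqrt(sig2_res);
      keep++;
    }
  }
  return out;
}
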