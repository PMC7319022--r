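#include <Rcpp.h>
using namespace Rcpp;

// Adaptive random-walk Metropolis-within-Gibbs chain for the hierarchical
// joint-encounter (JE) and dead-recovery (DR) models, run entirely in
// compiled code for speed. Randomness comes from R's RNG (norm_rand /
// unif_rand under RNGScope), so a set.seed() before the call makes the
// chain bit-reproducible.
//
// Parameter vector layout (transformed scale), families in fixed order:
// per family f with K random effects: [u_f, v_f, eps_f1 .. eps_fK] with
//   mu_f    = lo[f] + wd[f] * plogis(u_f)        (uniform prior on mu)
//   sigma_f = sigma_upper * plogis(v_f)          (uniform prior on sigma)
//   theta_ft = plogis(qlogis(mu_f) + eps_ft),  eps_ft ~ N(0, sigma_f^2)

static inline double plogis_fast(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// forward-algorithm JE log-likelihood over pooled histories (see forward.cpp
// for the commented reference implementation of the same recursion)
static double je_ll(const IntegerMatrix &sym, const IntegerVector &first,
                    const NumericVector &mult, const double *S,
                    const double *F, const double *r, const double *p,
                    int T) {
  const int n = sym.nrow();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const int f = first[i];
    double a1 = 1.0, a2 = 0.0, a3 = 0.0, a4 = 0.0, ll = 0.0;
    bool impossible = false;
    for (int t = f + 1; t <= T; ++t) {
      const int k = t - 2;
      const double St = S[k], Ft = F[k], rt = r[k], pt = p[k];
      const double b1 = a1 * St * Ft;
      const double b2 = a1 * St * (1.0 - Ft) + a2 * St;
      const double b3 = (a1 + a2) * (1.0 - St) * rt;
      const double b4 = (a1 + a2) * (1.0 - St) * (1.0 - rt) + a3 + a4;
      const int y = sym(i, t - 1);
      if (y == 1) { a1 = b1 * pt; a2 = a3 = a4 = 0.0; }
      else if (y == 2) { a1 = a2 = a4 = 0.0; a3 = b3; }
      else { a1 = b1 * (1.0 - pt); a2 = b2; a3 = 0.0; a4 = b4; }
      const double s = a1 + a2 + a3 + a4;
      if (s <= 0.0) { impossible = true; break; }
      ll += std::log(s);
      a1 /= s; a2 /= s; a3 /= s; a4 /= s;
      if (y == 2) break;
    }
    total += mult[i] * (impossible ? R_NegInf : ll);
  }
  return total;
}

// Seber m-array log-likelihood: counts is J x (K+1) with the remainder in
// the last column; the multinomial coefficient is omitted.
static double dr_ll(const NumericMatrix &counts, const double *S,
                    const double *r, int K) {
  const int J = counts.nrow();
  double ll = 0.0;
  std::vector<double> cp(K + 1);
  cp[0] = 1.0;
  for (int k = 0; k < K; ++k) cp[k + 1] = cp[k] * S[k];
  for (int j = 0; j < J; ++j) {
    double rowsum = 0.0;
    for (int k = j; k < K; ++k) {
      const double pi = cp[k] / cp[j] * (1.0 - S[k]) * r[k];
      rowsum += pi;
      const double c = counts(j, k);
      if (c > 0.0) {
        if (pi <= 0.0) return R_NegInf;
        ll += c * std::log(pi);
      }
    }
    const double c = counts(j, K);
    if (c > 0.0) {
      const double rem = 1.0 - rowsum;
      if (rem <= 0.0) return R_NegInf;
      ll += c * std::log(rem);
    }
  }
  return ll;
}

struct Model {
  int type;  // 0 prior-only, 1 JE, 2 DR
  int nf, K, T;
  IntegerMatrix sym;
  IntegerVector first;
  NumericVector mult;
  NumericMatrix counts;
  NumericVector lo, wd;
  double sigma_upper;
  std::vector<double> theta;  // nf * K workspace

  double log_post(const double *x) {
    double lp = 0.0;
    for (int f = 0; f < nf; ++f) {
      const double *xf = x + f * (K + 2);
      const double u = xf[0], v = xf[1];
      const double au = std::fabs(u), av = std::fabs(v);
      lp += -au - 2.0 * std::log1p(std::exp(-au))
            - av - 2.0 * std::log1p(std::exp(-av));
      double sigma = sigma_upper * plogis_fast(v);
      if (sigma < 1e-12) sigma = 1e-12;
      lp -= K * std::log(sigma);
      double qmu = 0.0;
      const double mu = lo[f] + wd[f] * plogis_fast(u);
      qmu = std::log(mu) - std::log1p(-mu);
      double *th = &theta[f * K];
      for (int k = 0; k < K; ++k) {
        const double e = xf[2 + k];
        lp -= 0.5 * (e / sigma) * (e / sigma);
        th[k] = plogis_fast(qmu + e);
      }
    }
    if (!std::isfinite(lp)) return R_NegInf;
    if (type == 1) {
      lp += je_ll(sym, first, mult, &theta[0], &theta[K], &theta[2 * K],
                  &theta[3 * K], T);
    } else if (type == 2) {
      lp += dr_ll(counts, &theta[0], &theta[K], K);
    }
    return lp;
  }
};

// [[Rcpp::export]]
NumericMatrix mwg_chain_cpp(int model_type, List data, int nf, int K,
                            NumericVector lo, NumericVector wd,
                            double sigma_upper, int n_iter, int n_burnin,
                            int thin, NumericVector x0) {
  Model m;
  m.type = model_type; m.nf = nf; m.K = K;
  m.lo = lo; m.wd = wd; m.sigma_upper = sigma_upper;
  m.theta.assign(nf * K, 0.0);
  if (model_type == 1) {
    m.sym = as<IntegerMatrix>(data["sym"]);
    m.first = as<IntegerVector>(data["first"]);
    m.mult = as<NumericVector>(data["mult"]);
    m.T = m.sym.ncol();
  } else if (model_type == 2) {
    m.counts = as<NumericMatrix>(data["counts"]);
  }
  const int n_par = nf * (K + 2);
  std::vector<double> x(x0.begin(), x0.end());
  double lp = m.log_post(x.data());
  if (!std::isfinite(lp)) stop("non-finite log posterior at the initial point");

  // scalar random-walk scales plus, per family, scales for the two
  // interweaving moves (mean-effects translation, SD-effects rescaling)
  std::vector<double> lstep(n_par, std::log(0.4));
  std::vector<int> acc(n_par, 0);
  std::vector<double> lstep_tr(nf, std::log(0.3)), lstep_sc(nf, std::log(0.3));
  std::vector<int> acc_tr(nf, 0), acc_sc(nf, 0);
  int batch = 0, kept_i = 0;
  const int n_keep = (n_iter - n_burnin) / thin;
  NumericMatrix kept(n_keep, n_par);

  RNGScope scope;
  for (int iter = 1; iter <= n_iter; ++iter) {
    for (int j = 0; j < n_par; ++j) {
      const double old = x[j];
      x[j] = old + std::exp(lstep[j]) * norm_rand();
      const double lpp = m.log_post(x.data());
      if (std::isfinite(lpp) && std::log(unif_rand()) < lpp - lp) {
        lp = lpp;
        acc[j] += 1;
      } else {
        x[j] = old;
      }
    }

    // Interweaving moves, one pair per family. They target the two slow
    // directions of the centered hierarchy: (a) translating the grand mean
    // against the effects with the year-specific values held fixed (the
    // likelihood cancels), and (b) rescaling the effects together with
    // their SD (the effects' prior and the Jacobian cancel).
    for (int f = 0; f < nf; ++f) {
      double *xf = x.data() + f * (K + 2);
      // (a) translation: qlogis(mu) += delta, eps -= delta; theta unchanged
      {
        const double delta = std::exp(lstep_tr[f]) * norm_rand();
        const double mu = lo[f] + wd[f] * plogis_fast(xf[0]);
        const double qmu = std::log(mu) - std::log1p(-mu);
        const double mu2 = plogis_fast(qmu + delta);
        if (mu2 > lo[f] && mu2 < lo[f] + wd[f]) {
          const double sigma = std::max(sigma_upper * plogis_fast(xf[1]), 1e-12);
          double dquad = 0.0;
          for (int k = 0; k < K; ++k) {
            const double e2 = xf[2 + k] - delta;
            dquad += e2 * e2 - xf[2 + k] * xf[2 + k];
          }
          const double lacc = std::log(mu2) + std::log1p(-mu2)
                            - std::log(mu) - std::log1p(-mu)
                            - 0.5 * dquad / (sigma * sigma);
          if (std::log(unif_rand()) < lacc) {
            xf[0] = std::log(mu2 - lo[f]) - std::log(lo[f] + wd[f] - mu2);
            for (int k = 0; k < K; ++k) xf[2 + k] -= delta;
            lp = m.log_post(x.data());
            acc_tr[f] += 1;
          }
        }
      }
      // (b) rescaling: v += delta, eps *= sigma2/sigma; needs the likelihood
      {
        const double delta = std::exp(lstep_sc[f]) * norm_rand();
        const double v = xf[1], v2 = v + delta;
        const double c = plogis_fast(v2) / std::max(plogis_fast(v), 1e-300);
        std::vector<double> eps_old(K);
        for (int k = 0; k < K; ++k) {
          eps_old[k] = xf[2 + k];
          xf[2 + k] *= c;
        }
        xf[1] = v2;
        const double lpp = m.log_post(x.data());
        // log_post already holds the v prior and the scaled-eps prior; the
        // eps-prior change (-K log c) is exactly undone by the map's
        // Jacobian (+K log c), so the remaining correction is +K log c
        const double lacc = lpp - lp + K * std::log(c);
        if (std::isfinite(lpp) && std::log(unif_rand()) < lacc) {
          lp = lpp;
          acc_sc[f] += 1;
        } else {
          xf[1] = v;
          for (int k = 0; k < K; ++k) xf[2 + k] = eps_old[k];
        }
      }
    }

    if (iter <= n_burnin && iter % 50 == 0) {
      batch += 1;
      const double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
      for (int j = 0; j < n_par; ++j) {
        lstep[j] += (acc[j] / 50.0 > 0.44) ? delta : -delta;
        acc[j] = 0;
      }
      for (int f = 0; f < nf; ++f) {
        lstep_tr[f] += (acc_tr[f] / 50.0 > 0.3) ? delta : -delta;
        lstep_sc[f] += (acc_sc[f] / 50.0 > 0.3) ? delta : -delta;
        acc_tr[f] = 0; acc_sc[f] = 0;
      }
    }
    if (iter > n_burnin && (iter - n_burnin) % thin == 0) {
      for (int j = 0; j < n_par; ++j) kept(kept_i, j) = x[j];
      kept_i += 1;
    }
  }
  return kept;
}
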