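// Computational core: data-augmented Gibbs sampler for the multivariate
// probit mixture (latent class model with free within-class correlation
// matrices), inverse-Wishart prior sampling, posterior predictive
// discrepancies, and a quasi-Monte Carlo multivariate-normal orthant
// probability routine.
//
// All randomness flows through R's RNG (unif_rand / exp_rand / Rf_rchisq),
// so set.seed() on the R side makes every exported routine reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Box-Muller normal generator driven by R's uniform stream.  A local
// instance per exported call keeps the cached spare from leaking state
// across calls.
struct BoxMuller {
  bool has_spare = false;
  double spare = 0.0;
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u1;
    do { u1 = unif_rand(); } while (u1 <= 0.0);
    const double u2 = unif_rand();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// Standard normal truncated to [a, Inf).  Plain rejection is efficient for
// a below ~0.45; Robert's (1995) translated-exponential rejection covers
// the upper tail with bounded expected cost.
double rtnorm_lower_std(double a, BoxMuller& bm) {
  if (a < 0.45) {
    for (;;) {
      const double z = bm();
      if (z >= a) return z;
    }
  }
  const double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    const double z = a + exp_rand() / lambda;
    const double d = z - lambda;
    if (unif_rand() <= std::exp(-0.5 * d * d)) return z;
  }
}

// N(mean, sd^2) truncated to [0, Inf) when positive, (-Inf, 0) otherwise.
double rtnorm01(double mean, double sd, bool positive, BoxMuller& bm) {
  if (positive) return mean + sd * rtnorm_lower_std(-mean / sd, bm);
  return mean - sd * rtnorm_lower_std(mean / sd, bm);
}

// Draw W ~ InverseWishart(Psi, nu) by Bartlett decomposition of the
// Wishart(Psi^{-1}, nu) draw; returns W without forming explicit inverses:
// W = Lp A^{-T} A^{-1} Lp^T with Psi = Lp Lp^T and A the Bartlett factor.
arma::mat riwishart(const arma::mat& Psi, double nu, BoxMuller& bm) {
  const arma::uword p = Psi.n_rows;
  arma::mat Lp = arma::chol(Psi, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(Rf_rchisq(nu - static_cast<double>(i)));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = bm();
  }
  // M1 = A^{-1} Lp^T  =>  W = M1^T M1
  arma::mat M1 = arma::solve(arma::trimatl(A), Lp.t());
  return M1.t() * M1;
}

void cov2cor_inplace(arma::mat& W) {
  const arma::uword p = W.n_rows;
  arma::vec d(p);
  for (arma::uword i = 0; i < p; ++i) d(i) = 1.0 / std::sqrt(W(i, i));
  for (arma::uword i = 0; i < p; ++i)
    for (arma::uword j = 0; j < p; ++j) W(i, j) *= d(i) * d(j);
}

// Column index of pair (j, k), j < k (0-based), in the flattened
// upper-triangle ordering (0,1), (0,2), ..., (0,J-1), (1,2), ...
inline int pair_col(int j, int k, int J) {
  return j * J - j * (j + 1) / 2 + (k - j - 1);
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_prior_corr_draws(int iw_df, int n_items, int n_draws) {
  BoxMuller bm;
  NumericVector out(n_draws);
  const arma::mat I = arma::eye(n_items, n_items);
  int n_failed = 0;
  for (int t = 0; t < n_draws; ++t) {
    for (;;) {
      try {
        arma::mat W = riwishart(I, iw_df, bm);
        out[t] = W(0, 1) / std::sqrt(W(0, 0) * W(1, 1));
        break;
      } catch (...) {
        if (++n_failed > n_draws) stop("inverse-Wishart sampling failed repeatedly");
      }
    }
  }
  out.attr("n_resampled") = n_failed;
  return out;
}

// Gibbs sampler for the multivariate probit mixture under the
// non-identified parameter expansion: the state carries each class's
// latent COVARIANCE matrix W_m with conjugate update
// W_m | y*, X ~ IW(I + S_m, f + n_m).  The latent scale adapts to the
// prior (W ~ I / (f - p - 1) a priori), which is what makes the
// inverse-Wishart degrees of freedom control the shrinkage of the
// identified correlations.  Stored draws are the IDENTIFIED parameters:
// standardized thresholds mu_j / sqrt(W_jj) and correlations cov2cor(W).
//' @noRd
// [[Rcpp::export]]
List cpp_gibbs(const IntegerMatrix& Y, int M, double mu0, double v0,
               const arma::vec& dir_alpha, double iw_df,
               int n_iter, int n_burn, int thin,
               const IntegerVector& z_init, const arma::mat& mu_init,
               double w0, int n_inner) {
  const int N = Y.nrow();
  const int J = Y.ncol();
  const int JP = J * (J - 1) / 2;
  BoxMuller bm;

  // transposed 0/1 copy for cache-friendly row sweeps
  std::vector<unsigned char> yt(static_cast<size_t>(J) * std::max(N, 1));
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < J; ++j) yt[static_cast<size_t>(i) * J + j] = Y(i, j);

  arma::ivec z(std::max(N, 1));
  for (int i = 0; i < N; ++i) z(i) = z_init[i];  // 0-based classes
  arma::mat mu = mu_init;                        // M x J, raw (W) scale
  arma::vec q(M, arma::fill::value(1.0 / M));
  // start the latent covariance at the prior's equilibrium scale
  // w0 = 1 / (f - p - 1) so the first sweeps are shock-free
  arma::cube W(J, J, M);
  for (int m = 0; m < M; ++m) W.slice(m) = w0 * arma::eye(J, J);

  // latent responses, J x N
  const double sd0 = std::sqrt(w0);
  arma::mat ystar(J, std::max(N, 1));
  for (int i = 0; i < N; ++i) {
    const int m = z(i);
    for (int j = 0; j < J; ++j)
      ystar(j, i) = rtnorm01(mu(m, j), sd0, yt[static_cast<size_t>(i) * J + j] == 1, bm);
  }

  const int n_ret = (n_iter - n_burn + thin - 1) / thin;
  arma::mat q_draws(n_ret, M);
  arma::mat mu_draws(n_ret, M * J);
  arma::mat rho_draws(n_ret, M * JP);

  arma::cube P(J, J, M);        // per-class precision of W
  arma::vec logdet(M);
  arma::mat cond_sd(M, J);
  arma::ivec nm(M);
  arma::vec empty_run(M, arma::fill::zeros);
  arma::mat Psi(J, J), Apost(J, J);
  arma::vec svec(J), b(J), zv(J), ll(M), pr(M), logq(M);
  int n_empty_events = 0, n_pd_redraw = 0, stored = 0;
  nm.zeros();
  for (int i = 0; i < N; ++i) ++nm(z(i));

  for (int iter = 1; iter <= n_iter; ++iter) {
   // inner sub-iterations advance the strongly coupled (y*, W) pair
   // several steps per sweep (class memberships, proportions and
   // thresholds are updated once, on the last sub-iteration)
   for (int inner = 0; inner < n_inner; ++inner) {
    // cache precision matrices, log determinants, conditional sds
    for (int m = 0; m < M; ++m) {
      arma::mat L = arma::chol(W.slice(m), "lower");
      logdet(m) = 2.0 * arma::sum(arma::log(L.diag()));
      P.slice(m) = arma::inv_sympd(W.slice(m));
      for (int j = 0; j < J; ++j) cond_sd(m, j) = 1.0 / std::sqrt(P.slice(m)(j, j));
    }

    // (1) latent responses: systematic-scan truncated-normal conditionals
    for (int i = 0; i < N; ++i) {
      const int m = z(i);
      const arma::mat& Pm = P.slice(m);
      const unsigned char* yrow = &yt[static_cast<size_t>(i) * J];
      double* ys = ystar.colptr(i);
      for (int j = 0; j < J; ++j) {
        double d = 0.0;
        const double* pcol = Pm.colptr(j);  // symmetric: column == row
        for (int k = 0; k < J; ++k) d += pcol[k] * (ys[k] - mu(m, k));
        d -= pcol[j] * (ys[j] - mu(m, j));
        const double mcond = mu(m, j) - d / pcol[j];
        ys[j] = rtnorm01(mcond, cond_sd(m, j), yrow[j] == 1, bm);
      }
    }

    if (inner == n_inner - 1) {
    // (2) class memberships given latent responses
    nm.zeros();
    for (int m = 0; m < M; ++m) logq(m) = std::log(q(m));
    for (int i = 0; i < N; ++i) {
      const double* ys = ystar.colptr(i);
      for (int m = 0; m < M; ++m) {
        const arma::mat& Pm = P.slice(m);
        double quad = 0.0;
        for (int j = 0; j < J; ++j) {
          const double rj = ys[j] - mu(m, j);
          const double* pcol = Pm.colptr(j);
          double s = 0.0;
          for (int k = j + 1; k < J; ++k) s += pcol[k] * (ys[k] - mu(m, k));
          quad += pcol[j] * rj * rj + 2.0 * rj * s;
        }
        ll(m) = logq(m) - 0.5 * logdet(m) - 0.5 * quad;
      }
      const double mx = ll.max();
      double tot = 0.0;
      for (int m = 0; m < M; ++m) { pr(m) = std::exp(ll(m) - mx); tot += pr(m); }
      double u = unif_rand() * tot;
      int m = 0;
      while (m < M - 1 && u > pr(m)) { u -= pr(m); ++m; }
      z(i) = m;
      ++nm(m);
    }
    for (int m = 0; m < M; ++m) {
      if (N > 0 && nm(m) == 0) {
        if (++empty_run(m) == 50) ++n_empty_events;
      } else empty_run(m) = 0;
    }

    // (3) class proportions
    {
      double tot = 0.0;
      for (int m = 0; m < M; ++m) { q(m) = Rf_rgamma(dir_alpha(m) + nm(m), 1.0); tot += q(m); }
      q /= tot;
    }

    // (4) thresholds: conjugate MVN update given W_m and the independent
    //     N(mu0, v0) element prior (on the raw latent scale)
    for (int m = 0; m < M; ++m) {
      svec.zeros();
      for (int i = 0; i < N; ++i)
        if (z(i) == m) svec += ystar.col(i);
      Apost = nm(m) * P.slice(m);
      Apost.diag() += 1.0 / v0;
      b = P.slice(m) * svec;
      b += mu0 / v0;
      arma::mat La = arma::chol(Apost, "lower");
      arma::vec mean_m = arma::solve(arma::trimatu(La.t()),
                                     arma::solve(arma::trimatl(La), b));
      for (int j = 0; j < J; ++j) zv(j) = bm();
      arma::vec draw = mean_m + arma::solve(arma::trimatu(La.t()), zv);
      mu.row(m) = draw.t();
    }
    }  // end once-per-sweep block (steps 2-4)

    // (5) latent covariance: conjugate inverse-Wishart draw (no rescaling
    //     of the state; standardization happens only at storage)
    for (int m = 0; m < M; ++m) {
      Psi.eye();
      for (int i = 0; i < N; ++i) {
        if (z(i) != m) continue;
        const double* ys = ystar.colptr(i);
        for (int j = 0; j < J; ++j) {
          const double rj = ys[j] - mu(m, j);
          double* pc = Psi.colptr(j);
          for (int k = j; k < J; ++k) pc[k] += (ys[k] - mu(m, k)) * rj;
        }
      }
      Psi = arma::symmatl(Psi);
      for (;;) {
        try {
          arma::mat Wm = riwishart(Psi, iw_df + nm(m), bm);
          arma::mat L = arma::chol(Wm, "lower");  // PD guard
          (void)L;
          W.slice(m) = 0.5 * (Wm + Wm.t());
          break;
        } catch (...) {
          if (++n_pd_redraw > 1000 + n_iter) stop("covariance update failed repeatedly");
        }
      }
    }
   }  // end inner sub-iterations

    // (6) scale group move (generalized Gibbs along the non-identified
    //     direction): propose (W, mu, y*) -> (sW, sqrt(s) mu, sqrt(s) y*)
    //     with a log-normal random walk in s.  Identified quantities are
    //     invariant; the move anchors and decorrelates the latent scale,
    //     which otherwise random-walks (slowly) for small iw_df.
    {
      const double A = M * J * (1.0 - iw_df) / 2.0;
      double beta = 0.0;
      for (int m = 0; m < M; ++m)
        beta += 0.5 * arma::trace(arma::inv_sympd(W.slice(m)));
      double gam = 0.0, mu_dot = 0.0;
      for (int m = 0; m < M; ++m)
        for (int j = 0; j < J; ++j) {
          gam += mu(m, j) * mu(m, j);
          mu_dot += mu(m, j) * mu0;
        }
      gam /= (2.0 * v0);
      mu_dot /= v0;
      const double sigma = std::sqrt(2.0 / (std::fabs(A) + 2.0));
      for (int rep = 0; rep < 2; ++rep) {
        const double ls = sigma * bm();
        const double s = std::exp(ls);
        const double rs = std::sqrt(s);
        const double logacc = (A + 1.0) * ls - beta * (1.0 / s - 1.0) -
                              gam * (s - 1.0) + mu_dot * (rs - 1.0);
        if (std::log(unif_rand()) <= logacc) {
          W *= s;
          mu *= rs;
          if (N > 0) ystar.cols(0, N - 1) *= rs;
          beta /= s;
          gam *= s;
          mu_dot *= rs;
        }
      }
    }

    // storage with per-draw relabeling: classes ordered by decreasing
    // mean standardized threshold (class 1 = high-endorsement class)
    if (iter > n_burn && (iter - n_burn - 1) % thin == 0) {
      arma::mat mu_std(M, J);
      for (int m = 0; m < M; ++m)
        for (int j = 0; j < J; ++j)
          mu_std(m, j) = mu(m, j) / std::sqrt(W.slice(m)(j, j));
      arma::vec mbar = arma::mean(mu_std, 1);
      arma::uvec ord = arma::sort_index(mbar, "descend");
      for (int m = 0; m < M; ++m) {
        const int src = ord(m);
        q_draws(stored, m) = q(src);
        for (int j = 0; j < J; ++j) mu_draws(stored, m * J + j) = mu_std(src, j);
        const arma::mat& Wm = W.slice(src);
        for (int j = 0; j < J; ++j)
          for (int k = j + 1; k < J; ++k)
            rho_draws(stored, m * JP + pair_col(j, k, J)) =
              Wm(j, k) / std::sqrt(Wm(j, j) * Wm(k, k));
      }
      ++stored;
    }
    if (iter % 512 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["q"] = q_draws, _["mu"] = mu_draws, _["rho"] = rho_draws,
                      _["n_empty_events"] = n_empty_events,
                      _["n_pd_redraw"] = n_pd_redraw);
}

namespace {

// rebuild M correlation matrices (with unit diagonal) from one flattened
// draw row
void unpack_sigma(const double* rho_row, int M, int J, arma::cube& Sigma) {
  const int JP = J * (J - 1) / 2;
  for (int m = 0; m < M; ++m) {
    arma::mat& S = Sigma.slice(m);
    S.eye(J, J);
    for (int j = 0; j < J; ++j)
      for (int k = j + 1; k < J; ++k) {
        const double r = rho_row[m * JP + pair_col(j, k, J)];
        S(j, k) = r;
        S(k, j) = r;
      }
  }
}

// likelihood-ratio chi-square over response patterns with counts > 0
double lr_discrepancy(const std::vector<int>& counts, int N,
                      const std::vector<double>& prob) {
  double d = 0.0;
  const int C = static_cast<int>(counts.size());
  for (int c = 0; c < C; ++c) {
    if (counts[c] > 0)
      d += counts[c] * std::log(counts[c] / (N * prob[c]));
  }
  return 2.0 * d;
}

}  // namespace

// Posterior predictive discrepancies.  For each supplied posterior draw:
// estimate all 2^J pattern probabilities by Monte Carlo simulation of the
// latent mixture (n_mc latent vectors, smoothed by adding `smooth` to every
// pattern cell), compute the observed LR discrepancy, generate a replicated
// dataset of size N from the same draw, and compute its discrepancy.
//' @noRd
// [[Rcpp::export]]
List cpp_ppp(const IntegerMatrix& Y, const arma::mat& q_draws,
             const arma::mat& mu_draws, const arma::mat& rho_draws,
             int M, int n_mc, double smooth) {
  const int N = Y.nrow();
  const int J = Y.ncol();
  if (J > 30) stop("pattern enumeration infeasible for J > 30");
  const int C = 1 << J;
  const int T = q_draws.n_rows;
  BoxMuller bm;

  std::vector<int> counts_obs(C, 0);
  for (int i = 0; i < N; ++i) {
    int id = 0;
    for (int j = 0; j < J; ++j)
      if (Y(i, j) == 1) id |= (1 << j);
    ++counts_obs[id];
  }

  NumericVector d_obs(T), d_rep(T);
  arma::cube Sigma(J, J, M);
  arma::cube L(J, J, M);
  arma::vec zv(J), yv(J);
  std::vector<double> prob(C);
  std::vector<int> counts_rep(C);

  for (int t = 0; t < T; ++t) {
    {
      arma::rowvec rr = rho_draws.row(t);
      unpack_sigma(rr.memptr(), M, J, Sigma);
    }
    arma::vec q = q_draws.row(t).t();
    arma::vec cq = arma::cumsum(q);
    for (int m = 0; m < M; ++m)
      L.slice(m) = arma::chol(Sigma.slice(m), "lower");

    // MC pattern probabilities under the mixture
    std::fill(prob.begin(), prob.end(), smooth);
    double tot = smooth * C;
    for (int s = 0; s < n_mc; ++s) {
      const double u = unif_rand();
      int m = 0;
      while (m < M - 1 && u > cq(m)) ++m;
      for (int j = 0; j < J; ++j) zv(j) = bm();
      const arma::mat& Lm = L.slice(m);
      int id = 0;
      for (int j = 0; j < J; ++j) {
        double y = mu_draws(t, m * J + j);
        for (int k = 0; k <= j; ++k) y += Lm(j, k) * zv(k);
        if (y >= 0.0) id |= (1 << j);
      }
      prob[id] += 1.0;
    }
    tot += n_mc;
    for (int c = 0; c < C; ++c) prob[c] /= tot;

    d_obs[t] = lr_discrepancy(counts_obs, N, prob);

    // replicated data from the same draw
    std::fill(counts_rep.begin(), counts_rep.end(), 0);
    for (int i = 0; i < N; ++i) {
      const double u = unif_rand();
      int m = 0;
      while (m < M - 1 && u > cq(m)) ++m;
      for (int j = 0; j < J; ++j) zv(j) = bm();
      const arma::mat& Lm = L.slice(m);
      int id = 0;
      for (int j = 0; j < J; ++j) {
        double y = mu_draws(t, m * J + j);
        for (int k = 0; k <= j; ++k) y += Lm(j, k) * zv(k);
        if (y >= 0.0) id |= (1 << j);
      }
      counts_rep[id] += 1;
    }
    d_rep[t] = lr_discrepancy(counts_rep, N, prob);
    if (t % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["d_obs"] = d_obs, _["d_rep"] = d_rep);
}

// Per-class Monte Carlo pattern probabilities for one parameter set
// (used for entropy / posterior classification).
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_pattern_probs_mc(const arma::mat& mu, const List& sigma,
                                   int n_mc, double smooth) {
  const int M = mu.n_rows;
  const int J = mu.n_cols;
  if (J > 30) stop("pattern enumeration infeasible for J > 30");
  const int C = 1 << J;
  BoxMuller bm;
  NumericMatrix out(C, M);
  arma::vec zv(J);
  for (int m = 0; m < M; ++m) {
    arma::mat S = as<arma::mat>(sigma[m]);
    arma::mat Lm = arma::chol(S, "lower");
    std::vector<double> cnt(C, smooth);
    for (int s = 0; s < n_mc; ++s) {
      for (int j = 0; j < J; ++j) zv(j) = bm();
      int id = 0;
      for (int j = 0; j < J; ++j) {
        double y = mu(m, j);
        for (int k = 0; k <= j; ++k) y += Lm(j, k) * zv(k);
        if (y >= 0.0) id |= (1 << j);
      }
      cnt[id] += 1.0;
    }
    const double tot = n_mc + smooth * C;
    for (int c = 0; c < C; ++c) out(c, m) = cnt[c] / tot;
  }
  return out;
}

// Quasi-Monte Carlo (Richtmyer lattice, randomly shifted through R's RNG)
// orthant probability for N(mu, sigma): P(y_j >= 0 if signs[j] == 1,
// y_j < 0 otherwise), via the sequential conditioning of Genz (1992).
//' @noRd
// [[Rcpp::export]]
double cpp_orthant(const arma::vec& mu, const arma::mat& sigma,
                   const IntegerVector& signs, int n_points) {
  const int J = mu.n_elem;
  static const double primes[] = {2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37,
                                  41, 43, 47, 53, 59, 61, 67, 71, 73, 79, 83,
                                  89, 97, 101, 103, 107, 109, 113};
  if (J > 30) stop("orthant dimension limited to 30");
  arma::mat L = arma::chol(sigma, "lower");
  std::vector<double> sq(J), shift(J);
  for (int j = 0; j < J; ++j) {
    sq[j] = std::sqrt(primes[j]);
    shift[j] = unif_rand();
  }
  std::vector<double> z(J);
  double acc = 0.0;
  for (int k = 1; k <= n_points; ++k) {
    double f = 1.0;
    for (int j = 0; j < J; ++j) {
      double s = mu(j);
      for (int i = 0; i < j; ++i) s += L(j, i) * z[i];
      const double t = -s / L(j, j);
      const double pt = Rf_pnorm5(t, 0.0, 1.0, 1, 0);
      double d, e;
      if (signs[j] == 1) { d = pt; e = 1.0; } else { d = 0.0; e = pt; }
      f *= (e - d);
      if (f <= 0.0) { f = 0.0; break; }
      if (j < J - 1) {
        double w = sq[j] * k + shift[j];
        w -= std::floor(w);
        double p = d + w * (e - d);
        if (p <= 0.0) p = 1e-16;
        if (p >= 1.0) p = 1.0 - 1e-16;
        z[j] = Rf_qnorm5(p, 0.0, 1.0, 1, 0);
      }
    }
    acc += f;
  }
  return acc / n_points;
}
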