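# shared fixtures: cached fits so several test files can reuse the same
# moderately expensive MCMC runs

.fixture_env <- new.env(parent = emptyenv())

cached_fit <- function(key, maker) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- maker()
  .fixture_env[[key]]
}

# standard two-class study fit on independence data, weakly informative prior
std_fit0 <- function() {
  cached_fit("fit0", function() {
    d <- generate_dataset(build_population(0), n = 400, seed = 11)
    list(data = d,
         fit = fit_blca(d, 2, prior_from_ladder("weakly informative"),
                        mcmc_config(max_iterations = 1200, seed = 5)))
  })
}

# fit on strong-dependence data, uniform prior (detection setting)
std_fit8 <- function() {
  cached_fit("fit8", function() {
    d <- generate_dataset(build_population(0.8), n = 400, seed = 21)
    list(data = d,
         fit = fit_blca(d, 2, prior_from_ladder("strongly non-informative"),
                        mcmc_config(max_iterations = 1200, seed = 6)))
  })
}

# quadrature oracle for the bivariate normal CDF P(Z1 < h, Z2 < k; rho),
# independent of the package's orthant code
pbvn_oracle <- function(h, k, rho) {
  f <- function(z) {
    stats::dnorm(z) * stats::pnorm((k - rho * z) / sqrt(1 - rho^2))
  }
  stats::integrate(f, -8, h, rel.tol = 1e-9)$value
}

# maximum-likelihood tetrachoric estimate from a 2x2 table of two
# dichotomized variables (oracle built on the quadrature above)
tetrachoric_oracle <- function(x, y) {
  h <- stats::qnorm(mean(x))   # P(x = 1) = P(Z > -h) with threshold at 0
  k <- stats::qnorm(mean(y))
  # match the 0-0 cell: P(x=0, y=0) = P(Z1 < -h, Z2 < -k; rho)
  obj <- function(r) (pbvn_oracle(-h, -k, r) - mean(x == 0 & y == 0))^2
  stats::optimize(obj, c(-0.99, 0.99))$minimum
}
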