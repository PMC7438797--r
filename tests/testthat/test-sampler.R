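# helper: fabricate a minimal fit object from given draw matrices
fake_fit <- function(q, mu, rho, chain, M = 2L, J = 10L) {
  structure(list(draws = list(q = q, mu = mu, rho = rho), chain = chain,
                 n_classes = M, n_items = J, n_obs = 0L,
                 prior = prior_spec(J, 108),
                 config = mcmc_config(seed = 1),
                 diagnostics = list(psr = NULL, max_psr = NA, converged = NA)),
            class = "flexlca_fit")
}

test_that("identical seed and configuration give identical draws", {
  d <- generate_dataset(build_population(0.2), n = 120, seed = 3)
  cfg <- mcmc_config(max_iterations = 400, seed = 42)
  pr <- prior_from_ladder("weakly informative")
  f1 <- fit_blca(d, 2, pr, cfg)
  f2 <- fit_blca(d, 2, pr, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_blca(d, 2, pr, mcmc_config(max_iterations = 400, seed = 43))
  expect_false(identical(f1$draws$rho, f3$draws$rho))
})

test_that("single-class probit fit finds no spurious correlations", {
  # homogeneous population, conditionally independent items; the
  # tolerance reflects the sampling error of a tetrachoric estimate at
  # this N (about 0.027 per pair, 45 pairs)
  set.seed(31)
  Y <- matrix(rbinom(4000 * 10, 1, stats::pnorm(0.3)), 4000, 10)
  fit <- fit_blca(Y, 1, prior_spec(10, 52, class_dirichlet = 10),
                  mcmc_config(max_iterations = 800, seed = 8))
  med <- posterior_medians(fit)
  rho <- med[grep("^rho", names(med))]
  expect_length(rho, 45)
  expect_lt(max(abs(rho)), 0.09)
  expect_lt(mean(abs(rho)), 0.04)
  mu <- med[grep("^mu", names(med))]
  expect_lt(max(abs(mu - 0.3)), 0.08)
})

test_that("prior-only mode reproduces the induced correlation prior", {
  empty <- as_flexlca_data(matrix(integer(0), 0, 10))
  for (df in c(11L, 52L)) {
    fit <- fit_blca(empty, 1, prior_spec(10, df, class_dirichlet = 10),
                    mcmc_config(n_chains = 2, max_iterations = 2000, seed = df))
    r <- fit$draws$rho[, "rho[1,1,2]"]
    v <- marginal_correlation_variance(df, 10)
    se <- sqrt(2 / length(r)) * v * sqrt(1.5)
    expect_lt(abs(mean(r)), 4 * sqrt(v / length(r)))
    expect_lt(abs(var(r) - v), 4 * se)
  }
})

test_that("a large true correlation is recovered within its credible interval", {
  fx <- std_fit8()
  sig <- test_correlation_significance(fx$fit, 1, c(1, 2))
  ci <- attr(sig, "interval")
  expect_true(sig)                  # clearly detected
  expect_gt(attr(sig, "median"), 0.5)
  expect_true(ci[1] <= 0.85 && 0.5 <= ci[2])  # interval in the right region
  # the two untouched dependent pairs are estimated high as well
  expect_gt(median(correlation_draws(fx$fit, 1, c(5, 7))), 0.5)
  expect_gt(median(correlation_draws(fx$fit, 2, c(4, 6))), 0.4)
})

test_that("Gelman-Rubin diagnostics behave on engineered chains", {
  n <- 60
  base <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("q[1]", "q[2]")))
  mu <- matrix(rnorm(n * 20), n, 20)
  rho <- matrix(rnorm(n * 90), n, 90)
  # two chains that are exact copies: PSR = 1 everywhere
  f <- fake_fit(rbind(base, base), rbind(mu, mu), rbind(rho, rho),
                chain = rep(1:2, each = n))
  expect_true(all(abs(gelman_rubin(f) - 1) < 1e-12))
  # large constant offset between chains: PSR >> 1
  f2 <- fake_fit(rbind(base, base + 50), rbind(mu, mu + 50),
                 rbind(rho, rho + 50), chain = rep(1:2, each = n))
  expect_true(all(gelman_rubin(f2) > 5))
  # single chain is an error
  f3 <- fake_fit(base, mu, rho, chain = rep(1L, n))
  expect_error(gelman_rubin(f3), "at least 2 chains")
})

test_that("permuting initial assignments leaves relabeled summaries stable", {
  d <- generate_dataset(build_population(0), n = 300, seed = 77)
  pr <- prior_from_ladder("weakly informative")
  f1 <- fit_blca(d, 2, pr, mcmc_config(max_iterations = 1000, seed = 1))
  f2 <- fit_blca(d, 2, pr, mcmc_config(max_iterations = 1000, seed = 2))
  m1 <- posterior_medians(f1)
  m2 <- posterior_medians(f2)
  expect_equal(m1[1:2], m2[1:2], tolerance = 0.05)        # q
  expect_equal(m1[3:22], m2[3:22], tolerance = 0.15)      # mu
  expect_equal(unname(m1[-(1:22)]), unname(m2[-(1:22)]), tolerance = 0.12)
})

test_that("relabeling orders class 1 as the high-endorsement class", {
  fx <- std_fit0()
  med <- posterior_medians(fx$fit)
  expect_gt(mean(med[grep("^mu\\[1,", names(med))]), 0.5)
  expect_lt(mean(med[grep("^mu\\[2,", names(med))]), -0.5)
})

test_that("simulation-based calibration ranks are consistent with the prior", {
  # single-class, 5 items: generate from the prior + model, fit with the
  # same prior, record the posterior rank of the generating correlation
  J <- 5L; f <- 9L; n_rep <- 12L
  ranks <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(4000 + r)
    rho_true <- sample_prior_correlations(f, J, 1, seed = 4000 + r)
    S <- diag(J); S[1, 2] <- S[2, 1] <- rho_true
    mu_true <- rnorm(J, 0, sqrt(5))
    Z <- matrix(rnorm(60 * J), 60, J) %*% chol(S)
    Y <- (sweep(Z, 2, mu_true, `+`) >= 0) + 0L
    fit <- fit_blca(Y, 1, prior_spec(J, f, class_dirichlet = 10),
                    mcmc_config(n_chains = 1, max_iterations = 400,
                                seed = 5000 + r))
    ranks[r] <- mean(fit$draws$rho[, "rho[1,1,2]"] < rho_true)
  }
  # uniformity at this replication count: reject only gross miscalibration
  expect_gt(suppressWarnings(stats::ks.test(ranks, "punif"))$p.value, 0.01)
  expect_gt(max(ranks), 0.5)
  expect_lt(min(ranks), 0.5)
})

test_that("every stored correlation draw forms a valid correlation matrix", {
  fx <- std_fit8()
  rho <- fx$fit$draws$rho
  expect_true(all(abs(rho) < 1))
  idx <- seq(1, nrow(rho), length.out = 25)
  for (i in round(idx)) {
    for (m in 1:2) {
      S <- diag(10)
      S[upper.tri(S)] <- NA
      draws <- rho[i, (m - 1) * 45 + seq_len(45)]
      k <- 0
      for (a in 1:9) for (b in (a + 1):10) {
        k <- k + 1
        S[a, b] <- S[b, a] <- draws[k]
      }
      expect_true(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0)
    }
  }
})

test_that("configuration and identifiability guards trigger", {
  expect_error(mcmc_config(max_iterations = 150), "at least 100")
  expect_error(mcmc_config(burn_in_fraction = 1.2), "burn_in_fraction")
  d <- generate_dataset(build_population(0), n = 50, seed = 1)
  expect_error(fit_blca(d, 2, prior_spec(9, 108)), "J = 9")
  toy <- as_flexlca_data(matrix(c(0, 1, 1, 0, 1, 1), 3, 2))
  expect_error(fit_blca(toy, 2, prior_spec(2, 108)), "underidentified")
})

test_that("draws persist and reload without changing summaries", {
  fx <- std_fit0()
  base <- file.path(tempdir(), "draws_roundtrip")
  write_draws(fx$fit, base)
  fit2 <- read_draws(base)
  expect_equal(posterior_medians(fit2), posterior_medians(fx$fit))
  expect_equal(fit2$diagnostics$max_psr, fx$fit$diagnostics$max_psr)
  s1 <- summary(fx$fit)
  s2 <- summary(fit2)
  expect_equal(s1$point_estimates, s2$point_estimates)
})
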