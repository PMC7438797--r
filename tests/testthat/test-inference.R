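test_that("credible-interval significance decisions are correct", {
  n <- 200
  mk <- function(vals12) {
    rho <- matrix(0, n, 90)
    colnames(rho) <- grep("^rho", param_names(2, 10), value = TRUE)
    rho[, 1] <- vals12
    structure(list(draws = list(q = matrix(0.5, n, 2), mu = matrix(0, n, 20),
                                rho = rho),
                   chain = rep(1:2, each = n / 2), n_classes = 2L,
                   n_items = 10L, n_obs = 0L),
              class = "flexlca_fit")
  }
  # all draws well inside (0.3, 0.6): significant
  f <- mk(runif(n, 0.3, 0.6))
  expect_true(test_correlation_significance(f, 1, c(1, 2)))
  # symmetric around zero: not significant
  f2 <- mk(rnorm(n, 0, 0.2))
  expect_false(test_correlation_significance(f2, 1, c(1, 2)))
  expect_error(test_correlation_significance(f, 3, c(1, 2)), "class")
  expect_error(test_correlation_significance(f, 1, c(1, 11)), "pair")
})

test_that("significance is monotone in the credible level", {
  fx <- std_fit8()
  ct95 <- correlation_table(fx$fit, level = 0.95)
  ct99 <- correlation_table(fx$fit, level = 0.99)
  expect_true(all(ct95$significant[ct99$significant]))
  # intervals bracket the medians for every parameter
  s <- summary(fx$fit)
  pe <- s$point_estimates
  expect_true(all(pe$ci_low <= pe$median & pe$median <= pe$ci_high))
})

test_that("PPP is near one half when data come from the evaluated draw", {
  # a fixed parameter set repeated as the whole posterior: observed data
  # drawn from it are exchangeable with the replicates
  n_draw <- 60
  q <- matrix(0.5, n_draw, 2)
  mu <- matrix(rep(c(rep(1, 10), rep(-1, 10)), each = n_draw), n_draw, 20)
  rho <- matrix(0, n_draw, 90)
  fit <- structure(list(draws = list(q = q, mu = mu, rho = rho),
                        chain = rep(1:2, each = n_draw / 2),
                        n_classes = 2L, n_items = 10L, n_obs = 0L),
                   class = "flexlca_fit")
  ppps <- vapply(1:8, function(r) {
    d <- generate_dataset(build_population(0), n = 300, seed = 6000 + r)
    as.numeric(compute_ppp(d, fit, n_ppp_draws = 60, seed = r, n_mc = 20000))
  }, numeric(1))
  expect_gt(mean(ppps), 0.25)
  expect_lt(mean(ppps), 0.75)
})

test_that("pattern probabilities normalize and match the bivariate oracle", {
  # quasi-Monte Carlo orthant vs quadrature oracle in two dimensions
  set.seed(1)
  for (rho in c(-0.4, 0, 0.6)) {
    S <- matrix(c(1, rho, rho, 1), 2, 2)
    p00 <- mvn_orthant(c(0.6, -0.2), S, c(0L, 0L), n_points = 16384)
    expect_lt(abs(p00 - pbvn_oracle(-0.6, 0.2, rho)), 1e-4)
    p11 <- mvn_orthant(c(0.6, -0.2), S, c(1L, 1L), n_points = 16384)
    expect_lt(abs(p11 - pbvn_oracle(0.6, -0.2, rho)), 1e-4)
  }
  # full-pattern normalization at J = 10 with a correlated matrix
  S <- diag(10)
  S[1, 2] <- S[2, 1] <- 0.4
  S[3, 9] <- S[9, 3] <- 0.25
  S[5, 7] <- S[7, 5] <- -0.3
  set.seed(2)
  pr <- pattern_probabilities(c(0.5, 0.5), rbind(rep(1, 10), rep(-1, 10)),
                              list(S, diag(10)), method = "orthant",
                              n_points = 4096)
  expect_equal(sum(pr), 1, tolerance = 1e-4)
  set.seed(3)
  pr2 <- pattern_probabilities(c(0.5, 0.5), rbind(rep(1, 10), rep(-1, 10)),
                               list(S, diag(10)), method = "simulation",
                               n_mc = 200000)
  expect_equal(sum(pr2), 1, tolerance = 1e-12)
  # the two estimators agree on the most likely patterns
  top <- order(pr, decreasing = TRUE)[1:5]
  expect_equal(pr[top], pr2[top], tolerance = 0.02)
})

test_that("PPP is invariant to relabeling items", {
  fx <- std_fit0()
  p1 <- as.numeric(compute_ppp(fx$data, fx$fit, n_ppp_draws = 60, seed = 9))
  # permute items in data and identically in all parameter draws
  perm <- c(3, 1, 2, 5, 4, 7, 6, 9, 10, 8)
  d2 <- as_flexlca_data(fx$data$responses[, perm])
  f2 <- fx$fit
  f2$draws$mu <- f2$draws$mu[, c(perm, 10 + perm)]
  reidx <- function(m) {
    k <- 0; out <- integer(45)
    for (a in 1:9) for (b in (a + 1):10) {
      k <- k + 1
      pa <- perm[a]; pb <- perm[b]
      out[k] <- pair_index(min(pa, pb), max(pa, pb), 10)
    }
    (m - 1) * 45 + out
  }
  f2$draws$rho <- f2$draws$rho[, c(reidx(1), reidx(2))]
  p2 <- as.numeric(compute_ppp(d2, f2, n_ppp_draws = 60, seed = 9))
  expect_lt(abs(p1 - p2), 0.12)  # equal up to Monte Carlo noise
})

test_that("margin-based fallback discrepancy produces a valid PPP", {
  fx <- std_fit0()
  p <- compute_ppp(fx$data, fx$fit, n_ppp_draws = 50, seed = 4,
                   method = "margins")
  expect_gte(as.numeric(p), 0)
  expect_lte(as.numeric(p), 1)
  disc <- attr(p, "discrepancies")
  expect_true(all(disc$d_obs >= 0) && all(disc$d_rep >= 0))
})

test_that("classification entropy reflects class separation", {
  fx <- std_fit0()
  e <- classification_entropy(fx$fit, fx$data, seed = 1)
  expect_gt(e, 0.8)   # two-sd separation classifies almost perfectly
  expect_lte(e, 1)
  # single-class fit: entropy 1 by convention
  set.seed(5)
  Y <- matrix(rbinom(600, 1, 0.5), 60, 10)
  f1 <- fit_blca(Y, 1, prior_spec(10, 108, class_dirichlet = 10),
                 mcmc_config(n_chains = 1, max_iterations = 300, seed = 2))
  expect_identical(classification_entropy(f1, Y), 1)
})

test_that("fit summaries serialize to JSON, text and CSV", {
  fx <- std_fit0()
  s <- summary(fx$fit, data = fx$data, n_ppp_draws = 60, ppp_seed = 2)
  expect_s3_class(s, "flexlca_summary")
  expect_true(s$ppp >= 0 && s$ppp <= 1)
  base <- file.path(tempdir(), "fitsum")
  paths <- write_fit_summary(s, base)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths["json"], simplifyVector = TRUE)
  expect_equal(js$ppp, as.numeric(s$ppp))
  ct <- utils::read.csv(paths["csv"])
  expect_identical(nrow(ct), 90L)
  expect_identical(names(ct), c("class", "item_j", "item_k", "median",
                                "ci_low", "ci_high", "significant"))
})
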