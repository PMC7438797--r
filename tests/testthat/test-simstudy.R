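# synthetic replication table covering a balanced factorial grid
synth_reps <- function(ppp_fun, n_rep = 4) {
  g <- expand.grid(N = c(100, 500), corr_size = c(0, 0.5),
                   prior = c("weakly informative", "strongly non-informative"),
                   rep = seq_len(n_rep), stringsAsFactors = FALSE)
  g$ppp <- mapply(ppp_fun, g$N, g$corr_size, g$prior, g$rep)
  g$converged <- TRUE
  for (p in c("rho_1_12", "rho_1_13", "rho_1_38", "rho_1_39", "rho_1_57",
              "rho_2_46")) {
    g[[paste0(p, "_median")]] <- g$corr_size * 0.5
    g[[paste0(p, "_sig")]] <- g$corr_size > 0
  }
  g
}

test_that("eta-squared isolates a single active factor", {
  reps <- synth_reps(function(N, C, P, r) 0.5 - 0.4 * (C > 0))
  eta <- eta_squared(reps)
  expect_equal(unname(eta["C"]), 1)
  expect_equal(unname(eta[c("N", "P", "N:C", "N:P", "C:P", "N:C:P")]),
               rep(0, 6), tolerance = 1e-12)
  # constant PPP: all effects zero
  eta0 <- eta_squared(synth_reps(function(N, C, P, r) 0.5))
  expect_true(all(abs(eta0) < 1e-12))
  # additive two-factor structure splits the variance accordingly
  reps2 <- synth_reps(function(N, C, P, r)
    0.5 - 0.3 * (C > 0) - 0.1 * (P == "strongly non-informative"))
  eta2 <- eta_squared(reps2)
  expect_gt(eta2["C"], eta2["P"])
  expect_equal(unname(eta2["C"] + eta2["P"]), 1, tolerance = 1e-12)
})

test_that("eta-squared validates grid completeness and balance", {
  reps <- synth_reps(function(N, C, P, r) runif(1))
  expect_error(eta_squared(reps[reps$corr_size == 0, ]), "2 levels")
  expect_error(eta_squared(reps[-1, ]), "unbalanced")
  miss <- reps[!(reps$N == 100 & reps$corr_size == 0 &
                   reps$prior == "weakly informative"), ]
  expect_error(eta_squared(miss), "missing cell")
  reps$ppp <- NA_real_
  expect_error(eta_squared(reps), "PPP is missing")
})

test_that("bias table aggregates monitored pairs by condition", {
  reps <- synth_reps(function(N, C, P, r) 0.5)
  reps$rho_1_12_median <- ifelse(reps$prior == "weakly informative", 0.1, 0.3)
  bt <- bias_table(reps)
  expect_identical(names(bt), c("corr_size", "prior", "rho_1_12", "rho_1_13",
                                "rho_1_38"))
  expect_equal(bt$rho_1_12[bt$prior == "weakly informative"], c(0.1, 0.1))
  expect_equal(bt$rho_1_12[bt$prior == "strongly non-informative"], c(0.3, 0.3))
  expect_identical(attr(bt, "sample_sizes"), c(100, 500))
})

test_that("condition grid validates prior names", {
  expect_error(condition_grid(priors = c("weakly informative", "bogus")),
               "unknown prior")
  g <- condition_grid(sample_sizes = 100, corr_sizes = 0,
                      priors = "weakly informative", n_replications = 2)
  expect_s3_class(g, "flexlca_grid")
})

test_that("a small study runs end to end, reproducibly, with checkpoints", {
  g <- condition_grid(sample_sizes = 80L, corr_sizes = c(0, 0.8),
                      priors = "weakly non-informative",
                      n_replications = 2L,
                      mcmc = mcmc_config(max_iterations = 400),
                      master_seed = 5L, compute_ppp = TRUE,
                      n_ppp_draws = 50L, ppp_n_mc = 5000L)
  s1 <- run_study(g)
  expect_s3_class(s1, "flexlca_study")
  expect_identical(nrow(s1$replications), 4L)
  expect_identical(s1$n_failed, 0L)
  expect_true(all(s1$cells$convergence_rate >= 0 & s1$cells$convergence_rate <= 100))
  expect_true(all(s1$replications$ppp >= 0 & s1$replications$ppp <= 1))
  sig_cols <- grep("_pct_sig$", names(s1$cells), value = TRUE)
  expect_true(all(as.matrix(s1$cells[, sig_cols]) %in% c(0, 50, 100)))
  # exact reproducibility of the whole study
  s2 <- run_study(g)
  expect_identical(s1$replications, s2$replications)
  # checkpointed rerun restores identical results
  ckdir <- file.path(tempdir(), "study_ck")
  unlink(ckdir, recursive = TRUE)
  s3 <- run_study(g, checkpoint_dir = ckdir)
  expect_true(length(list.files(ckdir)) >= 1)
  s4 <- run_study(g, checkpoint_dir = ckdir)
  expect_equal(s3$cells, s4$cells)
  # study tables serialize
  outdir <- file.path(tempdir(), "study_tables")
  paths <- write_study_tables(s3, outdir)
  expect_true(all(file.exists(paths)))
})

test_that("detection power increases with sample size", {
  pr <- "weakly non-informative"
  power <- function(N) {
    hits <- vapply(1:6, function(r) {
      row <- run_replication(N, 0.8, pr, rep_seed = derive_seed(9L, N, r),
                             mcmc = mcmc_config(max_iterations = 600),
                             compute_ppp = FALSE)
      row$rho_1_12_sig
    }, logical(1))
    mean(hits)
  }
  expect_gte(power(400), power(60))
})

test_that("per-replication seeds are distinct and stable across cells", {
  s1 <- derive_seed(1L, 100, 0, 1, 1)
  s2 <- derive_seed(1L, 100, 0, 1, 2)
  s3 <- derive_seed(1L, 500, 0, 1, 1)
  expect_true(length(unique(c(s1, s2, s3))) == 3)
  expect_identical(s1, derive_seed(1L, 100, 0, 1, 1))
  expect_true(all(c(s1, s2, s3) > 0))
})
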