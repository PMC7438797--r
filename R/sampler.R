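#' MCMC configuration
#'
#' @param n_chains number of independent chains (>= 1; Gelman-Rubin
#'   diagnostics require >= 2).
#' @param max_iterations iterations per chain.
#' @param burn_in_fraction fraction of each chain discarded as burn-in
#'   (default 0.5: the first half of each chain).
#' @param thin thinning interval (default 1).
#' @param psr_threshold potential-scale-reduction cut below which a model
#'   counts as converged (default 1.05).
#' @param n_inner inner sub-iterations of the coupled latent-response /
#'   covariance updates per sweep.  The conjugate covariance draw inherits
#'   an autocorrelation of roughly n / (n + f - J - 1) from the latent
#'   responses, so weak priors (small f) mix slowly; `NULL` (default)
#'   chooses 1-4 sub-iterations from that ratio at fit time.
#' @param seed integer master seed; per-chain seeds are derived from it.
#' @return an object of class `flexlca_mcmc`.
#' @export
mcmc_config <- function(n_chains = 2L, max_iterations = 2000L,
                        burn_in_fraction = 0.5, thin = 1L,
                        psr_threshold = 1.05, n_inner = NULL, seed = 1L) {
  n_chains <- as.integer(n_chains)
  max_iterations <- as.integer(max_iterations)
  thin <- as.integer(thin)
  if (!is.null(n_inner)) {
    n_inner <- as.integer(n_inner)
    if (n_inner < 1L) stop("n_inner must be at least 1")
  }
  if (burn_in_fraction <= 0 || burn_in_fraction >= 1) {
    stop("burn_in_fraction must lie in (0, 1)")
  }
  if (psr_threshold <= 1) stop("psr_threshold must exceed 1")
  retained <- floor(max_iterations * (1 - burn_in_fraction) / thin)
  if (retained < 100) {
    stop("configuration retains only ", retained,
         " draws per chain; at least 100 are required")
  }
  structure(list(n_chains = n_chains, max_iterations = max_iterations,
                 burn_in_fraction = burn_in_fraction, thin = thin,
                 psr_threshold = psr_threshold, n_inner = n_inner,
                 seed = as.integer(seed)),
            class = "flexlca_mcmc")
}

# deterministic sub-seed derivation (Lehmer-style mixing, stays < 2^31)
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    v <- as.numeric(p)
    if (!is.finite(v)) v <- 0
    h <- (h * 48271 + abs(round(v * 1000)) %% 2147483563 + 1) %% 2147483563
  }
  as.integer(h + 1)
}

pair_index <- function(j, k, J) {
  if (j > k) { tmp <- j; j <- k; k <- tmp }
  (j - 1) * J - j * (j - 1) / 2 + (k - j)
}

param_names <- function(M, J) {
  pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  c(paste0("q[", seq_len(M), "]"),
    as.vector(t(outer(seq_len(M), seq_len(J),
                      function(m, j) paste0("mu[", m, ",", j, "]")))),
    unlist(lapply(seq_len(M), function(m)
      paste0("rho[", m, ",", pairs[, 1], ",", pairs[, 2], "]"))))
}

#' Fit the flexible Bayesian latent class model
#'
#' Data-augmented Gibbs sampling for the multivariate probit mixture: each
#' sweep updates (1) the latent responses by systematic-scan truncated
#' normal conditionals, (2) class memberships, (3) class proportions
#' (Dirichlet), (4) thresholds (conjugate multivariate normal), and (5)
#' each class's correlation matrix by a conjugate inverse-Wishart draw on
#' the latent covariance rescaled to unit diagonal (parameter expansion,
#' consistent with the symmetric-beta marginal prior on each correlation).
#' Draws are relabeled per iteration so classes are ordered by decreasing
#' mean threshold.
#'
#' Chains start from a total-score split of the units into provisional
#' classes (random tie-breaks) with thresholds at the probit of the class
#' item means plus a chain-specific jitter; this keeps starts
#' overdispersed across chains while avoiding the spurious
#' one-class-with-large-correlations mode that symmetric random starts
#' frequently fall into (see the methods vignette).
#'
#' @param data a `flexlca_data` (or 0/1 matrix).  `n = 0` rows runs the
#'   sampler in prior-only mode (useful for validating the realized prior).
#' @param n_classes number of latent classes M.
#' @param prior a `flexlca_prior` with `n_items` matching the data.
#' @param config a `flexlca_mcmc`.
#' @return an object of class `flexlca_fit` containing the pooled
#'   post-burn-in draws (`draws$q`, `draws$mu`, `draws$rho`, with
#'   chain provenance in `chain`), the Gelman-Rubin diagnostics
#'   (`diagnostics`), and the fit inputs.
#' @examples
#' d <- generate_dataset(build_population(0), n = 150, seed = 1)
#' fit <- fit_blca(d, n_classes = 2, prior = prior_from_ladder("weakly informative"),
#'                 config = mcmc_config(max_iterations = 400, seed = 1))
#' fit$diagnostics$max_psr
#' @export
fit_blca <- function(data, n_classes, prior, config = mcmc_config()) {
  if (!inherits(data, "flexlca_data")) data <- as_flexlca_data(data)
  stopifnot(inherits(prior, "flexlca_prior"), inherits(config, "flexlca_mcmc"))
  Y <- data$responses
  N <- nrow(Y)
  J <- ncol(Y)
  M <- as.integer(n_classes)
  if (M < 1L) stop("n_classes must be at least 1")
  if (J != prior$n_items) {
    stop("prior was built for J = ", prior$n_items, " items but data has J = ", J)
  }
  if (any(is.na(Y))) stop("missing responses are not supported")
  # identifiability guard: free parameters must not exceed the pattern
  # degrees of freedom
  n_free <- (M - 1) + M * J + M * J * (J - 1) / 2
  if (N > 0 && (2^J - 1) < n_free) {
    stop("model is underidentified: ", n_free, " free parameters but only ",
         2^J - 1, " response-pattern degrees of freedom (J = ", J,
         " binary items, M = ", M, " classes)")
  }
  alpha <- prior$class_dirichlet
  if (length(alpha) == 1L) alpha <- rep(alpha, M)
  if (length(alpha) != M) {
    stop("class_dirichlet has length ", length(alpha), " but n_classes = ", M)
  }

  n_iter <- config$max_iterations
  n_burn <- as.integer(floor(n_iter * config$burn_in_fraction))
  JP <- J * (J - 1) / 2

  # equilibrium scale of the non-identified latent covariance under
  # IW(I, f): E[W] = I / (f - p - 1).  The state is initialized there and
  # the threshold prior (stated on the standardized probit scale) is
  # mapped onto the raw latent scale with the same factor, so that
  # mu_j / sqrt(W_jj) ~ N(threshold_mean, threshold_variance) effectively.
  w0 <- 1 / max(prior$iw_df - J - 1, 1)

  # sub-iterations of the (latent, covariance) pair per sweep: more for
  # weak priors, whose conjugate covariance update mixes slowly
  n_inner <- config$n_inner
  if (is.null(n_inner)) {
    ar <- (N / M) / (N / M + prior$iw_df - J - 1)
    n_inner <- if (!is.finite(ar) || ar < 0.8) 1L else 2L
    if (N == 0) n_inner <- 1L
  }

  q_all <- NULL; mu_all <- NULL; rho_all <- NULL
  chain_id <- integer(0)
  counters <- c(n_empty_events = 0L, n_pd_redraw = 0L)
  for (ch in seq_len(config$n_chains)) {
    set.seed(derive_seed(config$seed, 7L, ch))
    if (N > 0) {
      # data-informed start: split units by total score (random tie-breaks)
      # into M provisional classes ordered high to low endorsement, and set
      # thresholds to the probit of the class item means plus a
      # chain-specific jitter (overdispersion for Gelman-Rubin)
      score <- rowSums(Y) + stats::runif(N)
      z0 <- if (M == 1L) rep(0L, N) else
        M - as.integer(cut(rank(score), breaks = M, labels = FALSE))
      mu0 <- matrix(0, M, J)
      for (m in seq_len(M)) {
        p_hat <- colMeans(Y[z0 == (m - 1), , drop = FALSE])
        p_hat <- pmin(pmax(p_hat, 1 / (N + 2)), 1 - 1 / (N + 2))
        mu0[m, ] <- (stats::qnorm(p_hat) + stats::rnorm(J, 0, 0.3)) * sqrt(w0)
      }
    } else {
      z0 <- integer(0)
      mu0 <- matrix(stats::rnorm(M * J, prior$threshold_mean,
                                 sqrt(prior$threshold_variance)), M, J) * sqrt(w0)
    }
    res <- cpp_gibbs(Y, M, prior$threshold_mean * sqrt(w0),
                     prior$threshold_variance * w0,
                     alpha, prior$iw_df, n_iter, n_burn, config$thin,
                     if (N > 0) z0[seq_len(N)] else integer(0), mu0, w0,
                     n_inner)
    q_all <- rbind(q_all, res$q)
    mu_all <- rbind(mu_all, res$mu)
    rho_all <- rbind(rho_all, res$rho)
    chain_id <- c(chain_id, rep(ch, nrow(res$q)))
    counters["n_empty_events"] <- counters["n_empty_events"] + res$n_empty_events
    counters["n_pd_redraw"] <- counters["n_pd_redraw"] + res$n_pd_redraw
  }
  if (counters["n_empty_events"] > 0) {
    warning("a class stayed empty for 50+ consecutive iterations ",
            counters["n_empty_events"], " time(s); the Dirichlet prior keeps ",
            "the proportions proper but interpret the fit with care")
  }
  nm <- param_names(M, J)
  colnames(q_all) <- nm[seq_len(M)]
  colnames(mu_all) <- nm[M + seq_len(M * J)]
  colnames(rho_all) <- nm[M + M * J + seq_len(M * JP)]

  fit <- structure(
    list(draws = list(q = q_all, mu = mu_all, rho = rho_all),
         chain = chain_id,
         n_classes = M, n_items = J, n_obs = N,
         prior = prior, config = config,
         counters = counters,
         data_meta = data$meta),
    class = "flexlca_fit")
  fit$diagnostics <- tryCatch({
    if (config$n_chains >= 2L) {
      psr <- gelman_rubin(fit)
      list(psr = psr, max_psr = max(psr),
           converged = all(psr < config$psr_threshold))
    } else {
      list(psr = NULL, max_psr = NA_real_, converged = NA)
    }
  }, error = function(e) list(psr = NULL, max_psr = NA_real_, converged = NA))
  fit
}

#' @export
print.flexlca_fit <- function(x, ...) {
  cat("flexlca fit: M =", x$n_classes, "classes, J =", x$n_items,
      "items, N =", x$n_obs, "\n")
  cat("  chains:", x$config$n_chains, "x", x$config$max_iterations,
      "iterations (", length(x$chain), "retained draws )\n")
  if (!is.null(x$diagnostics$max_psr) && !is.na(x$diagnostics$max_psr)) {
    cat("  max PSR:", signif(x$diagnostics$max_psr, 4),
        if (isTRUE(x$diagnostics$converged)) "(converged)" else "(NOT converged)", "\n")
  }
  q_med <- apply(x$draws$q, 2, stats::median)
  cat("  posterior median class proportions:",
      paste(signif(q_med, 3), collapse = ", "), "\n")
  invisible(x)
}

# all scalar parameters as one draws matrix
all_draws <- function(fit) {
  cbind(fit$draws$q, fit$draws$mu, fit$draws$rho)
}

#' Gelman-Rubin potential scale reduction factors
#'
#' Computes the classical potential scale reduction factor (PSR: ratio of
#' pooled to within-chain variance) for every scalar parameter, using the
#' retained (post-burn-in) draws of each chain.
#'
#' @param fit a `flexlca_fit` with at least 2 chains.
#' @return named numeric vector of PSR values.
#' @export
gelman_rubin <- function(fit) {
  stopifnot(inherits(fit, "flexlca_fit"))
  chains <- unique(fit$chain)
  if (length(chains) < 2L) {
    stop("Gelman-Rubin diagnostics need at least 2 chains; rerun with ",
         "mcmc_config(n_chains = 2) or more")
  }
  X <- all_draws(fit)
  n <- min(table(fit$chain))
  if (n < 50L) stop("at least 50 retained draws per chain are required")
  psr <- vapply(seq_len(ncol(X)), function(p) {
    xs <- split(X[, p], fit$chain)
    means <- vapply(xs, mean, numeric(1))
    vars <- vapply(xs, stats::var, numeric(1))
    W <- mean(vars)
    B_over_n <- stats::var(means)
    if (W <= .Machine$double.eps) {
      return(if (B_over_n <= .Machine$double.eps) 1.0 else Inf)
    }
    # floored at 1: values below 1 are finite-sample artifacts
    max(1, sqrt((n - 1) / n + B_over_n / W))
  }, numeric(1))
  names(psr) <- colnames(X)
  psr
}

#' Posterior medians of all parameters
#'
#' @param fit a `flexlca_fit`.
#' @return named numeric vector of posterior medians (pooled chains).
#' @export
posterior_medians <- function(fit) {
  X <- all_draws(fit)
  stats::setNames(apply(X, 2, stats::median), colnames(X))
}

#' Extract the pooled draws of one correlation parameter
#'
#' @param fit a `flexlca_fit`.
#' @param class_index class m (1-based, after relabeling: class 1 is the
#'   high-endorsement class).
#' @param pair integer pair (j, k) of item indices (1-based).
#' @return numeric vector of draws of `rho[m, j, k]`.
#' @export
correlation_draws <- function(fit, class_index, pair) {
  J <- fit$n_items
  JP <- J * (J - 1) / 2
  if (class_index < 1 || class_index > fit$n_classes) stop("invalid class index")
  j <- pair[1]; k <- pair[2]
  if (j == k || any(c(j, k) < 1) || any(c(j, k) > J)) stop("invalid item pair")
  fit$draws$rho[, (class_index - 1) * JP + pair_index(j, k, J)]
}

#' Persist / reload posterior draws
#'
#' Writes the pooled draws to a CSV (one row per retained draw, chain id in
#' the first column) plus a JSON header with the prior, MCMC configuration,
#' and bookkeeping, so inference can be re-run without refitting.
#'
#' @param fit a `flexlca_fit`.
#' @param path base path; `<path>.csv` and `<path>.json` are written.
#' @return `write_draws` invisibly returns `path`; `read_draws` returns a
#'   `flexlca_fit` (without the original data).
#' @export
write_draws <- function(fit, path) {
  X <- data.frame(chain = fit$chain, all_draws(fit), check.names = FALSE)
  utils::write.csv(X, paste0(path, ".csv"), row.names = FALSE)
  hdr <- list(n_classes = fit$n_classes, n_items = fit$n_items,
              n_obs = fit$n_obs,
              prior = fit$prior[c("n_items", "iw_df", "threshold_mean",
                                  "threshold_variance", "class_dirichlet")],
              config = unclass(fit$config),
              counters = as.list(fit$counters))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
  M <- hdr$n_classes; J <- hdr$n_items; JP <- J * (J - 1) / 2
  chain <- X[[1]]
  X <- as.matrix(X[, -1, drop = FALSE])
  prior <- prior_spec(n_items = J, iw_df = hdr$prior$iw_df,
                      threshold_mean = hdr$prior$threshold_mean,
                      threshold_variance = hdr$prior$threshold_variance,
                      class_dirichlet = hdr$prior$class_dirichlet)
  config <- mcmc_config(n_chains = hdr$config$n_chains,
                        max_iterations = hdr$config$max_iterations,
                        burn_in_fraction = hdr$config$burn_in_fraction,
                        thin = hdr$config$thin,
                        psr_threshold = hdr$config$psr_threshold,
                        seed = hdr$config$seed)
  fit <- structure(
    list(draws = list(q = X[, seq_len(M), drop = FALSE],
                      mu = X[, M + seq_len(M * J), drop = FALSE],
                      rho = X[, M + M * J + seq_len(M * JP), drop = FALSE]),
         chain = chain, n_classes = M, n_items = J, n_obs = hdr$n_obs,
         prior = prior, config = config,
         counters = unlist(hdr$counters)),
    class = "flexlca_fit")
  fit$diagnostics <- if (length(unique(chain)) >= 2) {
    psr <- gelman_rubin(fit)
    list(psr = psr, max_psr = max(psr),
         converged = all(psr < config$psr_threshold))
  } else list(psr = NULL, max_psr = NA_real_, converged = NA)
  fit
}
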