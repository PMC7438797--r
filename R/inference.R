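#' Credible-interval significance test for one correlation
#'
#' A correlation is declared significant when its equal-tailed credible
#' interval (pooled post-burn-in chains) excludes zero — the Bayesian
#' analogue of a two-sided test at nominal level `1 - level`.
#'
#' @param fit a `flexlca_fit`.
#' @param class_index class m (1-based, relabeled order).
#' @param pair item pair (j, k), 1-based.
#' @param level credible level (default 0.95).
#' @return logical scalar with attributes `interval` (length-2 numeric) and
#'   `median`.
#' @export
test_correlation_significance <- function(fit, class_index, pair, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  draws <- correlation_draws(fit, class_index, pair)
  if (!length(draws)) stop("no draws available")
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(draws, c(a, 1 - a), type = 7))
  sig <- ci[1] > 0 || ci[2] < 0
  structure(sig, interval = ci, median = stats::median(draws))
}

#' Correlation summary table
#'
#' @param fit a `flexlca_fit`.
#' @param level credible level for the equal-tailed intervals.
#' @return data.frame with columns `class`, `item_j`, `item_k`, `median`,
#'   `ci_low`, `ci_high`, `significant`.
#' @export
correlation_table <- function(fit, level = 0.95) {
  J <- fit$n_items
  pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  a <- (1 - level) / 2
  out <- do.call(rbind, lapply(seq_len(fit$n_classes), function(m) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
      d <- correlation_draws(fit, m, pairs[r, ])
      ci <- unname(stats::quantile(d, c(a, 1 - a)))
      data.frame(class = m, item_j = pairs[r, 1], item_k = pairs[r, 2],
                 median = stats::median(d), ci_low = ci[1], ci_high = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Posterior predictive p-value (PPP)
#'
#' Model fit check based on the likelihood-ratio chi-square discrepancy
#' over binary response patterns: for each of `n_ppp_draws` evenly spaced
#' post-burn-in draws, the observed discrepancy
#' `D_obs = 2 * sum n_c log(n_c / (N * pi_c))` is compared with the
#' discrepancy `D_rep` of a replicated dataset of the same size generated
#' from that draw; `PPP = mean(D_rep >= D_obs)`.  A value near 0.5
#' indicates good fit, small values indicate misfit.
#'
#' Model-implied pattern probabilities `pi_c` are estimated per draw by
#' simulating `n_mc` latent response vectors from the fitted mixture
#' (`method = "simulation"`, the default), with a small symmetric smoothing
#' count so that no observed pattern has estimated probability zero.  For
#' `J > 15` full-pattern enumeration is refused and the cheaper
#' margin-based discrepancy (univariate plus bivariate Pearson chi-squares)
#' is used with a message.
#'
#' @param data a `flexlca_data` (or 0/1 matrix) the model was fitted to.
#' @param fit a `flexlca_fit`.
#' @param n_ppp_draws number of posterior draws used (default 100, evenly
#'   spaced through the pooled retained draws).
#' @param seed RNG seed for the replicated data and probability estimation.
#' @param method `"simulation"` (pattern LR discrepancy, default) or
#'   `"margins"` (margin-based discrepancy).
#' @param n_mc latent vectors simulated per draw for pattern-probability
#'   estimation.
#' @return the PPP value in `[0, 1]`, with the per-draw discrepancies in
#'   attribute `discrepancies`.
#' @export
compute_ppp <- function(data, fit, n_ppp_draws = 100L, seed = 1L,
                        method = c("simulation", "margins"), n_mc = 30000L) {
  if (!inherits(data, "flexlca_data")) data <- as_flexlca_data(data)
  method <- match.arg(method)
  Y <- data$responses
  J <- ncol(Y)
  if (J != fit$n_items) stop("data and fit disagree on the number of items")
  n_avail <- nrow(fit$draws$q)
  if (n_ppp_draws < 50L) stop("at least 50 posterior draws are required")
  n_ppp_draws <- min(as.integer(n_ppp_draws), n_avail)
  sel <- unique(round(seq(1L, n_avail, length.out = n_ppp_draws)))
  if (J > 15L && method == "simulation") {
    message("J = ", J, " > 15: full-pattern enumeration refused, ",
            "falling back to the margin-based discrepancy")
    method <- "margins"
  }
  set.seed(as.integer(seed))
  if (method == "simulation") {
    res <- cpp_ppp(Y, fit$draws$q[sel, , drop = FALSE],
                   fit$draws$mu[sel, , drop = FALSE],
                   fit$draws$rho[sel, , drop = FALSE],
                   fit$n_classes, as.integer(n_mc), 0.5)
  } else {
    res <- ppp_margins(Y, fit, sel)
  }
  ppp <- mean(res$d_rep >= res$d_obs)
  structure(ppp, discrepancies = data.frame(d_obs = res$d_obs,
                                            d_rep = res$d_rep))
}

# margin-based discrepancy: Pearson chi-squares of the J univariate and
# J(J-1)/2 bivariate margins against model-implied probabilities estimated
# from a simulated sample
ppp_margins <- function(Y, fit, sel) {
  N <- nrow(Y); J <- ncol(Y); M <- fit$n_classes
  JP <- J * (J - 1) / 2
  d_obs <- d_rep <- numeric(length(sel))
  pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
  margin_disc <- function(Yb, P1, P11, pairs) {
    p1 <- colMeans(Yb)
    d <- sum((p1 - P1)^2 / pmax(P1 * (1 - P1), 1e-12)) * nrow(Yb)
    for (r in seq_len(nrow(pairs))) {
      j <- pairs[r, 1]; k <- pairs[r, 2]
      o <- mean(Yb[, j] * Yb[, k])
      e <- P11[r]
      d <- d + nrow(Yb) * (o - e)^2 / pmax(e * (1 - e), 1e-12)
    }
    d
  }
  for (t in seq_along(sel)) {
    i <- sel[t]
    sim <- simulate_from_draw(fit, i, n = 4000L)
    rep_dat <- simulate_from_draw(fit, i, n = N)
    P1 <- colMeans(sim)
    P11 <- vapply(seq_len(nrow(pairs)), function(r)
      mean(sim[, pairs[r, 1]] * sim[, pairs[r, 2]]), numeric(1))
    d_obs[t] <- margin_disc(Y, P1, P11, pairs)
    d_rep[t] <- margin_disc(rep_dat, P1, P11, pairs)
  }
  list(d_obs = d_obs, d_rep = d_rep)
}

# simulate a binary dataset from one stored posterior draw
simulate_from_draw <- function(fit, draw_index, n) {
  M <- fit$n_classes; J <- fit$n_items; JP <- J * (J - 1) / 2
  q <- fit$draws$q[draw_index, ]
  cls <- sample.int(M, n, replace = TRUE, prob = q)
  Y <- matrix(0L, n, J)
  for (m in seq_len(M)) {
    idx <- which(cls == m)
    if (!length(idx)) next
    S <- diag(J)
    S[upper.tri(S)][order_pairs_upper(J)] <-
      fit$draws$rho[draw_index, (m - 1) * JP + seq_len(JP)]
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    mu <- fit$draws$mu[draw_index, (m - 1) * J + seq_len(J)]
    Z <- matrix(stats::rnorm(length(idx) * J), length(idx), J)
    lat <- Z %*% chol(S) + matrix(mu, length(idx), J, byrow = TRUE)
    Y[idx, ] <- (lat >= 0) + 0L
  }
  Y
}

# permutation such that `S[upper.tri(S)][order_pairs_upper(J)] <- rho`
# places the row-major pair sequence (1,2),(1,3),...,(2,3),... correctly
# into R's column-major upper-triangle positions
order_pairs_upper <- function(J) {
  pr <- which(upper.tri(diag(J)), arr.ind = TRUE)  # column-major
  order(pr[, 1], pr[, 2])
}

#' Multivariate normal orthant probability
#'
#' `P(Y_j >= 0)` for items with `signs[j] == 1` and `P(Y_j < 0)` otherwise,
#' for `Y ~ N(mu, sigma)`, computed by quasi-Monte Carlo sequential
#' conditioning (a randomly shifted square-root lattice).  Deterministic
#' given the RNG state; set a seed for reproducibility.
#'
#' @param mu mean vector.
#' @param sigma covariance matrix.
#' @param signs integer vector of 0/1 orthant signs.
#' @param n_points number of lattice points (default 512).
#' @return orthant probability.
#' @export
mvn_orthant <- function(mu, sigma, signs, n_points = 512L) {
  stopifnot(length(mu) == nrow(sigma), length(signs) == length(mu))
  cpp_orthant(as.numeric(mu), as.matrix(sigma), as.integer(signs),
              as.integer(n_points))
}

#' Model-implied response-pattern probabilities
#'
#' Probabilities of all `2^J` binary response patterns under a latent class
#' mixture of multivariate probit models, either by quasi-Monte Carlo
#' orthant integration (`method = "orthant"`) or by Monte Carlo simulation
#' of latent responses (`method = "simulation"`).
#'
#' @param q class proportion vector.
#' @param mu M x J threshold matrix.
#' @param sigma list of M correlation matrices.
#' @param method probability computation method.
#' @param n_points lattice points per orthant (orthant method).
#' @param n_mc simulated latent vectors per class (simulation method).
#' @return numeric vector of length `2^J`, named by pattern strings
#'   (item 1 = least significant position, e.g. `"1100000000"`).
#' @export
pattern_probabilities <- function(q, mu, sigma,
                                  method = c("orthant", "simulation"),
                                  n_points = 2048L, n_mc = 100000L) {
  method <- match.arg(method)
  mu <- as.matrix(mu)
  M <- nrow(mu); J <- ncol(mu)
  if (J > 15L) stop("pattern enumeration refused for J > 15")
  C <- 2L^J
  bits <- function(c) as.integer(intToBits(c - 1L))[seq_len(J)]
  if (method == "orthant") {
    probs <- numeric(C)
    for (c in seq_len(C)) {
      s <- bits(c)
      probs[c] <- sum(vapply(seq_len(M), function(m)
        q[m] * cpp_orthant(mu[m, ], as.matrix(sigma[[m]]), s,
                           as.integer(n_points)),
        numeric(1)))
    }
  } else {
    pm <- cpp_pattern_probs_mc(mu, lapply(sigma, as.matrix),
                               as.integer(n_mc), 0)
    probs <- as.numeric(pm %*% q)
  }
  names(probs) <- vapply(seq_len(C), function(c)
    paste(bits(c), collapse = ""), character(1))
  probs
}

#' Posterior classification entropy
#'
#' Relative entropy of the posterior classification computed at the
#' posterior point estimates (medians): `1 - mean(sum(-p*log(p))) /
#' log(M)`.  1 indicates perfectly separated classes; a single-class model
#' has entropy 1 by convention.
#'
#' @param fit a `flexlca_fit`.
#' @param data the fitted `flexlca_data`.
#' @param n_mc latent vectors per class for pattern-probability estimation.
#' @param seed RNG seed.
#' @return entropy in `[0, 1]`.
#' @export
classification_entropy <- function(fit, data, n_mc = 50000L, seed = 1L) {
  if (!inherits(data, "flexlca_data")) data <- as_flexlca_data(data)
  M <- fit$n_classes; J <- fit$n_items
  if (M == 1L) return(1)
  if (J > 15L) {
    warning("entropy computation requires pattern enumeration (J <= 15)")
    return(NA_real_)
  }
  med <- posterior_medians(fit)
  q <- med[seq_len(M)]
  q <- q / sum(q)
  mu <- matrix(med[M + seq_len(M * J)], M, J, byrow = TRUE)
  JP <- J * (J - 1) / 2
  sigma <- lapply(seq_len(M), function(m) {
    S <- diag(J)
    rho <- med[M + M * J + (m - 1) * JP + seq_len(JP)]
    S[upper.tri(S)][order_pairs_upper(J)] <- rho
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    # medianwise correlation matrices can in principle lose definiteness;
    # nudge if needed
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-8) S <- (S + (abs(ev) + 1e-6) * diag(J)) / (1 + abs(ev) + 1e-6)
    S
  })
  set.seed(as.integer(seed))
  pm <- cpp_pattern_probs_mc(mu, sigma, as.integer(n_mc), 0.5)
  ids <- as.integer(data$responses %*% (2L^(seq_len(J) - 1L))) + 1L
  P <- sweep(pm[ids, , drop = FALSE], 2, q, `*`)
  P <- P / pmax(rowSums(P), .Machine$double.xmin)
  ent <- -rowSums(ifelse(P > 0, P * log(P), 0))
  1 - mean(ent) / log(M)
}

#' Summarize a fitted model
#'
#' Bundles posterior point estimates (medians), equal-tailed credible
#' intervals, the set of significant correlation pairs, convergence
#' diagnostics, classification entropy, and (when data are supplied) the
#' posterior predictive p-value.
#'
#' @param object a `flexlca_fit`.
#' @param data optional `flexlca_data`; enables PPP and entropy.
#' @param level credible level (default 0.95).
#' @param ppp_seed RNG seed for the PPP computation.
#' @param n_ppp_draws posterior draws used for PPP.
#' @param ... unused.
#' @return an object of class `flexlca_summary`.
#' @export
summary.flexlca_fit <- function(object, data = NULL, level = 0.95,
                                ppp_seed = 1L, n_ppp_draws = 100L, ...) {
  X <- all_draws(object)
  a <- (1 - level) / 2
  qs <- t(apply(X, 2, stats::quantile, probs = c(a, 0.5, 1 - a)))
  est <- data.frame(parameter = rownames(qs), ci_low = qs[, 1],
                    median = qs[, 2], ci_high = qs[, 3], row.names = NULL)
  ctab <- correlation_table(object, level = level)
  sig <- ctab[ctab$significant, c("class", "item_j", "item_k")]
  ppp <- entropy <- NA_real_
  if (!is.null(data)) {
    ppp <- as.numeric(compute_ppp(data, object, n_ppp_draws = n_ppp_draws,
                                  seed = ppp_seed))
    entropy <- classification_entropy(object, data,
                                      seed = derive_seed(ppp_seed, 3L))
  }
  structure(list(point_estimates = est, correlation_table = ctab,
                 significant_pairs = sig, ppp = ppp, entropy = entropy,
                 converged = object$diagnostics$converged,
                 max_psr = object$diagnostics$max_psr,
                 level = level, n_obs = object$n_obs,
                 n_classes = object$n_classes, n_items = object$n_items),
            class = "flexlca_summary")
}

#' @export
print.flexlca_summary <- function(x, ...) {
  cat("flexlca summary: M =", x$n_classes, ", J =", x$n_items,
      ", N =", x$n_obs, "\n")
  if (!is.na(x$max_psr)) {
    cat("  convergence: max PSR =", signif(x$max_psr, 4),
        if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  }
  if (!is.na(x$ppp)) cat("  posterior predictive p-value:", signif(x$ppp, 3), "\n")
  if (!is.na(x$entropy)) cat("  classification entropy:", signif(x$entropy, 3), "\n")
  ns <- nrow(x$significant_pairs)
  cat("  significant correlations (", x$level * 100, "% CI excludes 0): ",
      ns, "\n", sep = "")
  if (ns > 0 && ns <= 20) {
    for (r in seq_len(ns)) {
      cat("    rho[", x$significant_pairs$class[r], ",",
          x$significant_pairs$item_j[r], ",",
          x$significant_pairs$item_k[r], "]\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a fit summary to disk
#'
#' Writes a JSON summary, a human-readable text report, and the
#' correlation table as CSV.
#'
#' @param summary a `flexlca_summary`.
#' @param path base path (without extension).
#' @return invisibly, the paths written.
#' @export
write_fit_summary <- function(summary, path) {
  stopifnot(inherits(summary, "flexlca_summary"))
  js <- paste0(path, ".json")
  jsonlite::write_json(
    list(n_classes = summary$n_classes, n_items = summary$n_items,
         n_obs = summary$n_obs, ppp = summary$ppp,
         entropy = summary$entropy, converged = summary$converged,
         max_psr = summary$max_psr,
         point_estimates = summary$point_estimates,
         significant_pairs = summary$significant_pairs),
    js, auto_unbox = TRUE, digits = NA, na = "null")
  cs <- paste0(path, "_correlations.csv")
  utils::write.csv(summary$correlation_table, cs, row.names = FALSE)
  tx <- paste0(path, ".txt")
  con <- file(tx, "w")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  print(summary)
  invisible(c(json = js, csv = cs, txt = tx))
}
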