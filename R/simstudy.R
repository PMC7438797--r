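#' Simulation condition grid
#'
#' Defines a Monte Carlo study over sample size, conditional-dependence
#' size, and prior rung.  The full published design (20 sample sizes x 4
#' correlation sizes x 5 priors x 200 replications, 2 x 50,000 iterations)
#' is cluster work; the desk-scale defaults use a 3-point sample-size grid,
#' 50 replications per cell, and 2 chains of 2,000 iterations, which
#' recover the qualitative effect directions.
#'
#' @param sample_sizes integer vector of N values (default
#'   `c(100, 500, 1000)`; use [study_sample_sizes()] for the full grid).
#' @param corr_sizes subset of `c(0, 0.2, 0.5, 0.8)`.
#' @param priors character vector of prior ladder rung names.
#' @param n_replications replications per cell (default 50).
#' @param mcmc an `flexlca_mcmc` configuration template (its seed is
#'   ignored; per-replication seeds are derived from `master_seed`).
#' @param master_seed integer master seed.
#' @param compute_ppp logical: compute the posterior predictive p-value for
#'   every replication (default TRUE).
#' @param n_ppp_draws,ppp_n_mc PPP settings (see [compute_ppp()]).
#' @return an object of class `flexlca_grid`.
#' @export
condition_grid <- function(sample_sizes = c(100L, 500L, 1000L),
                           corr_sizes = c(0, 0.2, 0.5, 0.8),
                           priors = prior_ladder()$name,
                           n_replications = 50L,
                           mcmc = mcmc_config(),
                           master_seed = 1L,
                           compute_ppp = TRUE,
                           n_ppp_draws = 100L,
                           ppp_n_mc = 30000L) {
  stopifnot(all(sample_sizes >= 1), n_replications >= 1)
  ladder <- prior_ladder()
  bad <- setdiff(priors, ladder$name)
  if (length(bad)) {
    stop("unknown prior name(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(ladder$name, collapse = ", "))
  }
  structure(list(sample_sizes = as.integer(sample_sizes),
                 corr_sizes = corr_sizes,
                 priors = priors,
                 n_replications = as.integer(n_replications),
                 mcmc = mcmc,
                 master_seed = as.integer(master_seed),
                 compute_ppp = isTRUE(compute_ppp),
                 n_ppp_draws = as.integer(n_ppp_draws),
                 ppp_n_mc = as.integer(ppp_n_mc)),
            class = "flexlca_grid")
}

# monitored correlation pairs: the bias-table trio in class 1 plus the
# truly dependent pairs in each class
monitored_pairs <- function() {
  list(list(class = 1L, pair = c(1L, 2L)),
       list(class = 1L, pair = c(1L, 3L)),
       list(class = 1L, pair = c(3L, 8L)),
       list(class = 1L, pair = c(3L, 9L)),
       list(class = 1L, pair = c(5L, 7L)),
       list(class = 2L, pair = c(4L, 6L)))
}

pair_label <- function(p) paste0("rho_", p$class, "_", p$pair[1], p$pair[2])

#' Run one replication of a simulation cell
#'
#' Generates a dataset from the study population, fits the two-class model
#' with the named prior, and records convergence, PPP (optionally), and the
#' posterior median / significance decision for every monitored pair.
#'
#' @param N sample size.
#' @param corr_size conditional-dependence size.
#' @param prior_name prior ladder rung name.
#' @param rep_seed integer seed for this replication.
#' @param mcmc an `flexlca_mcmc` template.
#' @param compute_ppp,n_ppp_draws,ppp_n_mc PPP settings.
#' @return one-row data.frame.
#' @export
run_replication <- function(N, corr_size, prior_name, rep_seed,
                            mcmc = mcmc_config(), compute_ppp = TRUE,
                            n_ppp_draws = 100L, ppp_n_mc = 30000L) {
  pop <- build_population(corr_size)
  dat <- generate_dataset(pop, n = N, seed = rep_seed)
  prior <- prior_from_ladder(prior_name)
  cfg <- mcmc_config(n_chains = mcmc$n_chains,
                     max_iterations = mcmc$max_iterations,
                     burn_in_fraction = mcmc$burn_in_fraction,
                     thin = mcmc$thin, psr_threshold = mcmc$psr_threshold,
                     seed = derive_seed(rep_seed, 11L))
  fit <- fit_blca(dat, n_classes = 2L, prior = prior, config = cfg)
  out <- data.frame(N = N, corr_size = corr_size, prior = prior_name,
                    seed = rep_seed,
                    converged = isTRUE(fit$diagnostics$converged),
                    max_psr = fit$diagnostics$max_psr,
                    ppp = NA_real_)
  if (compute_ppp) {
    out$ppp <- as.numeric(compute_ppp(dat, fit, n_ppp_draws = n_ppp_draws,
                                      seed = derive_seed(rep_seed, 13L),
                                      n_mc = ppp_n_mc))
  }
  for (p in monitored_pairs()) {
    lab <- pair_label(p)
    sig <- test_correlation_significance(fit, p$class, p$pair)
    out[[paste0(lab, "_median")]] <- attr(sig, "median")
    out[[paste0(lab, "_sig")]] <- as.logical(sig)
  }
  out
}

#' Run a Monte Carlo study
#'
#' Executes every (N, corr_size, prior) cell of the grid for the configured
#' number of replications.  Each replication has a deterministic seed
#' derived from the master seed and its cell coordinates, so any cell can
#' be reproduced in isolation and results do not depend on execution
#' order.  When `checkpoint_dir` is given, finished cells are written as
#' CSV and skipped on re-run, so interrupted studies resume.
#'
#' @param grid a `flexlca_grid`.
#' @param checkpoint_dir optional directory for per-cell checkpoints.
#' @param verbose print progress (default FALSE).
#' @return an object of class `flexlca_study`: a list with `replications`
#'   (one row per replication), `cells` (per-cell aggregates, see
#'   [aggregate_study()]), `grid`, and `n_failed`.
#' @export
run_study <- function(grid, checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "flexlca_grid"))
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }
  cells <- expand.grid(N = grid$sample_sizes, corr_size = grid$corr_sizes,
                       prior = grid$priors, stringsAsFactors = FALSE)
  reps <- vector("list", nrow(cells))
  n_failed <- 0L
  for (ci in seq_len(nrow(cells))) {
    N <- cells$N[ci]; cs <- cells$corr_size[ci]; pn <- cells$prior[ci]
    ck <- NULL
    if (!is.null(checkpoint_dir)) {
      ck <- file.path(checkpoint_dir,
                      sprintf("cell_N%d_c%02.0f_%s.csv", N, cs * 100,
                              gsub("[^a-z]", "_", pn)))
      if (file.exists(ck)) {
        prev <- utils::read.csv(ck, stringsAsFactors = FALSE)
        if (nrow(prev) == grid$n_replications) {
          reps[[ci]] <- prev
          if (verbose) message("cell ", ci, "/", nrow(cells), " restored")
          next
        }
      }
    }
    pi_idx <- match(pn, prior_ladder()$name)
    cell_rows <- vector("list", grid$n_replications)
    for (r in seq_len(grid$n_replications)) {
      rep_seed <- derive_seed(grid$master_seed, N, round(cs * 100), pi_idx, r)
      row <- tryCatch(
        run_replication(N, cs, pn, rep_seed, mcmc = grid$mcmc,
                        compute_ppp = grid$compute_ppp,
                        n_ppp_draws = grid$n_ppp_draws,
                        ppp_n_mc = grid$ppp_n_mc),
        error = function(e) {
          warning("replication failed (N=", N, ", corr=", cs, ", prior='",
                  pn, "', rep=", r, "): ", conditionMessage(e))
          NULL
        })
      if (is.null(row)) n_failed <- n_failed + 1L else {
        row$rep <- r
        cell_rows[[r]] <- row
      }
    }
    cell <- do.call(rbind, cell_rows)
    if (!is.null(cell) && grid$n_replications - nrow(cell) >
        0.05 * grid$n_replications) {
      warning("more than 5% of replications failed in cell (N=", N,
              ", corr=", cs, ", prior='", pn, "')")
    }
    reps[[ci]] <- cell
    if (!is.null(ck) && !is.null(cell)) utils::write.csv(cell, ck, row.names = FALSE)
    if (verbose) message("cell ", ci, "/", nrow(cells), " done")
  }
  replications <- do.call(rbind, reps)
  structure(list(replications = replications,
                 cells = aggregate_study(replications),
                 grid = grid, n_failed = n_failed),
            class = "flexlca_study")
}

#' Aggregate replication-level study results per cell
#'
#' @param replications the replication table from [run_study()].
#' @return data.frame keyed by (N, corr_size, prior) with percent
#'   significant and mean posterior median per monitored pair, mean PPP,
#'   and the convergence rate (all percentages in `[0, 100]`).
#' @export
aggregate_study <- function(replications) {
  key <- interaction(replications$N, replications$corr_size,
                     replications$prior, drop = TRUE)
  rows <- lapply(split(replications, key), function(d) {
    out <- data.frame(N = d$N[1], corr_size = d$corr_size[1],
                      prior = d$prior[1], n_reps = nrow(d),
                      mean_ppp = mean(d$ppp),
                      convergence_rate = 100 * mean(d$converged))
    for (p in monitored_pairs()) {
      lab <- pair_label(p)
      out[[paste0(lab, "_pct_sig")]] <- 100 * mean(d[[paste0(lab, "_sig")]])
      out[[paste0(lab, "_mean_median")]] <- mean(d[[paste0(lab, "_median")]])
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$corr_size, out$prior, out$N), ]
}

#' @export
print.flexlca_study <- function(x, ...) {
  cat("flexlca study:", nrow(x$cells), "cells,",
      nrow(x$replications), "replications (", x$n_failed, "failed )\n")
  cat("  convergence rate:",
      signif(100 * mean(x$replications$converged), 4), "%\n")
  invisible(x)
}

#' Bias table for true-zero correlation estimates
#'
#' Mean posterior-median estimates of rho[1; 1,2], rho[1; 1,3], and
#' rho[1; 3,8] by (corr_size, prior), averaged over replications and over
#' the sample sizes present in the study.  The aggregated sample sizes are
#' recorded in attribute `sample_sizes`.
#'
#' @param study a `flexlca_study` (or its replication table).
#' @return data.frame with columns `corr_size`, `prior`, `rho_1_12`,
#'   `rho_1_13`, `rho_1_38`.
#' @export
bias_table <- function(study) {
  reps <- if (inherits(study, "flexlca_study")) study$replications else study
  key <- interaction(reps$corr_size, reps$prior, drop = TRUE)
  rows <- lapply(split(reps, key), function(d) {
    data.frame(corr_size = d$corr_size[1], prior = d$prior[1],
               rho_1_12 = mean(d$rho_1_12_median),
               rho_1_13 = mean(d$rho_1_13_median),
               rho_1_38 = mean(d$rho_1_38_median))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$corr_size, match(out$prior, prior_ladder()$name)), ]
  attr(out, "sample_sizes") <- sort(unique(reps$N))
  out
}

#' Eta-squared decomposition of PPP over the simulation factors
#'
#' Fixed-effects full-factorial ANOVA of replication-level PPP on sample
#' size (N), correlation size (C), and prior variance (P):
#' `eta^2 = SS_effect / SS_total` for each main effect and interaction.
#'
#' @param study a `flexlca_study` (or its replication table) covering at
#'   least two levels of each factor on a complete balanced grid.
#' @return named numeric vector with entries `N`, `C`, `P`, `N:C`, `N:P`,
#'   `C:P`, `N:C:P` (and attribute `residual` for the unexplained share).
#' @export
eta_squared <- function(study) {
  reps <- if (inherits(study, "flexlca_study")) study$replications else study
  if (any(is.na(reps$ppp))) {
    stop("replication-level PPP is missing; run the study with compute_ppp = TRUE")
  }
  f <- data.frame(ppp = reps$ppp,
                  N = factor(reps$N), C = factor(reps$corr_size),
                  P = factor(reps$prior))
  if (nlevels(f$N) < 2 || nlevels(f$C) < 2 || nlevels(f$P) < 2) {
    stop("eta_squared needs at least 2 levels of each factor (N, C, P)")
  }
  tab <- table(f$N, f$C, f$P)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    stop("incomplete grid: missing cell(s) e.g. N=", dimnames(tab)[[1]][miss[1, 1]],
         ", C=", dimnames(tab)[[2]][miss[1, 2]],
         ", P=", dimnames(tab)[[3]][miss[1, 3]])
  }
  if (length(unique(as.vector(tab))) != 1) {
    stop("unbalanced grid: cells have unequal replication counts")
  }
  ss_total <- sum((f$ppp - mean(f$ppp))^2)
  if (ss_total <= .Machine$double.eps) {
    eta <- stats::setNames(rep(0, 7), c("N", "C", "P", "N:C", "N:P", "C:P", "N:C:P"))
    attr(eta, "residual") <- 0
    return(eta)
  }
  fit <- stats::aov(ppp ~ N * C * P, data = f)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  terms <- trimws(rownames(summary(fit)[[1]]))
  eta <- ss / ss_total
  names(eta) <- terms
  resid <- if ("Residuals" %in% terms) eta[["Residuals"]] else 0
  eta <- eta[setdiff(terms, "Residuals")]
  want <- c("N", "C", "P", "N:C", "N:P", "C:P", "N:C:P")
  eta <- stats::setNames(eta[match(want, names(eta))], want)
  eta[is.na(eta)] <- 0
  attr(eta, "residual") <- resid
  eta
}

#' Write study tables to a directory
#'
#' Persists the tidy replication table plus the aggregate analogues of the
#' published figures/tables: percent significant, mean PPP, the eta-squared
#' decomposition (when computable), and the bias table.
#'
#' @param study a `flexlca_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study_tables <- function(study, dir) {
  stopifnot(inherits(study, "flexlca_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(replications = file.path(dir, "replications.csv"),
             fig1 = file.path(dir, "fig1_percent_significant.csv"),
             fig2 = file.path(dir, "fig2_ppp.csv"),
             table2 = file.path(dir, "table2_bias.csv"))
  utils::write.csv(study$replications, paths["replications"], row.names = FALSE)
  sig_cols <- grep("_pct_sig$", names(study$cells), value = TRUE)
  utils::write.csv(study$cells[, c("N", "corr_size", "prior", sig_cols)],
                   paths["fig1"], row.names = FALSE)
  utils::write.csv(study$cells[, c("N", "corr_size", "prior", "mean_ppp",
                                   "convergence_rate")],
                   paths["fig2"], row.names = FALSE)
  utils::write.csv(bias_table(study), paths["table2"], row.names = FALSE)
  eta <- tryCatch(eta_squared(study), error = function(e) NULL)
  if (!is.null(eta)) {
    p <- file.path(dir, "table1_eta2.csv")
    utils::write.csv(data.frame(effect = names(eta), eta2 = as.numeric(eta)),
                     p, row.names = FALSE)
    paths <- c(paths, table1 = p)
  }
  invisible(paths)
}
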