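#' Population specification for the latent class simulator
#'
#' Describes the generative truth of a finite mixture of multivariate
#' probit models: class proportions, per-class threshold vectors, and
#' per-class tetrachoric correlation matrices.  Binary responses arise by
#' dichotomizing a latent multivariate normal `Y* | X = m ~ N(mu_m,
#' Sigma_m)` at zero, so the endorsement probability of item j in class m
#' is `pnorm(mu[m, j])`.
#'
#' @param class_proportions probability vector of length M (entries in
#'   (0, 1), summing to 1).
#' @param thresholds M x J numeric matrix of latent means `mu_m`.
#' @param correlation_matrices list of M symmetric positive-definite J x J
#'   matrices with unit diagonal.
#' @return an object of class `flexlca_population`.
#' @seealso [build_population()] for the two-class study population.
#' @export
population_spec <- function(class_proportions, thresholds, correlation_matrices) {
  class_proportions <- as.numeric(class_proportions)
  thresholds <- as.matrix(thresholds)
  M <- length(class_proportions)
  J <- ncol(thresholds)
  if (J < 2L) stop("at least 2 indicators are required")
  if (nrow(thresholds) != M) stop("thresholds must have one row per class")
  if (length(correlation_matrices) != M) {
    stop("correlation_matrices must have one matrix per class")
  }
  if (abs(sum(class_proportions) - 1) > 1e-8 ||
      any(class_proportions <= 0) || any(class_proportions >= 1)) {
    stop("class_proportions must lie in (0, 1) and sum to 1")
  }
  correlation_matrices <- lapply(seq_len(M), function(m) {
    S <- as.matrix(correlation_matrices[[m]])
    if (!isTRUE(all.equal(dim(S), c(J, J)))) {
      stop("correlation matrix for class ", m, " is not ", J, "x", J)
    }
    if (max(abs(S - t(S))) > 1e-10) stop("correlation matrix for class ", m, " is not symmetric")
    if (max(abs(diag(S) - 1)) > 1e-10) stop("correlation matrix for class ", m, " must have unit diagonal")
    off <- S[upper.tri(S)]
    if (any(abs(off) >= 1)) stop("off-diagonal correlations for class ", m, " must lie in (-1, 1)")
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10) {
      stop("correlation matrix for class ", m,
           " is not positive definite (min eigenvalue ", signif(ev, 3), ")")
    }
    S
  })
  structure(list(n_classes = M, n_items = J,
                 class_proportions = class_proportions,
                 thresholds = thresholds,
                 correlation_matrices = correlation_matrices),
            class = "flexlca_population")
}

#' @export
print.flexlca_population <- function(x, ...) {
  cat("flexlca population: M =", x$n_classes, "classes, J =", x$n_items, "items\n")
  cat("  proportions:", paste(signif(x$class_proportions, 3), collapse = ", "), "\n")
  for (m in seq_len(x$n_classes)) {
    S <- x$correlation_matrices[[m]]
    nz <- which(upper.tri(S) & abs(S) > 0, arr.ind = TRUE)
    cat("  class ", m, ": thresholds ",
        paste(signif(x$thresholds[m, ], 3), collapse = " "), "\n", sep = "")
    if (nrow(nz)) {
      for (r in seq_len(nrow(nz))) {
        cat("    rho[", nz[r, 1], ",", nz[r, 2], "] = ",
            S[nz[r, 1], nz[r, 2]], "\n", sep = "")
      }
    }
  }
  invisible(x)
}

#' The two-class study population with controllable conditional dependence
#'
#' Two equally sized classes of J = 10 binary indicators.  Thresholds are
#' +1 for every item in class 1 and -1 in class 2 (class separation of two
#' latent standard deviations).  Conditional dependence is injected as
#' tetrachoric correlations of size `corr_size` at item pairs (1,2), (3,9)
#' and (5,7) in class 1 and pair (4,6) in class 2; all other within-class
#' correlations are zero.
#'
#' @param corr_size one of 0, 0.20, 0.50, 0.80.
#' @return a `flexlca_population`.
#' @examples
#' build_population(0.5)
#' @export
build_population <- function(corr_size) {
  allowed <- c(0, 0.20, 0.50, 0.80)
  if (length(corr_size) != 1 || !any(abs(corr_size - allowed) < 1e-12)) {
    stop("corr_size must be one of 0, 0.20, 0.50, 0.80 ",
         "(use population_spec() for arbitrary populations)")
  }
  J <- 10L
  S1 <- diag(J)
  S2 <- diag(J)
  for (p in list(c(1, 2), c(3, 9), c(5, 7))) {
    S1[p[1], p[2]] <- S1[p[2], p[1]] <- corr_size
  }
  S2[4, 6] <- S2[6, 4] <- corr_size
  population_spec(
    class_proportions = c(0.5, 0.5),
    thresholds = rbind(rep(1, J), rep(-1, J)),
    correlation_matrices = list(S1, S2))
}

#' Sample sizes of the simulation study grid
#'
#' @return the 20 study sample sizes: 50 to 500 in steps of 25, plus 1000.
#' @examples
#' study_sample_sizes()
#' @export
study_sample_sizes <- function() {
  c(seq(50L, 500L, by = 25L), 1000L)
}

#' Generate a binary dataset from a population specification
#'
#' For each unit a class is drawn from the class proportions, a latent
#' response vector from `N(mu_m, Sigma_m)`, and the binary response is
#' `y = 1` iff the latent response is non-negative.
#'
#' @param spec a `flexlca_population`.
#' @param n number of units (>= 1).
#' @param seed integer RNG seed; identical seeds give bit-identical data.
#' @return an object of class `flexlca_data` with elements `responses`
#'   (n x J integer 0/1 matrix with columns `item1..itemJ`),
#'   `true_classes` (length-n integer vector, simulation provenance only),
#'   and `meta` (seed, n, and a population fingerprint).
#' @examples
#' d <- generate_dataset(build_population(0), n = 100, seed = 1)
#' colMeans(d$responses)
#' @export
generate_dataset <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "flexlca_population"), n >= 1)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  M <- spec$n_classes
  J <- spec$n_items
  cls <- sample.int(M, n, replace = TRUE, prob = spec$class_proportions)
  chol_list <- lapply(spec$correlation_matrices, chol)  # upper triangular
  Y <- matrix(0L, n, J)
  for (m in seq_len(M)) {
    idx <- which(cls == m)
    if (!length(idx)) next
    Z <- matrix(stats::rnorm(length(idx) * J), length(idx), J)
    lat <- Z %*% chol_list[[m]] +
      matrix(spec$thresholds[m, ], length(idx), J, byrow = TRUE)
    Y[idx, ] <- (lat >= 0) + 0L
  }
  storage.mode(Y) <- "integer"
  colnames(Y) <- paste0("item", seq_len(J))
  structure(list(responses = Y,
                 true_classes = cls,
                 meta = list(seed = as.integer(seed), n = n,
                             population = population_fingerprint(spec))),
            class = "flexlca_data")
}

#' @export
print.flexlca_data <- function(x, ...) {
  cat("flexlca dataset: N =", nrow(x$responses), ", J =", ncol(x$responses), "\n")
  cat("  item means:", paste(signif(colMeans(x$responses), 3), collapse = " "), "\n")
  invisible(x)
}

# short deterministic fingerprint of a population (for manifests)
population_fingerprint <- function(spec) {
  s <- paste(c(spec$class_proportions, as.vector(spec$thresholds),
               unlist(lapply(spec$correlation_matrices, as.vector))),
             collapse = ",")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Coerce a 0/1 matrix to a flexlca dataset
#'
#' @param responses matrix or data.frame with entries in \{0, 1\}.
#' @return a `flexlca_data`.
#' @export
as_flexlca_data <- function(responses) {
  Y <- as.matrix(responses)
  if (any(is.na(Y))) stop("missing values are not supported")
  if (!all(Y %in% c(0, 1))) stop("responses must be 0/1")
  storage.mode(Y) <- "integer"
  if (is.null(colnames(Y))) colnames(Y) <- paste0("item", seq_len(ncol(Y)))
  structure(list(responses = Y, true_classes = NULL,
                 meta = list(n = nrow(Y))),
            class = "flexlca_data")
}
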