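#' Graphical lasso at a single penalty
#'
#' Maximizes log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |theta_ij|
#' (penalty on off-diagonals only) by block coordinate descent. Off-diagonal
#' entries with magnitude below 1e-8 are snapped to exact zero. At
#' `lambda = 0` the problem is unpenalized and the exact solution
#' `Theta = S^{-1}` is returned.
#'
#' @param S positive-definite covariance/correlation matrix (repair with
#'   [nearest_positive_definite()] first if needed).
#' @param lambda penalty, `>= 0`.
#' @param tol convergence tolerance on the working covariance (relative to
#'   the mean absolute off-diagonal of `S`).
#' @param max_sweeps sweep cap; exceeding it raises a convergence error.
#' @return list of class `precision_fit`: `theta` (precision matrix), `ll0`
#'   (`log det Theta - tr(S Theta)`), `lambda`.
#' @export
glasso_precision <- function(S, lambda, tol = 1e-6, max_sweeps = 500) {
  S <- as.matrix(S)
  if (lambda < 0) stop("lambda must be nonnegative")
  if (!is_positive_definite(S, 0))
    stop("S is not positive definite; repair it first")
  if (lambda == 0) {
    theta <- solve(S)
    theta <- (theta + t(theta)) / 2
    theta[abs(theta) < 1e-8 & row(theta) != col(theta)] <- 0
    ll0 <- determinant(theta, logarithm = TRUE)$modulus[1] - sum(S * theta)
    return(structure(list(theta = theta, ll0 = ll0, lambda = 0),
                     class = "precision_fit"))
  }
  fit <- glasso_path_cpp(S, lambda, tol, as.integer(max_sweeps), 1e-8)
  if (fit$converged[1] != 1L)
    stop(sprintf("graphical lasso did not converge in %d sweeps (residual change %.3g)",
                 max_sweeps, fit$last_change[1]))
  structure(list(theta = fit$theta[, , 1], ll0 = fit$ll0[1], lambda = lambda),
            class = "precision_fit")
}

#' Extended Bayesian information criterion of a precision fit
#'
#' EBIC = -2 l(Theta) + E log n + 4 E gamma log p, where
#' l(Theta) = (n/2)(log det Theta - tr(S Theta)) up to an additive constant
#' (constants cancel along a single penalty path) and E is the number of
#' nonzero upper-triangle off-diagonal precision entries.
#'
#' @param fit a `precision_fit` from [glasso_precision()].
#' @param S the covariance/correlation matrix the fit used.
#' @param n sample size.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @return the EBIC value (scalar).
#' @export
ebic <- function(fit, S, n, gamma = 0.5) {
  theta <- fit$theta
  p <- ncol(theta)
  E <- sum(theta[upper.tri(theta)] != 0)
  ll <- (n / 2) * fit$ll0
  -2 * ll + E * log(n) + 4 * E * gamma * log(p)
}

edge_count_of <- function(w) sum(w[upper.tri(w)] != 0)

theta_to_weights <- function(theta) {
  d <- sqrt(diag(theta))
  w <- -theta / outer(d, d)
  diag(w) <- 0
  w <- (w + t(w)) / 2
  w
}

new_network_model <- function(nodes, weights, lambda, gamma, ebic, n) {
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights, lambda = lambda,
                 gamma = gamma, ebic = ebic,
                 edge_count = edge_count_of(weights), n = n),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d nodes, %d edges (lambda = %.4g, gamma = %.2g, EBIC = %.2f, n = %d)\n",
              length(x$nodes), x$edge_count, x$lambda, x$gamma, x$ebic, x$n))
  invisible(x)
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso along a path of `n_lambda` logarithmically spaced
#' penalties from `lambda_max = max |S_ij| (i != j)` down to
#' `lambda_max * lambda_min_ratio`, scores each fit by [ebic()], and returns
#' the minimizing model as a partial-correlation weight matrix
#' `w_ij = -theta_ij / sqrt(theta_ii theta_jj)`. EBIC ties are broken toward
#' the larger penalty (the sparser model).
#'
#' @param x an [item_dataset()], a `correlation_estimate`, or a correlation
#'   matrix (then `n` is required).
#' @param gamma EBIC hyperparameter, default 0.5.
#' @param n_lambda path length, default 100.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest,
#'   default 0.01.
#' @param items optional item subset when `x` is a dataset.
#' @param n sample size when `x` is a plain matrix.
#' @return a `network_model`: node labels, symmetric weight matrix with zero
#'   diagonal, selected `lambda`, `gamma`, `ebic`, `edge_count`, `n`.
#' @export
estimate_network <- function(x, gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01, items = NULL, n = NULL) {
  if (inherits(x, "item_dataset")) {
    ce <- rank_correlation_matrix(x, items = items)
    S <- ce$matrix; n <- ce$n
  } else if (inherits(x, "correlation_estimate")) {
    S <- x$matrix; n <- x$n
  } else {
    S <- as.matrix(x)
    if (is.null(n)) stop("supply n when passing a correlation matrix")
    if (!is_positive_definite(S, 0)) S <- nearest_positive_definite(S)
  }
  p <- ncol(S)
  if (p < 3) stop("need at least 3 nodes")
  nodes <- colnames(S)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))

  sel <- glasso_select(S, n, gamma, n_lambda, lambda_min_ratio)
  new_network_model(nodes, sel$weights, sel$lambda, gamma, sel$ebic, n)
}

# Path fit + EBIC selection on a ready correlation matrix; the hot path used
# by the bootstrap and permutation machinery.
glasso_select <- function(S, n, gamma = 0.5, n_lambda = 100,
                          lambda_min_ratio = 0.01,
                          tol = 1e-6, max_sweeps = 500) {
  off <- abs(S[upper.tri(S)])
  lambda_max <- max(off)
  if (lambda_max <= 0) lambda_max <- 0.1   # empty correlation: any path works
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambda))
  fit <- glasso_ebic_cpp(S, lambdas, n, gamma, tol,
                         as.integer(max_sweeps), 1e-8)
  list(weights = theta_to_weights(fit$theta),
       lambda = fit$lambda, ebic = fit$ebic,
       ebic_path = fit$ebic_path, lambdas = lambdas)
}

# One-call estimation from a raw values matrix; used inside resampling loops.
estimate_weights <- function(values, config) {
  r <- suppressWarnings(stats::cor(values, method = "spearman"))
  if (anyNA(r)) stop("constant item in resample")
  if (!is_positive_definite(r, 1e-10)) r <- nearest_positive_definite(r)
  glasso_select(r, nrow(values), config$gamma, config$n_lambda,
                config$lambda_min_ratio)$weights
}

#' Estimator settings shared across bootstraps and comparisons
#'
#' @param gamma EBIC hyperparameter.
#' @param n_lambda penalty path length.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest.
#' @return a list of class `net_config`.
#' @export
net_config <- function(gamma = 0.5, n_lambda = 100, lambda_min_ratio = 0.01) {
  stopifnot(gamma >= 0, n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(gamma = gamma, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio), class = "net_config")
}

#' Covariate-adjusted network
#'
#' Re-estimates the network with a covariate included as an additional node
#' and returns the symptom-by-symptom submatrix of weights, so every symptom
#' edge is a partial correlation additionally conditioned on the covariate.
#'
#' @param data an [item_dataset()] with the covariate in `$covariates`.
#' @param covariate name of one covariate column (numeric or 0/1 coded).
#' @param gamma,n_lambda,lambda_min_ratio estimator settings.
#' @return a `network_model` on the symptom nodes only (attribute
#'   `adjusted_for` records the covariate).
#' @export
covariate_adjusted_network <- function(data, covariate, gamma = 0.5,
                                       n_lambda = 100,
                                       lambda_min_ratio = 0.01) {
  stopifnot(inherits(data, "item_dataset"))
  if (is.null(data$covariates) || !covariate %in% names(data$covariates))
    stop("unknown covariate: ", covariate)
  z <- data$covariates[[covariate]]
  if (stats::sd(z) == 0) stop("covariate is constant: ", covariate)
  aug <- cbind(data$values, z)
  colnames(aug) <- c(data$item_labels, covariate)
  ce <- rank_correlation_matrix(aug)
  full <- estimate_network(ce, gamma = gamma, n_lambda = n_lambda,
                           lambda_min_ratio = lambda_min_ratio)
  keep <- seq_along(data$item_labels)
  net <- new_network_model(data$item_labels,
                           full$weights[keep, keep, drop = FALSE],
                           full$lambda, gamma, full$ebic, full$n)
  attr(net, "adjusted_for") <- covariate
  net
}

#' Similarity of two networks on the same nodes
#'
#' Pearson correlation of the vectorized strict lower triangles of the two
#' weight matrices, with its two-sided p-value.
#'
#' @param A,B `network_model`s with identical node sets in the same order.
#' @return list with `r`, `p`, and `defined` (FALSE when a triangle has zero
#'   variance, in which case `r` is `NA`).
#' @export
network_similarity <- function(A, B) {
  if (!identical(A$nodes, B$nodes))
    stop("networks must share the same node set and order")
  a <- A$weights[lower.tri(A$weights)]
  b <- B$weights[lower.tri(B$weights)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("similarity undefined: zero-variance edge vector")
    return(list(r = NA_real_, p = NA_real_, defined = FALSE))
  }
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}
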