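#' Permutation network comparison test between two groups
#'
#' Estimates both group networks with identical settings, computes the
#' observed global-strength invariance statistic `S = |GS_A - GS_B|` (GS the
#' sum of absolute edge weights) and the structure invariance statistic
#' `M = max_{i<j} |w_A,ij - w_B,ij|`, then pools the subjects and repeatedly
#' permutes the group labels (preserving the two sample sizes),
#' re-estimating both networks per permutation. One-sided exceedance
#' p-values use the +1 correction, `p = (1 + #{perm >= obs}) / (1 + n_perm)`,
#' so they are never 0. The statistics are symmetric in the group order and
#' the internal permutation scheme depends only on the unordered pair of
#' sample sizes, so `nct(A, B)` and `nct(B, A)` agree exactly for the same
#' seed.
#'
#' Optionally, per-edge invariance tests (permutation p-value of each
#' `|w_A,ij - w_B,ij|`, Holm-corrected) can be requested.
#'
#' @param dataA,dataB [item_dataset()]s with identical item sets and order.
#' @param config a [net_config()].
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param edge_tests if `TRUE`, also test each edge difference.
#' @return object of class `nct_result`: `S_observed`, `M_observed`,
#'   `p_S`, `p_M`, `perm_S`, `perm_M` (length `n_perm`), `n_perm`, `seed`,
#'   `netA`, `netB`, `redrawn` (failed permutations redrawn), and
#'   `edge_tests` (data frame or `NULL`).
#' @export
nct <- function(dataA, dataB, config = net_config(), n_perm = 1000,
                seed = NULL, edge_tests = FALSE) {
  stopifnot(inherits(dataA, "item_dataset"), inherits(dataB, "item_dataset"))
  if (!identical(dataA$item_labels, dataB$item_labels))
    stop("the two datasets must share the same item set and order")
  if (n_perm < 20) stop("n_perm must be at least 20")
  if (!is.null(seed)) set.seed(seed)

  netA <- estimate_network(dataA, gamma = config$gamma,
                           n_lambda = config$n_lambda,
                           lambda_min_ratio = config$lambda_min_ratio)
  netB <- estimate_network(dataB, gamma = config$gamma,
                           n_lambda = config$n_lambda,
                           lambda_min_ratio = config$lambda_min_ratio)
  ut <- upper.tri(netA$weights)
  S_obs <- abs(global_strength(netA) - global_strength(netB))
  edge_diff_obs <- abs(netA$weights - netB$weights)[ut]
  M_obs <- max(edge_diff_obs)

  # pool in a canonical order (independent of the argument order) so the
  # permutation draws, and hence the p-values, are identical under swap
  first_a <- nrow(dataA$values) < nrow(dataB$values) ||
    (nrow(dataA$values) == nrow(dataB$values) &&
       !vector_after(as.vector(dataA$values), as.vector(dataB$values)))
  pool <- if (first_a) rbind(dataA$values, dataB$values)
          else rbind(dataB$values, dataA$values)
  n_pool <- nrow(pool)
  n_small <- min(nrow(dataA$values), nrow(dataB$values))

  perm_S <- numeric(n_perm)
  perm_M <- numeric(n_perm)
  perm_edge_ge <- if (edge_tests) numeric(sum(ut)) else NULL
  redrawn <- 0L
  max_redraw <- max(1L, ceiling(0.05 * n_perm))
  k <- 1L
  while (k <= n_perm) {
    idx <- sample.int(n_pool, n_small)
    res <- tryCatch({
      w1 <- estimate_weights(pool[idx, , drop = FALSE], config)
      w2 <- estimate_weights(pool[-idx, , drop = FALSE], config)
      list(w1 = w1, w2 = w2)
    }, error = function(e) NULL)
    if (is.null(res)) {
      redrawn <- redrawn + 1L
      if (redrawn > max_redraw)
        stop("too many failed permutations (", redrawn, " redraws)")
      next
    }
    gs1 <- sum(abs(res$w1[ut])); gs2 <- sum(abs(res$w2[ut]))
    perm_S[k] <- abs(gs1 - gs2)
    d <- abs(res$w1 - res$w2)[ut]
    perm_M[k] <- max(d)
    if (edge_tests) perm_edge_ge <- perm_edge_ge + (d >= edge_diff_obs)
    k <- k + 1L
  }

  et <- NULL
  if (edge_tests) {
    p_raw <- (1 + perm_edge_ge) / (1 + n_perm)
    nodes <- netA$nodes
    et <- data.frame(
      node_i = nodes[row(netA$weights)[ut]],
      node_j = nodes[col(netA$weights)[ut]],
      diff = edge_diff_obs, p = p_raw,
      p_holm = stats::p.adjust(p_raw, method = "holm"),
      stringsAsFactors = FALSE)
  }

  structure(list(
    S_observed = S_obs, M_observed = M_obs,
    p_S = (1 + sum(perm_S >= S_obs)) / (1 + n_perm),
    p_M = (1 + sum(perm_M >= M_obs)) / (1 + n_perm),
    perm_S = perm_S, perm_M = perm_M, n_perm = n_perm,
    seed = seed, netA = netA, netB = netB, redrawn = redrawn,
    edge_tests = et), class = "nct_result")
}

# TRUE when x sorts strictly after y in lexicographic order
vector_after <- function(x, y) {
  k <- which(x != y)
  length(k) > 0 && x[k[1]] > y[k[1]]
}

#' @export
print.nct_result <- function(x, ...) {
  cat(sprintf("<nct_result> %d permutations\n", x$n_perm))
  cat(sprintf("  global strength: S = %.3f, p = %.3f\n", x$S_observed, x$p_S))
  cat(sprintf("  structure:       M = %.3f, p = %.3f\n", x$M_observed, x$p_M))
  invisible(x)
}
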