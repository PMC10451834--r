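#' Nonparametric bootstrap of edge weights
#'
#' Resamples subjects with replacement `B` times, re-estimates the network
#' with identical settings per resample, and reports per-edge percentile
#' confidence intervals. The per-resample edge, strength and expected
#' influence draws are retained for [bootstrap_difference_tests()]. A
#' resample whose estimation fails (e.g. a constant item) is skipped and
#' counted; a warning is raised when more than 1% are skipped.
#'
#' @param data an [item_dataset()].
#' @param config a [net_config()].
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed; results are reproducible given the seed.
#' @param level confidence level for the percentile intervals.
#' @return object of class `edge_stability`: `sample_net` (the full-sample
#'   `network_model`), `edges` (data frame: `node_i`, `node_j`, `sample`,
#'   `boot_mean`, `lower`, `upper`), `edge_draws` (B x n_edges matrix),
#'   `strength_draws`, `ei_draws` (B x p matrices), `skipped`, `B`, `level`.
#' @export
bootstrap_edge_cis <- function(data, config = net_config(), B = 1000,
                               seed = NULL, level = 0.95) {
  stopifnot(inherits(data, "item_dataset"), B >= 2)
  if (!is.null(seed)) set.seed(seed)
  v <- data$values
  n <- nrow(v)
  net <- estimate_network(data, gamma = config$gamma,
                          n_lambda = config$n_lambda,
                          lambda_min_ratio = config$lambda_min_ratio)
  p <- length(net$nodes)
  ut <- upper.tri(net$weights)
  pair_i <- row(net$weights)[ut]
  pair_j <- col(net$weights)[ut]
  n_edges <- sum(ut)

  edge_draws <- matrix(NA_real_, B, n_edges)
  strength_draws <- matrix(NA_real_, B, p)
  ei_draws <- matrix(NA_real_, B, p)
  skipped <- 0L
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    w <- tryCatch(estimate_weights(v[idx, , drop = FALSE], config),
                  error = function(e) NULL)
    if (is.null(w)) {
      skipped <- skipped + 1L
      if (skipped > B) stop("bootstrap estimation failed in every attempt")
      next
    }
    edge_draws[b, ] <- w[ut]
    strength_draws[b, ] <- rowSums(abs(w))
    ei_draws[b, ] <- rowSums(w)
    b <- b + 1L
  }
  if (skipped > 0.01 * B)
    warning(sprintf("%d resample(s) skipped due to estimation failure",
                    skipped))

  a <- (1 - level) / 2
  qs <- apply(edge_draws, 2, stats::quantile, probs = c(a, 1 - a),
              names = FALSE)
  edges <- data.frame(
    node_i = net$nodes[pair_i], node_j = net$nodes[pair_j],
    sample = net$weights[ut], boot_mean = colMeans(edge_draws),
    lower = qs[1, ], upper = qs[2, ], stringsAsFactors = FALSE)
  colnames(edge_draws) <- paste(edges$node_i, edges$node_j, sep = "--")
  colnames(strength_draws) <- colnames(ei_draws) <- net$nodes

  structure(list(sample_net = net, edges = edges, edge_draws = edge_draws,
                 strength_draws = strength_draws, ei_draws = ei_draws,
                 skipped = skipped, B = B, level = level),
            class = "edge_stability")
}

pairwise_differences <- function(draws, labels, level) {
  k <- ncol(draws)
  pairs <- utils::combn(k, 2)
  a <- (1 - level) / 2
  d <- draws[, pairs[1, ], drop = FALSE] - draws[, pairs[2, ], drop = FALSE]
  lo <- apply(d, 2, stats::quantile, probs = a, names = FALSE)
  hi <- apply(d, 2, stats::quantile, probs = 1 - a, names = FALSE)
  data.frame(a = labels[pairs[1, ]], b = labels[pairs[2, ]],
             lower = lo, upper = hi,
             significant = lo > 0 | hi < 0, stringsAsFactors = FALSE)
}

#' Bootstrap difference tests for edges and centralities
#'
#' For every pair of edges, and every pair of nodes (strength and expected
#' influence), forms the percentile confidence interval of the bootstrap
#' differences and flags the pair significant when the interval excludes
#' zero. No multiple-testing correction is applied. A quantity compared with
#' itself has a degenerate zero interval and is never significant.
#'
#' @param report an `edge_stability` object from [bootstrap_edge_cis()].
#' @param level confidence level (default the report's level).
#' @return list with data frames `edge_differences`,
#'   `strength_differences`, `ei_differences` (columns `a`, `b`, `lower`,
#'   `upper`, `significant`).
#' @export
bootstrap_difference_tests <- function(report, level = NULL) {
  stopifnot(inherits(report, "edge_stability"))
  if (is.null(level)) level <- report$level
  list(
    edge_differences = pairwise_differences(
      report$edge_draws, colnames(report$edge_draws), level),
    strength_differences = pairwise_differences(
      report$strength_draws, colnames(report$strength_draws), level),
    ei_differences = pairwise_differences(
      report$ei_draws, colnames(report$ei_draws), level))
}

#' Case-dropping bootstrap stability curve
#'
#' At each drop fraction, draws `B` subject subsets without replacement,
#' re-estimates the network, and correlates the subset centrality vector
#' (strength or expected influence) with the full-sample one. `prob_above`
#' is the fraction of resamples with correlation at least `r_threshold`;
#' the CS coefficient is the largest drop fraction at which that holds with
#' probability at least `prob` (see [cs_coefficient()]).
#'
#' @param data an [item_dataset()].
#' @param config a [net_config()].
#' @param statistic `"strength"` or `"expected_influence"`.
#' @param drops grid of drop fractions (default 0.05 to 0.75 by 0.05).
#' @param B resamples per fraction (default 1000; 200 gives a fast check).
#' @param seed integer seed.
#' @param r_threshold,prob CS definition constants (0.7 and 0.95).
#' @return object of class `cs_curve`: data frame `curve`
#'   (`drop`, `mean_correlation`, `prob_above`, `B_used`), `cs_coefficient`,
#'   `statistic`, `r_threshold`, `prob`.
#' @export
case_dropping_curve <- function(data, config = net_config(),
                                statistic = c("strength",
                                              "expected_influence"),
                                drops = seq(0.05, 0.75, by = 0.05),
                                B = 1000, seed = NULL,
                                r_threshold = 0.7, prob = 0.95) {
  stopifnot(inherits(data, "item_dataset"))
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  v <- data$values
  n <- nrow(v)
  p <- ncol(v)
  net <- estimate_network(data, gamma = config$gamma,
                          n_lambda = config$n_lambda,
                          lambda_min_ratio = config$lambda_min_ratio)
  cent <- function(w) if (statistic == "strength") rowSums(abs(w))
                      else rowSums(w)
  orig <- cent(net$weights)

  rows <- lapply(drops, function(f) {
    keep <- round((1 - f) * n)
    if (keep < p + 5) {
      warning(sprintf("drop fraction %.2f leaves %d < p + 5 subjects; skipped",
                      f, keep))
      return(NULL)
    }
    rs <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, keep)
      w <- tryCatch(estimate_weights(v[idx, , drop = FALSE], config),
                    error = function(e) NULL)
      if (is.null(w)) return(NA_real_)
      s <- cent(w)
      if (stats::sd(s) == 0 || stats::sd(orig) == 0) return(NA_real_)
      stats::cor(orig, s)
    }, numeric(1))
    rs <- rs[!is.na(rs)]
    if (length(rs) == 0)
      return(data.frame(drop = f, mean_correlation = NA_real_,
                        prob_above = 0, B_used = 0L))
    data.frame(drop = f, mean_correlation = mean(rs),
               prob_above = mean(rs >= r_threshold), B_used = length(rs))
  })
  curve <- do.call(rbind, rows)
  out <- structure(list(curve = curve, statistic = statistic,
                        r_threshold = r_threshold, prob = prob),
                   class = "cs_curve")
  if (is.null(curve) || nrow(curve) == 0) {
    warning("no usable drop fraction; CS coefficient undefined")
    out$cs_coefficient <- NA_real_
  } else {
    out$cs_coefficient <- cs_coefficient(out, r_threshold, prob)
  }
  out
}

#' Correlation stability (CS) coefficient of a case-dropping curve
#'
#' Largest drop fraction whose probability of retaining a correlation of at
#' least `r_threshold` with the full-sample centralities is `>= prob`;
#' 0 when no fraction on the grid qualifies. Values of 0.25 or higher are
#' conventionally considered acceptable, 0.5 or higher preferred.
#'
#' @param curve a `cs_curve` from [case_dropping_curve()].
#' @param r_threshold correlation threshold (default 0.7).
#' @param prob required probability (default 0.95).
#' @return scalar CS coefficient.
#' @export
cs_coefficient <- function(curve, r_threshold = 0.7, prob = 0.95) {
  stopifnot(inherits(curve, "cs_curve"))
  cv <- curve$curve
  if (is.null(cv) || nrow(cv) == 0) stop("empty stability curve")
  ok <- cv$drop[which(cv$prob_above >= prob)]
  if (length(ok) == 0) 0 else max(ok)
}
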