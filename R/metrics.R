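#' Node centrality, expected influence and predictability
#'
#' Computes, per node: strength (sum of absolute edge weights), one-step
#' expected influence (signed sum, retaining negative edges), harmonic
#' closeness and shortest-path betweenness on distances `d = 1/|w|` over the
#' nonzero edges (Dijkstra/Brandes with fractional credit for tied shortest
#' paths; unreachable pairs contribute 0 to closeness), their standardized
#' (z) versions across nodes, and, when `data` is supplied, nodewise
#' predictability R-squared from [predictability()]. Isolated nodes get
#' closeness and betweenness 0.
#'
#' @param net a `network_model`.
#' @param data optional [item_dataset()] for predictability.
#' @return data frame, one row per node: `node`, `strength`,
#'   `expected_influence`, `closeness`, `betweenness`, `z_strength`,
#'   `z_expected_influence`, `z_closeness`, `z_betweenness`, and
#'   `predictability` when data are given.
#' @export
centrality_table <- function(net, data = NULL) {
  w <- net$weights
  p <- ncol(w)
  if (p < 2) stop("need at least 2 nodes")
  strength <- rowSums(abs(w))
  ei <- rowSums(w)

  g <- igraph::graph_from_adjacency_matrix(abs(w), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  dist_w <- 1 / igraph::E(g)$weight
  if (igraph::ecount(g) > 0) {
    clo <- igraph::harmonic_centrality(g, weights = dist_w,
                                       normalized = FALSE)
    btw <- igraph::betweenness(g, weights = dist_w, directed = FALSE)
  } else {
    clo <- btw <- rep(0, p)
  }

  zscore <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  out <- data.frame(
    node = net$nodes, strength = strength, expected_influence = ei,
    closeness = unname(clo), betweenness = unname(btw),
    z_strength = zscore(strength), z_expected_influence = zscore(ei),
    z_closeness = zscore(unname(clo)), z_betweenness = zscore(unname(btw)),
    stringsAsFactors = FALSE)
  if (!is.null(data))
    out$predictability <- predictability(data, nodes = net$nodes)
  rownames(out) <- NULL
  out
}

#' Global strength of a network
#'
#' Sum of absolute edge weights over the strict upper triangle; equals half
#' the sum of node strengths.
#'
#' @param net a `network_model` (or a plain weight matrix).
#' @return scalar global strength.
#' @export
global_strength <- function(net) {
  w <- if (inherits(net, "network_model")) net$weights else as.matrix(net)
  sum(abs(w[upper.tri(w)]))
}

#' Nodewise predictability
#'
#' In-sample R-squared of the ordinary least-squares regression of each item
#' on all remaining items: the share of a node's variance its neighbors
#' explain. Rank-deficient predictor sets are handled by the least-squares
#' fit with a warning.
#'
#' @param data an [item_dataset()].
#' @param nodes item labels to evaluate (default: all items).
#' @return named numeric vector of R-squared values in `[0, 1]`.
#' @export
predictability <- function(data, nodes = NULL) {
  stopifnot(inherits(data, "item_dataset"))
  if (is.null(nodes)) nodes <- data$item_labels
  v <- data$values[, nodes, drop = FALSE]
  n <- nrow(v); p <- ncol(v)
  if (n <= p + 1) stop("need n > p + 1 subjects for nodewise regression")
  r2 <- vapply(seq_len(p), function(j) {
    y <- v[, j]
    X <- cbind(1, v[, -j, drop = FALSE])
    fit <- stats::lsfit(v[, -j, drop = FALSE], y, intercept = TRUE)
    if (any(is.na(fit$coefficients))) {
      warning("collinear predictors for node ", nodes[j],
              "; dropped aliased columns")
      fit$coefficients[is.na(fit$coefficients)] <- 0
    }
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(0)
    1 - sum(fit$residuals^2) / tss
  }, numeric(1))
  names(r2) <- nodes
  pmin(pmax(r2, 0), 1)
}

#' Flow decomposition around a focal node
#'
#' Partitions the non-focal nodes into the direct neighbors of the focal
#' node (nonzero edge to it), successive indirect layers (breadth-first
#' search on the nonzero-edge graph: layer k nodes touch layer k-1 but no
#' earlier layer), and nodes with no path to the focal node. Also returns
#' the focal node's edges ranked by absolute weight, so both the
#' direct/indirect partition and the strongest-edge reading are available.
#'
#' @param net a `network_model`.
#' @param focal a node label present in the network.
#' @return list of class `flow_decomposition`: `focal`, `direct`,
#'   `indirect_layers` (list of character vectors, possibly empty),
#'   `unreached`, `edges_to_focal` (data frame `node`, `weight`, sorted by
#'   `|weight|` descending).
#' @export
flow_decompose <- function(net, focal) {
  w <- net$weights
  nodes <- net$nodes
  if (!focal %in% nodes) stop("unknown focal node: ", focal)
  fi <- match(focal, nodes)
  adj <- w != 0

  direct <- nodes[which(adj[fi, ])]
  seen <- c(focal, direct)
  layers <- list()
  frontier <- direct
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      vi <- match(v, nodes)
      nxt <- union(nxt, nodes[which(adj[vi, ])])
    }
    nxt <- setdiff(nxt, seen)
    if (length(nxt) == 0) break
    layers <- c(layers, list(nxt))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  unreached <- setdiff(nodes, seen)

  ef <- data.frame(node = direct, weight = w[fi, match(direct, nodes)],
                   stringsAsFactors = FALSE)
  ef <- ef[order(-abs(ef$weight)), , drop = FALSE]
  rownames(ef) <- NULL
  structure(list(focal = focal, direct = direct, indirect_layers = layers,
                 unreached = unreached, edges_to_focal = ef),
            class = "flow_decomposition")
}

#' @export
print.flow_decomposition <- function(x, ...) {
  cat(sprintf("<flow_decomposition> focal = %s\n", x$focal))
  cat("  direct:", if (length(x$direct)) paste(x$direct, collapse = ", ")
      else "(none)", "\n")
  for (k in seq_along(x$indirect_layers))
    cat(sprintf("  indirect layer %d: %s\n", k + 1,
                paste(x$indirect_layers[[k]], collapse = ", ")))
  if (length(x$unreached))
    cat("  unreached:", paste(x$unreached, collapse = ", "), "\n")
  invisible(x)
}
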