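# JSON/CSV serialization of models and results. All JSON is written with a
# fixed field order and fixed numeric precision so identical analyses give
# byte-identical files.

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Serialize a network model to JSON
#'
#' Writes the node list, dense weight matrix, selected penalty, EBIC
#' hyperparameter and value, edge count and sample size.
#'
#' @param net a `network_model`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "network_model"))
  write_json_stable(list(
    nodes = net$nodes,
    weights = unname(apply(net$weights, 1, as.numeric, simplify = FALSE)),
    lambda = net$lambda, gamma = net$gamma, ebic = net$ebic,
    edge_count = net$edge_count, n = net$n), path)
}

#' Read a network model back from JSON
#' @param path file written by [write_network_json()].
#' @return a `network_model`.
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- as.matrix(x$weights)
  dimnames(w) <- list(x$nodes, x$nodes)
  structure(list(nodes = x$nodes, weights = w, lambda = x$lambda,
                 gamma = x$gamma, ebic = x$ebic,
                 edge_count = x$edge_count, n = x$n),
            class = "network_model")
}

#' Weighted edge list of a network
#' @param net a `network_model`.
#' @param keep_zero include zero-weight pairs (default FALSE).
#' @return data frame `node_i`, `node_j`, `weight` (upper triangle).
#' @export
network_to_edgelist <- function(net, keep_zero = FALSE) {
  w <- net$weights
  ut <- upper.tri(w)
  out <- data.frame(node_i = net$nodes[row(w)[ut]],
                    node_j = net$nodes[col(w)[ut]],
                    weight = w[ut], stringsAsFactors = FALSE)
  if (!keep_zero) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a correlation matrix as a square labelled CSV
#' @param ce a `correlation_estimate` or plain labelled matrix.
#' @param path output file.
#' @export
write_correlation_csv <- function(ce, path) {
  m <- if (inherits(ce, "correlation_estimate")) ce$matrix else as.matrix(ce)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a square labelled correlation CSV
#' @param path file written by [write_correlation_csv()].
#' @param n effective sample size to attach.
#' @return a `correlation_estimate`.
#' @export
read_correlation_csv <- function(path, n) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  structure(list(matrix = m, method = "spearman", n = n, repaired = FALSE),
            class = "correlation_estimate")
}

flow_to_list <- function(fd) {
  list(focal = fd$focal, direct = as.list(fd$direct),
       indirect_layers = lapply(fd$indirect_layers, as.list),
       unreached = as.list(fd$unreached),
       edges_to_focal = fd$edges_to_focal)
}

nct_to_list <- function(x) {
  list(S_observed = x$S_observed, M_observed = x$M_observed,
       p_S = x$p_S, p_M = x$p_M, n_perm = x$n_perm, seed = x$seed,
       redrawn = x$redrawn, perm_S = x$perm_S, perm_M = x$perm_M)
}

# small FNV-1a string hash used to stamp outputs with their configuration
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
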