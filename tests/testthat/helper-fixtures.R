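# Fixtures are generated in code; oracles here are deliberately naive
# (enumeration / brute force) and independent of the package internals.

toy_truth <- function(seed = 77, p = 9, density = 0.3,
                      weights = c(0.2, 0.4)) {
  make_true_network(p, density, weights, seed = seed)
}

toy_dataset <- function(n = 400, seed = 99, p = 9, truth = NULL) {
  if (is.null(truth)) truth <- toy_truth(p = p)
  sample_ordinal_dataset(truth, n, default_emulation(p), seed = seed)
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# all simple paths between s and t on an adjacency with distances d (Inf = no
# edge); returns list of integer vectors (node sequences)
all_simple_paths_bf <- function(d, s, t) {
  p <- nrow(d)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (v in seq_len(p)) {
      if (v %in% path) next
      if (is.finite(d[last, v])) walk(c(path, v))
    }
  }
  walk(s)
  out
}

path_length_bf <- function(d, path) {
  if (length(path) < 2) return(0)
  sum(d[cbind(path[-length(path)], path[-1])])
}

# exhaustive-enumeration betweenness with fractional credit for ties
betweenness_bf <- function(w) {
  p <- nrow(w)
  d <- 1 / abs(w)
  d[w == 0] <- Inf
  btw <- numeric(p)
  for (s in 1:(p - 1)) for (t in (s + 1):p) {
    paths <- all_simple_paths_bf(d, s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, function(pt) path_length_bf(d, pt), numeric(1))
    best <- min(lens)
    short <- paths[abs(lens - best) < 1e-9]
    for (pt in short) {
      mid <- setdiff(pt, c(s, t))
      btw[mid] <- btw[mid] + 1 / length(short)
    }
  }
  btw
}

# exhaustive-enumeration harmonic closeness on d = 1/|w|
closeness_bf <- function(w) {
  p <- nrow(w)
  d <- 1 / abs(w)
  d[w == 0] <- Inf
  clo <- numeric(p)
  for (s in 1:p) for (t in 1:p) {
    if (s == t) next
    paths <- all_simple_paths_bf(d, s, t)
    if (length(paths) == 0) next
    best <- min(vapply(paths, function(pt) path_length_bf(d, pt), numeric(1)))
    clo[s] <- clo[s] + 1 / best
  }
  clo
}

# independent BFS layer classification around a focal node
flow_layers_bf <- function(w, fi) {
  p <- nrow(w)
  adj <- w != 0
  dist <- rep(Inf, p)
  dist[fi] <- 0
  frontier <- fi
  k <- 0
  while (length(frontier)) {
    k <- k + 1
    nxt <- integer(0)
    for (v in frontier) nxt <- union(nxt, which(adj[v, ]))
    nxt <- nxt[!is.finite(dist[nxt])]
    dist[nxt] <- k
    frontier <- nxt
  }
  dist
}

fast_cfg <- function() net_config()
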