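#' Sample a sparse ground-truth partial-correlation network
#'
#' Draws an edge pattern with the requested density, edge magnitudes uniform
#' in `weight_range` with a `sign_mix` probability of a negative sign, and
#' constructs a positive-definite precision matrix whose realized partial
#' correlations match the drawn weights. The precision starts with unit
#' diagonal and off-diagonals `-w_ij`; if its smallest eigenvalue falls
#' below `min_eigen` the diagonal is inflated and the off-diagonals
#' recalibrated until the realized partial correlations are within `tol` of
#' target. Infeasible specifications (high density with large weights)
#' raise a constructive-failure error.
#'
#' @param p number of nodes (>= 3).
#' @param density fraction of the `p(p-1)/2` possible edges present.
#' @param weight_range interval for the absolute partial correlation of
#'   present edges.
#' @param sign_mix probability that an edge is negative.
#' @param seed integer seed.
#' @param min_eigen smallest allowed precision eigenvalue (default 0.05).
#' @param tol maximum allowed deviation of realized from target partial
#'   correlations (default 0.02).
#' @param scalable_to optional scale factor; when given, only truths whose
#'   edge weights can all be multiplied by this factor while remaining a
#'   valid (positive-definite) model are accepted, so the truth can serve
#'   as the base of a two-group design with that `group_scale`.
#' @return object of class `true_network`: `weights` (realized partial
#'   correlations, zero diagonal), `correlation` (implied latent correlation
#'   matrix), `precision`, `p`, `density`.
#' @export
make_true_network <- function(p, density, weight_range = c(0.2, 0.4),
                              sign_mix = 0, seed = NULL,
                              min_eigen = 0.05, tol = 0.02,
                              scalable_to = NULL) {
  stopifnot(p >= 3, density >= 0, density <= 1, sign_mix >= 0, sign_mix <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- p * (p - 1) / 2
  n_edges <- round(density * n_pairs)

  # a drawn edge pattern can place its weights so that no positive-definite
  # precision realizes them exactly; such draws are rejected and redrawn
  # (deterministically, advancing the seeded RNG), and only a spec for which
  # every attempt fails is declared infeasible
  for (attempt in 1:100) {
    target <- matrix(0, p, p)
    if (n_edges > 0) {
      pick <- sample.int(n_pairs, n_edges)
      mag <- stats::runif(n_edges, weight_range[1], weight_range[2])
      sgn <- ifelse(stats::runif(n_edges) < sign_mix, -1, 1)
      ut <- which(upper.tri(target))
      target[ut[pick]] <- mag * sgn
      target <- target + t(target)
    }
    out <- tryCatch(rebuild_from_target(target, p, density, min_eigen, tol),
                    error = function(e) NULL)
    if (is.null(out) ||
        min(eigen(out$correlation, symmetric = TRUE,
                  only.values = TRUE)$values) < 0.01)
      next
    if (!is.null(scalable_to) &&
        is.null(tryCatch(scale_true_network(out, scalable_to),
                         error = function(e) NULL)))
      next
    return(out)
  }
  stop("infeasible network spec: no positive-definite realization found; ",
       "lower density or weights")
}

#' Rescale every edge of a ground-truth network
#'
#' Multiplies all true partial correlations by `scale` and reconstructs the
#' precision and implied correlation. Errors when the scaled network is no
#' longer a valid (positive-definite) model, instructing a smaller scale.
#'
#' @param truth a `true_network`.
#' @param scale multiplier applied to every edge weight.
#' @return a `true_network` with scaled weights.
#' @export
scale_true_network <- function(truth, scale) {
  stopifnot(inherits(truth, "true_network"))
  if (scale == 1) return(truth)
  target <- truth$weights * scale
  out <- tryCatch(
    rebuild_from_target(target, truth$p, truth$density),
    error = function(e)
      stop("scaled network is not positive definite; use a smaller group_scale"))
  out
}

rebuild_from_target <- function(target, p, density,
                                min_eigen = 0.05, tol = 0.02) {
  theta <- -target
  diag(theta) <- 1
  delta <- 0
  repeat {
    ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= min_eigen) break
    delta <- delta + 0.05
    if (delta > 4) stop("not positive definite")
    diag(theta) <- 1 + delta
  }
  w_cur <- target
  for (iter in 1:50) {
    d <- sqrt(diag(theta))
    realized <- -theta / outer(d, d)
    diag(realized) <- 0
    if (max(abs(realized - target)) <= tol) break
    w_cur <- target * outer(d, d)
    theta <- -w_cur
    diag(theta) <- 1 + delta
    ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
    while (min(ev) < min_eigen) {
      delta <- delta + 0.05
      if (delta > 4) stop("not positive definite")
      diag(theta) <- 1 + delta
      ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
    }
    if (iter == 50) stop("calibration failed")
  }
  d <- sqrt(diag(theta))
  weights <- -theta / outer(d, d)
  diag(weights) <- 0
  correlation <- stats::cov2cor(solve(theta))
  correlation <- (correlation + t(correlation)) / 2
  structure(list(weights = weights, correlation = correlation,
                 precision = theta, p = p, density = density),
            class = "true_network")
}

#' Calibrate thresholds for a discretized standard normal item
#'
#' Finds three increasing cut points partitioning N(0,1) into categories
#' 0..3 whose discretized mean and SD match the targets (mean weighted more
#' heavily, as marginal location is what the reference descriptives pin
#' down).
#'
#' @param target_mean,target_sd desired marginal mean and SD of the 0-3 item.
#' @return numeric vector of three increasing cut points.
#' @export
calibrate_thresholds <- function(target_mean, target_sd) {
  obj <- function(par) {
    cuts <- cumsum(c(par[1], exp(par[2]), exp(par[3])))
    pr <- diff(c(0, stats::pnorm(cuts), 1))
    m <- sum(pr * 0:3)
    s <- sqrt(sum(pr * (0:3)^2) - m^2)
    4 * (m - target_mean)^2 + (s - target_sd)^2
  }
  fit <- stats::optim(c(0, log(0.8), log(0.8)), obj,
                      control = list(maxit = 2000, reltol = 1e-12))
  cumsum(c(fit$par[1], exp(fit$par[2]), exp(fit$par[3])))
}

#' Default ordinal emulation settings
#'
#' Thresholds for the nine PHQ items calibrated to the urban reference
#' marginals (right-skewed, mostly-zero responses) and affine latent-to-
#' score maps for the two IU dimensions. With `p = 9` only the PHQ items
#' are produced; with `p = 11` the AA and IA dimension scores are appended.
#'
#' @param p 9 (PHQ only) or 11 (PHQ plus AA/IA).
#' @return list with `labels`, `thresholds` (list of cut-point vectors per
#'   PHQ item) and `iu` (per IU item, `mean` and `sd` of the affine map).
#' @export
default_emulation <- function(p = 11) {
  stopifnot(p %in% c(9, 11))
  ref <- reference_descriptives()
  phq <- ref[1:9, ]
  thresholds <- lapply(1:9, function(i)
    calibrate_thresholds(phq$m_urban[i], phq$sd_urban[i]))
  names(thresholds) <- phq$item
  out <- list(labels = phq$item, thresholds = thresholds, iu = NULL)
  if (p == 11) {
    out$labels <- c(out$labels, "AA", "IA")
    out$iu <- list(AA = list(mean = ref$m_urban[10], sd = ref$sd_urban[10]),
                   IA = list(mean = ref$m_urban[11], sd = ref$sd_urban[11]))
  }
  out
}

#' Sample an ordinal questionnaire dataset from a ground-truth network
#'
#' Draws latent multivariate-normal scores with the truth's implied
#' correlation matrix, discretizes PHQ columns at the emulation thresholds
#' (categories 0-3), and maps IU columns to the 1-5 scale by an affine
#' transform truncated at the scale ends.
#'
#' @param truth a `true_network` with `p` equal to the number of emulated
#'   items.
#' @param n number of subjects.
#' @param emulation settings from [default_emulation()] (default matches
#'   `truth$p`).
#' @param group optional single group label attached to all subjects.
#' @param seed integer seed.
#' @return an [item_dataset()].
#' @export
sample_ordinal_dataset <- function(truth, n, emulation = NULL,
                                   group = NULL, seed = NULL) {
  stopifnot(inherits(truth, "true_network"))
  if (is.null(emulation)) emulation <- default_emulation(truth$p)
  if (length(emulation$labels) != truth$p)
    stop("emulation settings and truth dimension disagree")
  if (!is.null(seed)) set.seed(seed)
  z <- MASS::mvrnorm(n, mu = rep(0, truth$p), Sigma = truth$correlation)
  out <- matrix(0, n, truth$p, dimnames = list(NULL, emulation$labels))
  for (j in seq_along(emulation$labels)) {
    lab <- emulation$labels[j]
    if (lab %in% names(emulation$thresholds)) {
      cuts <- emulation$thresholds[[lab]]
      if (is.unsorted(cuts, strictly = TRUE))
        stop("thresholds must be strictly increasing for item ", lab)
      out[, j] <- findInterval(z[, j], cuts)
    } else {
      iu <- emulation$iu[[lab]]
      out[, j] <- pmin(pmax(iu$mean + iu$sd * z[, j], 1), 5)
    }
  }
  item_dataset(out,
               group = if (!is.null(group)) rep(group, n) else NULL,
               phq_items = intersect(emulation$labels,
                                     names(emulation$thresholds)),
               iu_items = setdiff(emulation$labels,
                                  names(emulation$thresholds)))
}

#' Simulate a two-group study with a controllable edge-weight difference
#'
#' Group A is sampled from the ground truth; group B from the same truth
#' with every edge weight multiplied by `group_scale` (so the true
#' global-strength ratio is exactly `group_scale`). Default sizes emulate a
#' 439 / 1049 urban-rural design.
#'
#' @param truth a `true_network`.
#' @param nA,nB group sizes (defaults 439 and 1049).
#' @param group_scale multiplier for group B's edge weights (must keep the
#'   scaled precision positive definite).
#' @param emulation ordinal emulation settings (default matches `truth$p`).
#' @param labels group labels, length 2.
#' @param seed integer seed; group draws use `seed` and `seed + 1`.
#' @return list with `A`, `B` ([item_dataset()]s), `truth_A`, `truth_B`,
#'   `pooled` (both groups stacked with the group label set).
#' @export
make_two_group_study <- function(truth, nA = 439, nB = 1049,
                                 group_scale = 1, emulation = NULL,
                                 labels = c("urban", "rural"),
                                 seed = NULL) {
  stopifnot(inherits(truth, "true_network"), length(labels) == 2)
  truth_b <- scale_true_network(truth, group_scale)
  if (is.null(emulation)) emulation <- default_emulation(truth$p)
  if (is.null(seed)) seed <- sample.int(2^30, 1)
  A <- sample_ordinal_dataset(truth, nA, emulation, group = labels[1],
                              seed = seed)
  B <- sample_ordinal_dataset(truth_b, nB, emulation, group = labels[2],
                              seed = seed + 1L)
  pooled <- item_dataset(
    rbind(A$values, B$values),
    group = c(rep(labels[1], nA), rep(labels[2], nB)),
    phq_items = intersect(emulation$labels, names(emulation$thresholds)),
    iu_items = setdiff(emulation$labels, names(emulation$thresholds)))
  list(A = A, B = B, truth_A = truth, truth_B = truth_b, pooled = pooled)
}
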