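#' Spearman rank correlation matrix for network estimation
#'
#' Pairwise Spearman correlations (average ranks for ties) over complete
#' data. Ordinal PHQ items and the near-continuous IU dimension scores are
#' treated identically by the rank estimator. If the resulting matrix is not
#' positive definite it is repaired by [nearest_positive_definite()] so the
#' graphical-lasso log-determinant objective is finite; the `repaired` flag
#' records this.
#'
#' @param data an [item_dataset()] or a numeric matrix with named columns.
#' @param items optional subset of item labels.
#' @return object of class `correlation_estimate`: list with `matrix`,
#'   `method = "spearman"`, `n` (subjects), `repaired`.
#' @export
rank_correlation_matrix <- function(data, items = NULL) {
  v <- if (inherits(data, "item_dataset")) data$values else as.matrix(data)
  if (!is.null(items)) v <- v[, items, drop = FALSE]
  if (nrow(v) < 10) stop("need at least 10 subjects")
  if (ncol(v) < 2) stop("need at least 2 items")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("correlation undefined: constant item ",
         colnames(v)[which(sds == 0)[1]])
  r <- stats::cor(v, method = "spearman")
  out <- list(matrix = r, method = "spearman", n = nrow(v), repaired = FALSE)
  if (!is_positive_definite(r, 1e-10)) {
    out$matrix <- nearest_positive_definite(r)
    out$repaired <- TRUE
  }
  class(out) <- "correlation_estimate"
  out
}

is_positive_definite <- function(m, eps = 0) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > eps
}

#' Repair a symmetric matrix to positive definiteness
#'
#' Eigenvalues are clipped below at `eps`, the matrix is reconstituted and
#' rescaled back to unit diagonal; this repeats until the smallest eigenvalue
#' is at least `eps` (usually one pass). A matrix that is already positive
#' definite is returned unchanged, which makes the repair idempotent.
#'
#' @param m symmetric numeric matrix.
#' @param eps eigenvalue floor (default 1e-6).
#' @return repaired symmetric matrix with unit diagonal and smallest
#'   eigenvalue >= `eps`.
#' @export
nearest_positive_definite <- function(m, eps = 1e-6) {
  m <- as.matrix(m)
  if (!isSymmetric(m, tol = 1e-8))
    stop("input must be symmetric")
  dn <- dimnames(m)
  for (i in 1:50) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= eps) break
    lam <- pmax(e$values, eps)
    m <- e$vectors %*% (lam * t(e$vectors))
    m <- stats::cov2cor(m)
    m <- (m + t(m)) / 2
  }
  dimnames(m) <- dn
  m
}
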