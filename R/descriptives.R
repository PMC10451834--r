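#' Item-level descriptive statistics
#'
#' Mean, sample standard deviation (n-1 denominator), moment skewness and
#' excess kurtosis per item, overall or per group. Skewness is
#' g1 = m3 / m2^(3/2) and excess kurtosis g2 = m4 / m2^2 - 3, with mk the
#' central moments using 1/n denominators. For a constant column both shape
#' statistics are undefined: they are returned as `NA` with `constant = TRUE`.
#'
#' @param data an [item_dataset()].
#' @param by_group if `TRUE`, compute within each group level.
#' @return data frame with columns `group` (or `"all"`), `item`, `mean`,
#'   `sd`, `skewness`, `kurtosis`, `n`, `constant`.
#' @export
describe_items <- function(data, by_group = FALSE) {
  stopifnot(inherits(data, "item_dataset"))
  groups <- if (by_group) {
    if (is.null(data$group)) stop("by_group = TRUE but dataset has no group")
    split(seq_len(nrow(data$values)), data$group)
  } else list(all = seq_len(nrow(data$values)))

  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) < 3) stop("need at least 3 subjects per group")
    do.call(rbind, lapply(data$item_labels, function(it) {
      x <- data$values[idx, it]
      n <- length(x)
      m <- mean(x)
      d <- x - m
      m2 <- mean(d^2)
      const <- m2 <= .Machine$double.eps * max(1, m^2)
      data.frame(
        group = g, item = it, mean = m, sd = stats::sd(x),
        skewness = if (const) NA_real_ else mean(d^3) / m2^1.5,
        kurtosis = if (const) NA_real_ else mean(d^4) / m2^2 - 3,
        n = n, constant = const, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PHQ-9 totals and depression prevalence by group
#'
#' Sums the nine PHQ items per subject and classifies a subject as screening
#' positive for depression when the total is greater than or equal to the
#' cutoff (default 8, the validated optimal PHQ-9 cut-off).
#'
#' @param data an [item_dataset()] containing all nine PHQ columns.
#' @param cutoff integer in 0..27.
#' @param phq_items the nine PHQ column labels.
#' @return list with `totals` (per-subject integer totals), `depressed`
#'   (logical), and `counts`, a group x {depressed, not_depressed} integer
#'   matrix (a single "all" row when the dataset has no group label).
#' @export
phq_total_and_prevalence <- function(data, cutoff = 8,
                                     phq_items = paste0("PHQ", 1:9)) {
  stopifnot(inherits(data, "item_dataset"))
  if (length(cutoff) != 1 || cutoff < 0 || cutoff > 27)
    stop("cutoff must lie in [0, 27]")
  miss <- setdiff(phq_items, data$item_labels)
  if (length(miss)) stop("missing PHQ column(s): ", paste(miss, collapse = ", "))
  totals <- rowSums(data$values[, phq_items, drop = FALSE])
  dep <- totals >= cutoff
  grp <- if (is.null(data$group)) factor(rep("all", length(dep))) else data$group
  counts <- t(vapply(levels(grp), function(g) {
    c(depressed = sum(dep[grp == g]), not_depressed = sum(!dep & grp == g))
  }, integer(2)))
  list(totals = totals, depressed = dep, counts = counts, cutoff = cutoff)
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Uncorrected Pearson statistic sum((O-E)^2/E) with expected counts from the
#' margins, df = 1. No Yates continuity correction is applied.
#'
#' @param counts 2x2 matrix of nonnegative counts.
#' @return data frame with `statistic`, `value`, `df`, `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0))
    stop("counts must be a nonnegative 2x2 table")
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: a marginal total is zero")
  expected <- outer(rs, cs) / n
  stat <- sum((counts - expected)^2 / expected)
  data.frame(statistic = "chi_square", value = stat, df = 1,
             p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student t with pooled variance
#' s_p^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2),
#' t = (m1-m2) / (s_p sqrt(1/n1 + 1/n2)), df = n1+n2-2, two-sided p, and
#' Cohen's d = (m1-m2)/s_p. When both SDs are zero the statistic is 0 for
#' equal means and infinite (flagged) otherwise.
#'
#' @param m1,sd1,n1 mean, sample SD and size of group 1.
#' @param m2,sd2,n2 mean, sample SD and size of group 2.
#' @return data frame with `t`, `df`, `p`, `cohens_d`, `infinite` flag.
#' @export
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be nonnegative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  diff <- m1 - m2
  if (sp2 == 0) {
    if (diff == 0)
      return(data.frame(t = 0, df = df, p = 1, cohens_d = 0, infinite = FALSE))
    return(data.frame(t = sign(diff) * Inf, df = df, p = 0,
                      cohens_d = sign(diff) * Inf, infinite = TRUE))
  }
  sp <- sqrt(sp2)
  tval <- diff / (sp * sqrt(1 / n1 + 1 / n2))
  data.frame(t = tval, df = df,
             p = 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE),
             cohens_d = diff / sp, infinite = FALSE)
}

#' Pooled-variance t test from raw columns
#'
#' Computes the group summaries and delegates to [t_from_summary()], so the
#' two entry points agree exactly.
#'
#' @param x,y numeric vectors for the two groups.
#' @return see [t_from_summary()].
#' @export
t_from_columns <- function(x, y) {
  t_from_summary(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y))
}
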