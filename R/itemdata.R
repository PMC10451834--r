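#' Construct a validated item-level dataset
#'
#' Container for subject-by-item questionnaire responses: nine PHQ-9 items
#' scored 0-3, optionally the two intolerance-of-uncertainty dimension scores
#' (prospective anxiety `AA`, inhibitory anxiety `IA`) on a 1-5 scale, a
#' two-level group label and numeric covariates.
#'
#' @param values numeric matrix or data frame, subjects in rows, items in
#'   columns. Column names are the item labels.
#' @param group optional per-subject group label (character or factor).
#' @param covariates optional data frame of per-subject numeric covariates
#'   (e.g. age in years, gender coded 0/1).
#' @param phq_items labels of columns holding PHQ-9 items (integer 0-3).
#' @param iu_items labels of columns holding IU dimension scores (real 1-5).
#' @param n_dropped number of rows removed upstream (kept for the record).
#' @return An object of class `item_dataset` with elements `values`,
#'   `item_labels`, `group`, `covariates`, `n_dropped`.
#' @export
item_dataset <- function(values, group = NULL, covariates = NULL,
                         phq_items = paste0("PHQ", 1:9),
                         iu_items = c("AA", "IA"),
                         n_dropped = 0L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("item columns must be named")
  if (anyNA(values))
    stop("missing values present; drop or impute before construction")

  labs <- colnames(values)
  phq_present <- intersect(phq_items, labs)
  iu_present <- intersect(iu_items, labs)

  for (it in phq_present) {
    x <- values[, it]
    bad <- which(!(x %in% 0:3))
    if (length(bad))
      stop(sprintf("item %s out of range {0,1,2,3} at row %d (value %g)",
                   it, bad[1], x[bad[1]]))
  }
  for (it in iu_present) {
    x <- values[, it]
    bad <- which(x < 1 | x > 5)
    if (length(bad))
      stop(sprintf("item %s outside [1,5] at row %d (value %g)",
                   it, bad[1], x[bad[1]]))
  }
  if (!is.null(group)) {
    group <- factor(group)
    if (length(group) != nrow(values))
      stop("group label length does not match number of subjects")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values))
      stop("covariate rows do not match number of subjects")
    if (!all(vapply(covariates, is.numeric, logical(1))))
      stop("covariates must be numeric (code gender 0/1)")
    if (anyNA(covariates))
      stop("missing values present in covariates")
  }
  structure(
    list(values = values, item_labels = labs, group = group,
         covariates = covariates, n_dropped = as.integer(n_dropped)),
    class = "item_dataset")
}

#' @export
print.item_dataset <- function(x, ...) {
  cat(sprintf("<item_dataset> %d subjects x %d items\n",
              nrow(x$values), ncol(x$values)))
  cat("  items:", paste(x$item_labels, collapse = ", "), "\n")
  if (!is.null(x$group)) {
    tab <- table(x$group)
    cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), tab),
                           collapse = ", "), "\n")
  }
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  if (x$n_dropped > 0)
    cat("  rows dropped at read time:", x$n_dropped, "\n")
  invisible(x)
}

#' Number of subjects
#' @param data an `item_dataset`.
#' @return integer subject count.
#' @export
n_subjects <- function(data) nrow(data$values)

#' Read an item-level CSV into a validated dataset
#'
#' Reads a subject-per-row CSV, maps columns to item/group/covariate roles,
#' drops rows with any missing mapped value (listwise deletion, counted in
#' `n_dropped` and reported via a message), and validates ranges. Out-of-range
#' values that are not missing raise an error naming the offending CSV data
#' row and column.
#'
#' @param path path to a CSV file with a header row.
#' @param schema named list mapping roles to column names: `phq` (character
#'   vector, the PHQ item columns in order), `iu` (optional, the AA/IA
#'   columns), `group` (optional, a string-valued column), `covariates`
#'   (optional character vector). Defaults assume columns named PHQ1..PHQ9,
#'   AA, IA, group, and covariates age/gender when present.
#' @return An [item_dataset()]; `n_dropped` records listwise deletions.
#' @export
read_item_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)

  if (is.null(schema)) schema <- list()
  if (is.null(schema$phq)) schema$phq <- paste0("PHQ", 1:9)
  if (is.null(schema$iu)) schema$iu <- intersect(c("AA", "IA"), names(raw))
  if (is.null(schema$group))
    schema$group <- if ("group" %in% names(raw)) "group" else NULL
  if (is.null(schema$covariates))
    schema$covariates <- intersect(c("age", "gender"), names(raw))

  needed <- c(schema$phq, schema$iu, schema$group, schema$covariates)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("schema error: column(s) not in file: ",
         paste(missing_cols, collapse = ", "))

  item_cols <- c(schema$phq, schema$iu)
  items <- raw[, item_cols, drop = FALSE]
  for (nm in item_cols) items[[nm]] <- suppressWarnings(as.numeric(items[[nm]]))
  cov <- if (length(schema$covariates))
    raw[, schema$covariates, drop = FALSE] else NULL
  if (!is.null(cov)) for (nm in names(cov))
    cov[[nm]] <- suppressWarnings(as.numeric(cov[[nm]]))
  grp <- if (!is.null(schema$group)) raw[[schema$group]] else NULL

  keep <- stats::complete.cases(items)
  if (!is.null(cov)) keep <- keep & stats::complete.cases(cov)
  if (!is.null(grp)) keep <- keep & !is.na(grp) & nzchar(as.character(grp))
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("read_item_table: dropped %d row(s) with missing values",
                    dropped))

  items <- items[keep, , drop = FALSE]
  orig_row <- which(keep)

  # range validation on retained rows, reporting original CSV data row
  for (it in schema$phq) {
    bad <- which(!(items[[it]] %in% 0:3))
    if (length(bad))
      stop(sprintf("validation error: %s = %g at row %d not in {0,1,2,3}",
                   it, items[[it]][bad[1]], orig_row[bad[1]]))
  }
  for (it in schema$iu) {
    bad <- which(items[[it]] < 1 | items[[it]] > 5)
    if (length(bad))
      stop(sprintf("validation error: %s = %g at row %d outside [1,5]",
                   it, items[[it]][bad[1]], orig_row[bad[1]]))
  }

  item_dataset(as.matrix(items),
               group = if (!is.null(grp)) grp[keep] else NULL,
               covariates = if (!is.null(cov)) cov[keep, , drop = FALSE]
                            else NULL,
               phq_items = schema$phq,
               iu_items = schema$iu,
               n_dropped = dropped)
}

#' Subset the items of a dataset
#' @param data an `item_dataset`.
#' @param items character vector of item labels to keep, in order.
#' @return an `item_dataset` restricted to `items`.
#' @export
select_items <- function(data, items) {
  miss <- setdiff(items, data$item_labels)
  if (length(miss)) stop("unknown item(s): ", paste(miss, collapse = ", "))
  item_dataset(data$values[, items, drop = FALSE], group = data$group,
               covariates = data$covariates,
               phq_items = intersect(items, paste0("PHQ", 1:9)),
               iu_items = intersect(items, c("AA", "IA")),
               n_dropped = data$n_dropped)
}

#' Split a dataset by its group label
#' @param data an `item_dataset` with a two-level group label.
#' @param phq_items,iu_items item-role labels passed through to the
#'   per-group [item_dataset()] constructors.
#' @return named list of two `item_dataset`s (group label retained per part).
#' @export
split_by_group <- function(data, phq_items = paste0("PHQ", 1:9),
                           iu_items = c("AA", "IA")) {
  if (is.null(data$group)) stop("dataset has no group label")
  lev <- levels(data$group)
  if (length(lev) != 2)
    stop("group must have exactly two levels, found ", length(lev))
  out <- lapply(lev, function(g) {
    idx <- data$group == g
    item_dataset(data$values[idx, , drop = FALSE],
                 group = droplevels(data$group[idx]),
                 covariates = if (!is.null(data$covariates))
                   data$covariates[idx, , drop = FALSE] else NULL,
                 phq_items = phq_items, iu_items = iu_items)
  })
  names(out) <- lev
  out
}
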