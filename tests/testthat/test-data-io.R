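toy_frame <- function(n = 5) {
  set.seed(11)
  df <- as.data.frame(matrix(sample(0:3, n * 9, replace = TRUE), n, 9))
  names(df) <- paste0("PHQ", 1:9)
  df$AA <- round(runif(n, 1, 5), 2)
  df$IA <- round(runif(n, 1, 5), 2)
  df$group <- rep(c("urban", "rural"), length.out = n)
  df$age <- sample(16:24, n, replace = TRUE)
  df$gender <- sample(0:1, n, replace = TRUE)
  df
}

test_that("well-formed CSV reads into a validated dataset", {
  path <- write_toy_csv(toy_frame(5))
  d <- read_item_table(path)
  expect_s3_class(d, "item_dataset")
  expect_equal(n_subjects(d), 5)
  expect_equal(d$item_labels, c(paste0("PHQ", 1:9), "AA", "IA"))
  expect_equal(levels(d$group), c("rural", "urban"))
  expect_equal(names(d$covariates), c("age", "gender"))
  expect_equal(d$n_dropped, 0L)
})

test_that("out-of-range PHQ value raises a validation error naming the row", {
  df <- toy_frame(5)
  df$PHQ1[3] <- 7
  path <- write_toy_csv(df)
  expect_error(read_item_table(path), "PHQ1 = 7 at row 3")
})

test_that("rows with missing mapped cells are dropped listwise and counted", {
  df <- toy_frame(6)
  df$IA[4] <- NA
  path <- write_toy_csv(df)
  expect_message(d <- read_item_table(path), "dropped 1 row")
  expect_equal(n_subjects(d), 5)
  expect_equal(d$n_dropped, 1L)
})

test_that("schema errors name the absent columns", {
  df <- toy_frame(4)
  df$PHQ9 <- NULL
  path <- write_toy_csv(df)
  expect_error(read_item_table(path), "PHQ9")
})

test_that("descriptives match direct moment formulas", {
  m <- cbind(A = c(0, 0, 3, 3), B = c(0, 0, 0, 3),
             C = c(1, 1, 1, 1))
  # constant column C allowed through the generic container
  d <- item_dataset(m, phq_items = c("A", "B", "C"), iu_items = character(0))
  desc <- describe_items(d)
  expect_equal(desc$mean, c(1.5, 0.75, 1))
  expect_equal(desc$skewness[1], 0)
  # {0,0,0,3}: m2 = 27/16, m3 = 81/32; g1 = m3/m2^1.5 = 2/sqrt(3)
  expect_equal(desc$skewness[2], 2 / sqrt(3), tolerance = 1e-12)
  expect_true(is.na(desc$skewness[3]) && desc$constant[3])
  expect_equal(desc$sd, c(sd(m[, 1]), sd(m[, 2]), 0))
})

test_that("excess kurtosis of standard normal draws is near zero", {
  set.seed(42)
  m <- cbind(Z = rnorm(1e5))
  d <- item_dataset(m, phq_items = character(0), iu_items = character(0))
  desc <- describe_items(d)
  expect_lt(abs(desc$kurtosis), 0.05)
  expect_lt(abs(desc$skewness), 0.05)
})

test_that("grouped descriptives need a group and 3+ subjects per level", {
  d <- toy_dataset(30, seed = 5)
  expect_error(describe_items(d, by_group = TRUE), "no group")
})

test_that("PHQ totals, cutoff boundary and per-group counts", {
  set.seed(21)
  vals <- matrix(sample(0:3, 10 * 9, replace = TRUE), 10, 9)
  colnames(vals) <- paste0("PHQ", 1:9)
  vals[1, ] <- 0                                # total 0
  vals[2, ] <- c(1, 1, 1, 1, 1, 1, 1, 1, 0)     # total 8: depressed
  grp <- rep(c("u", "r"), each = 5)
  d <- item_dataset(vals, group = grp)
  res <- phq_total_and_prevalence(d, cutoff = 8)
  expect_equal(res$totals, rowSums(vals))
  expect_false(res$depressed[1])
  expect_true(res$depressed[2])
  # brute-force tally per group
  for (g in c("u", "r")) {
    expect_equal(unname(res$counts[g, "depressed"]),
                 sum(rowSums(vals)[grp == g] >= 8))
  }
  expect_equal(sum(res$counts), 10)
  expect_error(phq_total_and_prevalence(d, cutoff = 30), "cutoff")
})

test_that("chi-square matches the direct formula and is label-invariant", {
  counts <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(chi_square_2x2(counts)$value, 0)
  counts <- matrix(c(10, 30, 20, 60), 2)   # proportional
  expect_equal(chi_square_2x2(counts)$value, 0)
  counts <- matrix(c(12, 5, 9, 14), 2)
  # direct formula evaluation
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  expect_equal(chi_square_2x2(counts)$value, sum((counts - E)^2 / E))
  expect_equal(chi_square_2x2(counts)$value,
               chi_square_2x2(counts[2:1, ])$value)
  expect_equal(chi_square_2x2(counts)$value,
               chi_square_2x2(counts[, 2:1])$value)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "degenerate")
})

test_that("pooled t from summaries: hand case, identical groups, edge cases", {
  expect_equal(t_from_summary(1, 1, 10, 1, 1, 10)$t, 0)
  # s_p = 1, SE = sqrt(0.2)
  r <- t_from_summary(1, 1, 10, 0, 1, 10)
  expect_equal(r$t, 1 / sqrt(0.2), tolerance = 1e-12)
  expect_equal(r$df, 18)
  expect_equal(r$cohens_d, 1)
  z <- t_from_summary(1, 0, 5, 1, 0, 5)
  expect_equal(z$t, 0)
  inf <- t_from_summary(2, 0, 5, 1, 0, 5)
  expect_true(inf$infinite && is.infinite(inf$t))
})

test_that("t from raw columns equals t from their summaries", {
  set.seed(3)
  for (k in 1:5) {
    x <- rnorm(20 + k, sd = 1 + k / 5)
    y <- rnorm(35, mean = 0.3)
    a <- t_from_columns(x, y)
    b <- t_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    expect_equal(a$t, b$t, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
})
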