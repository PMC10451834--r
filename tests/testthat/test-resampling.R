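test_that("bootstrap reports are seed-reproducible", {
  d <- toy_dataset(150, seed = 101)
  a <- bootstrap_edge_cis(d, B = 2, seed = 7)
  b <- bootstrap_edge_cis(d, B = 2, seed = 7)
  expect_identical(a$edge_draws, b$edge_draws)
  expect_identical(a$edges, b$edges)
  c2 <- bootstrap_edge_cis(d, B = 2, seed = 8)
  expect_false(identical(a$edge_draws, c2$edge_draws))
})

test_that("bootstrap CI ordering and coverage behavior", {
  # strong single edge: its CI excludes zero
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.6
  truth <- symptomnet:::rebuild_from_target(w, 3, NA)
  set.seed(111)
  z <- MASS::mvrnorm(2000, rep(0, 3), truth$correlation)
  colnames(z) <- c("a", "b", "c")
  d <- item_dataset(z, phq_items = character(0), iu_items = character(0))
  rep1 <- bootstrap_edge_cis(d, B = 120, seed = 9)
  expect_true(all(rep1$edges$lower <= rep1$edges$boot_mean + 1e-12))
  expect_true(all(rep1$edges$boot_mean <= rep1$edges$upper + 1e-12))
  strong <- rep1$edges[rep1$edges$node_i == "a" & rep1$edges$node_j == "b", ]
  expect_gt(strong$lower, 0)

  # independent data: nearly all edge CIs contain zero
  truth0 <- make_true_network(9, 0, seed = 113)
  d0 <- sample_ordinal_dataset(truth0, 600, default_emulation(9), seed = 114)
  rep0 <- bootstrap_edge_cis(d0, B = 120, seed = 10)
  covered <- mean(rep0$edges$lower <= 0 & rep0$edges$upper >= 0)
  expect_gte(covered, 0.9)
})

test_that("difference tests flag separated edges and spare equal ones", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.6     # strong edge
  w[3, 4] <- w[4, 3] <- 0.0     # absent edge
  truth <- symptomnet:::rebuild_from_target(w, 4, NA)
  set.seed(121)
  z <- MASS::mvrnorm(2000, rep(0, 4), truth$correlation)
  colnames(z) <- c("a", "b", "c", "d")
  d <- item_dataset(z, phq_items = character(0), iu_items = character(0))
  rep1 <- bootstrap_edge_cis(d, B = 150, seed = 11)
  diffs <- bootstrap_difference_tests(rep1)
  row <- diffs$edge_differences[
    diffs$edge_differences$a == "a--b" & diffs$edge_differences$b == "c--d", ]
  expect_true(row$significant)
  # flags are symmetric in pair order: the interval of (y - x) mirrors (x - y)
  expect_identical(diffs$edge_differences$significant,
                   with(diffs$edge_differences, lower > 0 | upper < 0))
})

test_that("equal true edges are flagged at roughly the nominal level", {
  # two equal edges: significance should be rare across repetitions
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.3
  w[3, 4] <- w[4, 3] <- 0.3
  truth <- symptomnet:::rebuild_from_target(w, 4, NA)
  hits <- 0
  for (r in 1:15) {
    set.seed(3000 + r)
    z <- MASS::mvrnorm(800, rep(0, 4), truth$correlation)
    colnames(z) <- c("a", "b", "c", "d")
    d <- item_dataset(z, phq_items = character(0), iu_items = character(0))
    rep1 <- bootstrap_edge_cis(d, B = 120, seed = r)
    diffs <- bootstrap_difference_tests(rep1)
    row <- diffs$edge_differences[
      diffs$edge_differences$a == "a--b" &
        diffs$edge_differences$b == "c--d", ]
    hits <- hits + row$significant
  }
  expect_lte(hits / 15, 0.2)
})

test_that("case-dropping curve starts at 1 and the CS scan is correct", {
  d <- toy_dataset(250, seed = 131)
  cs <- case_dropping_curve(d, drops = c(0.1, 0.3), B = 25, seed = 12)
  expect_s3_class(cs, "cs_curve")
  expect_true(all(cs$curve$prob_above >= 0 & cs$curve$prob_above <= 1))
  expect_true(cs$cs_coefficient %in% c(0, cs$curve$drop))

  # direct-scan oracle on a hand-built curve
  fake <- structure(list(curve = data.frame(
    drop = c(0.05, 0.10, 0.15, 0.20, 0.25),
    mean_correlation = c(.99, .97, .96, .9, .8),
    prob_above = c(1, 0.97, 0.96, 0.80, 0.5),
    B_used = 100), statistic = "strength",
    r_threshold = 0.7, prob = 0.95), class = "cs_curve")
  expect_equal(cs_coefficient(fake), 0.15)
  fake$curve$prob_above <- rep(1, 5)
  expect_equal(cs_coefficient(fake), 0.25)
  fake$curve$prob_above <- rep(0.9, 5)
  expect_equal(cs_coefficient(fake), 0)
  # raising the required probability can only lower the coefficient
  fake$curve$prob_above <- c(1, 0.97, 0.96, 0.80, 0.5)
  expect_lte(cs_coefficient(fake, prob = 0.99), cs_coefficient(fake, prob = 0.9))
})

test_that("case-dropping is seed-deterministic and respects the size floor", {
  d <- toy_dataset(80, seed = 141)
  a <- suppressWarnings(
    case_dropping_curve(d, drops = c(0.1, 0.9), B = 10, seed = 13))
  b <- suppressWarnings(
    case_dropping_curve(d, drops = c(0.1, 0.9), B = 10, seed = 13))
  expect_identical(a$curve, b$curve)
  expect_false(0.9 %in% a$curve$drop)   # 8 subjects < p + 5: skipped
  suppressWarnings(
    expect_warning(cs <- case_dropping_curve(d, drops = c(0.9), B = 5,
                                             seed = 1), "skipped"))
  expect_true(is.na(cs$cs_coefficient))
})
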