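test_that("glasso closed forms: identity, penalty dominance, equicorrelation", {
  expect_equal(glasso_precision(diag(4), 0.3)$theta, diag(4))

  S <- matrix(0.5, 3, 3); diag(S) <- 1
  f <- glasso_precision(S, 0.6)   # lambda >= max |S_ij|
  expect_equal(f$theta[upper.tri(f$theta)], rep(0, 3))

  # equicorrelation r = 0.5, lambda -> 0: partial correlations r/(1+r) = 1/3
  f0 <- glasso_precision(S, 1e-7)
  w <- -f0$theta / sqrt(outer(diag(f0$theta), diag(f0$theta)))
  expect_equal(w[upper.tri(w)], rep(1 / 3, 3), tolerance = 1e-4)

  expect_error(glasso_precision(matrix(c(1, 2, 2, 1), 2), 0.1),
               "positive definite")
  expect_error(glasso_precision(diag(3), -1), "nonnegative")
})

test_that("lambda -> 0 weights equal unpenalized partial correlations", {
  set.seed(12)
  for (k in 1:5) {
    q <- matrix(rnorm(16), 4)
    S <- cov2cor(crossprod(q) + 4 * diag(4))   # well conditioned
    f <- glasso_precision(S, 1e-7)
    inv <- solve(S)
    pc <- -inv / sqrt(outer(diag(inv), diag(inv)))
    w <- -f$theta / sqrt(outer(diag(f$theta), diag(f$theta)))
    expect_equal(w[upper.tri(w)], pc[upper.tri(pc)], tolerance = 1e-4)
  }
})

test_that("ebic identities: empty graph, gamma difference, hand formula", {
  f <- glasso_precision(diag(3), 0.5)
  expect_equal(ebic(f, diag(3), 100, gamma = 0),
               ebic(f, diag(3), 100, gamma = 0.9))   # E = 0

  S <- matrix(0, 3, 3); diag(S) <- 1
  S[1, 2] <- S[2, 1] <- 0.5; S[2, 3] <- S[3, 2] <- 0.4
  S <- nearest_positive_definite(S)
  f2 <- glasso_precision(S, 0.05)
  E <- sum(f2$theta[upper.tri(f2$theta)] != 0)
  expect_equal(ebic(f2, S, 100, gamma = 0.5) - ebic(f2, S, 100, gamma = 0),
               2 * E * log(3), tolerance = 1e-10)
  # penalty term at gamma: E log n + 4 E gamma log p
  ll <- (100 / 2) * f2$ll0
  expect_equal(ebic(f2, S, 100, gamma = 0.25),
               -2 * ll + E * log(100) + 4 * E * 0.25 * log(3),
               tolerance = 1e-10)
})

test_that("estimated networks are symmetric, zero-diagonal, with |w| < 1", {
  d <- toy_dataset(300, seed = 31)
  net <- estimate_network(d)
  expect_identical(net$weights, t(net$weights))
  expect_equal(diag(net$weights), setNames(rep(0, 9), net$nodes))
  expect_true(all(abs(net$weights) < 1))
  expect_equal(net$edge_count, sum(net$weights[upper.tri(net$weights)] != 0))
})

test_that("edge count is monotone along the path and in gamma", {
  d <- toy_dataset(500, seed = 32)
  ce <- rank_correlation_matrix(d)
  lmax <- max(abs(ce$matrix[upper.tri(ce$matrix)]))
  lams <- exp(seq(log(lmax), log(0.01 * lmax), length.out = 25))
  ecounts <- vapply(lams, function(l) {
    th <- glasso_precision(ce$matrix, l)$theta
    sum(th[upper.tri(th)] != 0)
  }, numeric(1))
  expect_true(all(diff(ecounts) >= 0))   # lambdas decreasing: edges grow

  n0 <- estimate_network(ce, gamma = 0)
  n1 <- estimate_network(ce, gamma = 1)
  expect_lte(n1$edge_count, n0$edge_count)
})

test_that("chain-graph truth is fully recovered at n = 2000", {
  w <- matrix(0, 9, 9)
  for (i in 1:8) w[i, i + 1] <- w[i + 1, i] <- 0.3
  truth <- symptomnet:::rebuild_from_target(w, 9, NA)
  d <- sample_ordinal_dataset(truth, 2000, default_emulation(9), seed = 41)
  net <- estimate_network(d)
  for (i in 1:8) expect_true(net$weights[i, i + 1] != 0)
})

test_that("independent items give an (almost) empty selected network", {
  truth <- make_true_network(9, 0, seed = 5)
  d <- sample_ordinal_dataset(truth, 2000, default_emulation(9), seed = 6)
  net <- estimate_network(d)
  expect_gte(mean(net$weights[upper.tri(net$weights)] == 0), 0.9)
})

test_that("covariate adjustment leaves an independent covariate inert", {
  truth <- toy_truth(seed = 52)
  d <- sample_ordinal_dataset(truth, 1500, default_emulation(9), seed = 53)
  set.seed(54)
  d$covariates <- data.frame(age = sample(16:24, 1500, replace = TRUE))
  base <- estimate_network(d)
  adj <- covariate_adjusted_network(d, "age")
  expect_identical(adj$nodes, base$nodes)
  sim <- network_similarity(base, adj)
  expect_gte(sim$r, 0.95)
  expect_error(covariate_adjusted_network(d, "height"), "unknown covariate")
  d$covariates$flat <- 1
  expect_error(covariate_adjusted_network(d, "flat"), "constant")
})

test_that("conditioning on a duplicated symptom shrinks its edges", {
  # 3 latent symptoms with one strong edge; covariate duplicates symptom 1
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.4
  truth <- symptomnet:::rebuild_from_target(w, 3, NA)
  set.seed(61)
  z <- MASS::mvrnorm(3000, rep(0, 3), truth$correlation)
  vals <- z
  colnames(vals) <- c("s1", "s2", "s3")
  d <- item_dataset(vals, phq_items = character(0), iu_items = character(0))
  d$covariates <- data.frame(dup = z[, 1] + rnorm(3000, sd = 0.05))
  base <- estimate_network(d)
  adj <- covariate_adjusted_network(d, "dup")
  expect_lt(abs(adj$weights["s1", "s2"]), abs(base$weights["s1", "s2"]))
})

test_that("network similarity: self, sign flip, three-edge hand case", {
  d <- toy_dataset(400, seed = 71)
  net <- estimate_network(d)
  expect_equal(network_similarity(net, net)$r, 1)
  neg <- net
  neg$weights <- -net$weights
  expect_equal(network_similarity(net, neg)$r, -1)

  a <- symptomnet:::new_network_model(c("x", "y", "z"),
    matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3), 0.1, 0.5, 0, 100)
  b <- symptomnet:::new_network_model(c("x", "y", "z"),
    matrix(c(0, .3, .1, .3, 0, .2, .1, .2, 0), 3), 0.1, 0.5, 0, 100)
  expect_equal(network_similarity(a, b)$r,
               cor(c(.1, .2, .3), c(.3, .1, .2)), tolerance = 1e-12)

  flat <- a
  flat$weights[] <- 0
  expect_warning(s <- network_similarity(a, flat), "undefined")
  expect_false(s$defined)
})
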