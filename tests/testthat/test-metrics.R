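star_net <- function(wt = 0.5) {
  w <- matrix(0, 5, 5)
  w[1, 2:5] <- wt; w[2:5, 1] <- wt
  symptomnet:::new_network_model(paste0("n", 1:5), w, 0.1, 0.5, 0, 500)
}

test_that("star network: strengths, center betweenness, closeness", {
  net <- star_net()
  ct <- centrality_table(net)
  expect_equal(ct$strength, c(2, rep(0.5, 4)))
  expect_equal(ct$expected_influence, ct$strength)   # all-positive net
  # every one of the C(4,2) = 6 leaf pairs routes through the center
  expect_equal(ct$betweenness, c(6, 0, 0, 0, 0))
  # center: 4 neighbors at distance 2; leaves: one at 2, three at 4
  expect_equal(ct$closeness, c(4 * 1 / 2, rep(1 / 2 + 3 * 1 / 4, 4)))
  expect_equal(mean(ct$z_strength), 0)
  expect_equal(sd(ct$z_strength), 1)
})

test_that("strength and EI disagree exactly by negative edges", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.3
  w[1, 3] <- w[3, 1] <- -0.2
  net <- symptomnet:::new_network_model(c("a", "b", "c"), w, .1, .5, 0, 100)
  ct <- centrality_table(net)
  expect_equal(ct$strength[1], 0.5)
  expect_equal(ct$expected_influence[1], 0.1)
  expect_true(all(ct$strength >= abs(ct$expected_influence)))
})

test_that("betweenness and closeness match exhaustive enumeration", {
  set.seed(17)
  for (k in 1:8) {
    p <- sample(4:6, 1)
    w <- matrix(0, p, p)
    ut <- upper.tri(w)
    vals <- ifelse(runif(sum(ut)) < 0.5, 0,
                   runif(sum(ut), 0.1, 0.9) * sign(runif(sum(ut)) - 0.3))
    w[ut] <- vals
    w <- w + t(w)
    net <- symptomnet:::new_network_model(paste0("v", 1:p), w, .1, .5, 0, 100)
    ct <- centrality_table(net)
    expect_equal(ct$betweenness, betweenness_bf(w), tolerance = 1e-9)
    expect_equal(ct$closeness, closeness_bf(w), tolerance = 1e-9)
  }
})

test_that("global strength sums the upper triangle and halves node strength", {
  empty <- symptomnet:::new_network_model(c("a", "b", "c"),
                                          matrix(0, 3, 3), .1, .5, 0, 100)
  expect_equal(global_strength(empty), 0)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.3
  w[1, 3] <- w[3, 1] <- -0.2
  net <- symptomnet:::new_network_model(c("a", "b", "c"), w, .1, .5, 0, 100)
  expect_equal(global_strength(net), 0.5)
  d <- toy_dataset(300, seed = 91)
  net2 <- estimate_network(d)
  ct <- centrality_table(net2)
  expect_equal(global_strength(net2), sum(ct$strength) / 2)
})

test_that("predictability: null item, exact copy, variance decomposition", {
  set.seed(23)
  n <- 5000
  x <- rnorm(n)
  vals <- cbind(x = x,
                copy = x,
                yhalf = 0.5 * x + rnorm(n, sd = 0.5 * sd(x)),
                indep = rnorm(n))
  d <- item_dataset(vals, phq_items = character(0), iu_items = character(0))
  suppressWarnings(r2 <- predictability(d))
  expect_equal(unname(r2["copy"]), 1, tolerance = 1e-10)
  expect_lt(unname(predictability(d, c("indep", "yhalf", "x"))["indep"]),
            0.01)
  # y = 0.5 x + e with sd(e) = 0.5 sd(x): R2 = 0.25/(0.25+0.25) = 0.5
  r2y <- predictability(d, c("yhalf", "x"))["yhalf"]
  expect_equal(unname(r2y), 0.5, tolerance = 0.03)
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("centrality table can attach predictability", {
  d <- toy_dataset(400, seed = 95)
  net <- estimate_network(d)
  ct <- centrality_table(net, data = d)
  expect_true("predictability" %in% names(ct))
  expect_true(all(ct$predictability >= 0 & ct$predictability <= 1))
})

test_that("flow decomposition: forced layers and full connectivity", {
  # F-A, A-B edges; C isolated
  w <- matrix(0, 4, 4, dimnames = rep(list(c("F", "A", "B", "C")), 2))
  w["F", "A"] <- w["A", "F"] <- 0.4
  w["A", "B"] <- w["B", "A"] <- 0.3
  net <- symptomnet:::new_network_model(colnames(w), w, .1, .5, 0, 100)
  fd <- flow_decompose(net, "F")
  expect_equal(fd$direct, "A")
  expect_equal(fd$indirect_layers, list("B"))
  expect_equal(fd$unreached, "C")
  expect_equal(fd$edges_to_focal$node, "A")

  full <- matrix(0.2, 4, 4, dimnames = rep(list(c("F", "A", "B", "C")), 2))
  diag(full) <- 0
  netf <- symptomnet:::new_network_model(colnames(full), full, .1, .5, 0, 100)
  fdf <- flow_decompose(netf, "F")
  expect_setequal(fdf$direct, c("A", "B", "C"))
  expect_length(fdf$indirect_layers, 0)
  expect_error(flow_decompose(net, "Z"), "unknown focal")
})

test_that("flow layers agree with an independent BFS on random networks", {
  set.seed(29)
  for (k in 1:10) {
    p <- 10
    w <- matrix(0, p, p)
    ut <- upper.tri(w)
    vals <- ifelse(runif(sum(ut)) < 0.7, 0, runif(sum(ut), 0.1, 0.5))
    w[ut] <- vals
    w <- w + t(w)
    w[1, 2] <- w[2, 1] <- 0   # force a zeroed focal edge
    nodes <- paste0("v", 1:p)
    dimnames(w) <- list(nodes, nodes)
    net <- symptomnet:::new_network_model(nodes, w, .1, .5, 0, 100)
    fd <- flow_decompose(net, "v1")
    dist <- flow_layers_bf(w, 1)
    expect_setequal(fd$direct, nodes[which(dist == 1)])
    expect_setequal(fd$unreached, nodes[which(!is.finite(dist))])
    for (l in seq_along(fd$indirect_layers))
      expect_setequal(fd$indirect_layers[[l]], nodes[which(dist == l + 1)])
    # direct set is exactly the nonzero-edge neighborhood
    expect_setequal(fd$direct, nodes[which(w[1, ] != 0)])
  }
})
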