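random_weight_matrix <- function(n, seed = 1, density = 0.3) {
  withr::with_seed(seed, {
    pairs <- edge_pairs(n)
    w <- ifelse(runif(nrow(pairs)) < density, runif(nrow(pairs)), 0)
  })
  m <- matrix(0, n, n, dimnames = list(sprintf("r%02d", 1:n),
                                       sprintf("r%02d", 1:n)))
  m[edge_pairs(n)] <- w
  m + t(m)
}

test_that("node strength sums each region's weighted connections", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.5
  ns <- node_strength(m)
  expect_equal(ns$strength, c(0.5, 0.5, 0, 0))
  expect_equal(node_strength(matrix(0, 3, 3))$strength, rep(0, 3))

  m20 <- random_weight_matrix(20, seed = 91)
  ns20 <- node_strength(m20)
  # brute-force row-sum oracle
  oracle <- vapply(1:20, function(i) {
    s <- 0
    for (j in 1:20) if (j != i) s <- s + m20[i, j]
    s
  }, numeric(1))
  expect_equal(ns20$strength, oracle, tolerance = 1e-12)
  # handshake identity: total strength = 2 x total edge weight
  expect_equal(sum(ns20$strength), 2 * sum(m20[edge_pairs(20)]),
               tolerance = 1e-12)

  bad <- m20; bad[1, 2] <- bad[1, 2] + 1
  expect_error(node_strength(bad), "symmetric")
})

test_that("network-block aggregation matches a brute-force double loop", {
  labels2 <- data.frame(region_id = 0:3, region_name = paste0("r", 1:4),
                        network_name = c("A", "A", "B", "B"))
  m <- matrix(0, 4, 4)
  m[1, 3] <- m[3, 1] <- 0.7  # one cross-network edge
  blk <- aggregate_by_network(m, labels2)
  expect_equal(blk["A", "B"], 0.7)
  expect_equal(blk["A", "A"], 0)

  one_net <- data.frame(region_id = 0:3, region_name = paste0("r", 1:4),
                        network_name = "A")
  m2 <- random_weight_matrix(4, seed = 92, density = 1)
  expect_equal(aggregate_by_network(m2, one_net)[1, 1],
               sum(m2[edge_pairs(4)]))

  n <- 21
  m7 <- random_weight_matrix(n, seed = 93)
  labels7 <- data.frame(region_id = 0:(n - 1),
                        region_name = sprintf("r%02d", 1:n),
                        network_name = rep(paste0("net", 1:7), each = 3))
  blk7 <- aggregate_by_network(m7, labels7)
  oracle <- matrix(0, 7, 7, dimnames = dimnames(blk7))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- labels7$network_name[i]; b <- labels7$network_name[j]
    oracle[a, b] <- oracle[a, b] + m7[i, j]
    if (a != b) oracle[b, a] <- oracle[b, a] + m7[i, j]
  }
  expect_equal(blk7, oracle, tolerance = 1e-12)
  # normalization divides by the possible edge count per block
  blk7n <- aggregate_by_network(m7, labels7, normalize = TRUE)
  expect_equal(blk7n["net1", "net2"], oracle["net1", "net2"] / 9)
  expect_equal(blk7n["net1", "net1"], oracle["net1", "net1"] / 3)

  expect_error(aggregate_by_network(m7, labels7[-3, ]), "unlabeled")
})

test_that("top-edge extraction is deterministic with index tie-breaks", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.5
  m[3, 4] <- m[4, 3] <- 0.5
  m[1, 3] <- m[3, 1] <- 0.2
  te <- top_edges(m, 1.0)
  expect_equal(nrow(te), 6L)
  expect_true(all(diff(te$weight) <= 0))
  # the two tied maxima come first, in canonical index order
  expect_equal(te$edge_id[1:2], sort(c(edge_id(1, 2, 4), edge_id(3, 4, 4))))

  # fraction arithmetic at atlas scale: 0.15% of 35,778 edges is 54
  expect_equal(ceiling(0.0015 * nrow(edge_pairs(268))), 54)
  big <- matrix(0, 268, 268)
  big[1, 2] <- big[2, 1] <- 1
  expect_equal(nrow(top_edges(big, 0.0015)), 54L)
})

test_that("node strength and block aggregation are linear in the weights", {
  a <- random_weight_matrix(10, seed = 94)
  b <- random_weight_matrix(10, seed = 95)
  expect_equal(node_strength(a + b)$strength,
               node_strength(a)$strength + node_strength(b)$strength,
               tolerance = 1e-12)
  labs <- data.frame(region_id = 0:9, region_name = sprintf("r%02d", 1:10),
                     network_name = rep(c("X", "Y"), 5))
  expect_equal(aggregate_by_network(a + b, labs),
               aggregate_by_network(a, labs) + aggregate_by_network(b, labs),
               tolerance = 1e-12)
})
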