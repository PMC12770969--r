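test_that("fixed in-degree networks have exact row sums for every seed", {
  net <- fixed_in_degree_network(100, 4, seed = 1)
  expect_equal(rowSums(net$adjacency), rep(4, 100))
  expect_equal(sum(net$adjacency), 400)
  expect_equal(sum(fixed_in_degree_network(10, 0, seed = 1)$adjacency), 0)
  full <- fixed_in_degree_network(5, 4, seed = 2)
  expect_equal(sum(full$adjacency), 20)
  expect_equal(full$adjacency, 1 - diag(5))
  ## property over many seeds, plus determinism
  for (s in 1:100) {
    n <- fixed_in_degree_network(12, 3, seed = s)
    expect_equal(rowSums(n$adjacency), rep(3, 12))
    expect_equal(diag(n$adjacency), rep(0, 12))
  }
  expect_identical(fixed_in_degree_network(30, 4, seed = 5),
                   fixed_in_degree_network(30, 4, seed = 5))
  expect_error(fixed_in_degree_network(10, 10, seed = 1), "d_in")
})

test_that("standard topologies have the expected degree structure", {
  ## ER: expected directed edge count n (n-1) p = 400
  edges <- vapply(1:40, function(s)
    sum(standard_topology("ER", 100, list(mean_in_degree = 4),
                          seed = s)$adjacency), 0)
  expect_lt(abs(mean(edges) - 400), 15)
  ## WS without rewiring: regular ring, every in-degree = ring_k
  ws <- standard_topology("WS", 100, list(ring_k = 4, p_rewire = 0),
                          seed = 1)
  expect_equal(rowSums(ws$adjacency), rep(4, 100))
  ## BA: heavy-tailed total degree
  for (s in 1:5) {
    ba <- standard_topology("BA", 100, list(m = 2), seed = s)
    deg <- rowSums(ba$adjacency) + colSums(ba$adjacency)
    expect_gte(max(deg) / mean(deg), 3)
  }
  expect_error(standard_topology("XX", 10, list(), seed = 1))
})

test_that("hub nodes reach the requested out-degree", {
  net <- small_world_hub_network(300, 4, 0.1, 5, 60, seed = 2)
  expect_equal(sum(colSums(net$adjacency) >= 60), 5)
  plain <- small_world_hub_network(50, 4, 0.1, 0, 0, seed = 3)
  expect_true(all(plain$adjacency %in% c(0, 1)))
  expect_equal(diag(plain$adjacency), rep(0, 50))
  expect_error(small_world_hub_network(20, 4, 0.1, 2, 25, seed = 1))
})

test_that("weight assignment respects the law and the edge set", {
  net <- fixed_in_degree_network(30, 4, seed = 1)
  u <- assign_weights(net, "uniform", 0.02, 0.04, seed = 2)
  on_edges <- u$weights[u$adjacency == 1]
  expect_true(all(on_edges >= 0.02 & on_edges <= 0.04))
  expect_true(all(u$weights[u$adjacency == 0] == 0))
  k <- assign_weights(net, "constant", 0.1)
  expect_true(all(k$weights[k$adjacency == 1] == 0.1))
  empty <- assign_weights(fixed_in_degree_network(10, 0, seed = 1),
                          "uniform", 0.1, 0.2, seed = 1)
  expect_equal(sum(empty$weights), 0)
  expect_error(assign_weights(net, "uniform", -1, 2), "lo")
})

test_that("hiding nodes restricts the truth to the observed sub-network", {
  net <- assign_weights(fixed_in_degree_network(100, 4, seed = 4),
                        "uniform", 1, 2, seed = 5)
  all_obs <- hide_nodes(net, 0, seed = 1)
  expect_identical(all_obs$observed_ids, 1:100)
  expect_identical(all_obs$sub_truth$adjacency, net$adjacency)
  half <- hide_nodes(net, 0.5, seed = 2)
  expect_length(half$observed_ids, 50)
  keep <- half$observed_ids
  expect_identical(half$sub_truth$adjacency, net$adjacency[keep, keep])
  expect_identical(half$sub_truth$weights, net$weights[keep, keep])
  expect_error(hide_nodes(net, 0.995, seed = 1), "observed")
})

test_that("node relabelling permutes adjacency and weights consistently", {
  net <- assign_weights(fixed_in_degree_network(15, 3, seed = 6),
                        "uniform", 1, 5, seed = 7)
  perm <- with_seed(8, sample(15))
  p <- permute_network(net, perm)
  for (i in 1:15) for (j in 1:15) {
    expect_identical(p$adjacency[perm[i], perm[j]], net$adjacency[i, j])
    expect_identical(p$weights[perm[i], perm[j]], net$weights[i, j])
  }
})

test_that("edge-list files round-trip exactly", {
  net <- assign_weights(fixed_in_degree_network(25, 3, seed = 9),
                        "uniform", 0.001, 0.999, seed = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "source\ttarget\tweight")
  back <- read_edge_list(path, 25)
  expect_identical(back$adjacency, net$adjacency)
  expect_equal(back$weights, net$weights, tolerance = 0)
})

test_that("dense matrix files round-trip weights and edges", {
  net <- assign_weights(fixed_in_degree_network(12, 3, seed = 13),
                        "uniform", 0.5, 1.5, seed = 14)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network_matrix(net, path)
  back <- read_network_matrix(path)
  expect_identical(back$adjacency, net$adjacency)
  expect_equal(back$weights, net$weights, tolerance = 0)
})

test_that("invalid networks are rejected", {
  expect_error(directed_network(matrix(1, 3, 3)), "diagonal")
  adj <- matrix(0, 3, 3); adj[1, 2] <- 1
  w <- adj; w[2, 1] <- 0.5
  expect_error(directed_network(adj, w), "non-edge")
  expect_error(directed_network(adj, adj * -1), "nonnegative")
})
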