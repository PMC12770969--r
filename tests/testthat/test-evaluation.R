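make_truth <- function(adj, w = NULL) directed_network(adj, w)

test_that("AUROC equals exhaustive pair counting", {
  ## 2 true edges scoring {0.9, 0.4}; non-edges {0.5, 0.1} (duplicated)
  adj <- matrix(0, 3, 3); adj[1, 2] <- 1; adj[2, 3] <- 1
  kh <- matrix(0, 3, 3)
  kh[1, 2] <- 0.9; kh[2, 3] <- 0.4
  kh[1, 3] <- 0.5; kh[2, 1] <- 0.1; kh[3, 1] <- 0.5; kh[3, 2] <- 0.1
  r <- auroc(kh, make_truth(adj))
  expect_equal(r$auroc, auroc_pairs(c(0.9, 0.4), c(0.5, 0.1, 0.5, 0.1)))
  expect_equal(r$auroc, 0.75)
  ## perfect separation and pure chance
  kh2 <- adj * 2 + 0.1
  diag(kh2) <- 0
  expect_equal(auroc(kh2, make_truth(adj))$auroc, 1)
  expect_equal(auroc(matrix(1, 3, 3) - diag(3),
                     make_truth(adj))$auroc, 0.5)
  expect_error(auroc(kh, make_truth(matrix(0, 3, 3))), "degenerate")
})

test_that("AUROC matches the rank-statistic oracle on tied fixtures", {
  for (case in 1:20) {
    n <- 8
    adj <- with_seed(case, {
      a <- matrix(stats::rbinom(n * n, 1, 0.3), n); diag(a) <- 0; a
    })
    if (sum(adj) == 0 || sum(adj) == n * (n - 1)) next
    kh <- with_seed(1000 + case, {
      k <- matrix(sample(seq(0, 1, 0.25), n * n, TRUE), n); diag(k) <- 0; k
    })
    off <- row(adj) != col(adj)
    r <- auroc(kh, make_truth(adj))
    expect_equal(r$auroc,
                 auroc_pairs(kh[off][adj[off] == 1],
                             kh[off][adj[off] == 0]),
                 tolerance = 1e-12)
    ## area under the reported curve agrees with the rank statistic
    trap <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) +
                                 utils::tail(r$tpr, -1)) / 2)
    expect_equal(trap, r$auroc, tolerance = 1e-12)
    ## curve is monotone from (0,0) to (1,1)
    expect_true(!is.unsorted(r$fpr) && !is.unsorted(r$tpr))
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(utils::tail(r$fpr, 1), utils::tail(r$tpr, 1)), c(1, 1))
  }
})

test_that("AUROC is invariant under strictly increasing transforms", {
  n <- 10
  adj <- with_seed(21, {
    a <- matrix(stats::rbinom(n * n, 1, 0.2), n); diag(a) <- 0; a
  })
  kh <- with_seed(22, matrix(stats::runif(n * n), n))
  diag(kh) <- 0
  tr <- make_truth(adj)
  a1 <- auroc(kh, tr)$auroc
  kh2 <- exp(3 * kh); diag(kh2) <- 0
  expect_equal(auroc(kh2, tr)$auroc, a1, tolerance = 1e-12)
})

test_that("Otsu threshold separates bimodal scores and matches the scan oracle", {
  s1 <- c(rep(0, 8), rep(1, 2))
  e1 <- otsu_threshold(s1)
  expect_gt(e1, 0); expect_lt(e1, 1)
  expect_equal(sum(s1 > e1), 2)
  s2 <- c(1, 2, 3, 10, 11, 12)
  e2 <- otsu_threshold(s2)
  expect_gt(e2, 3); expect_lt(e2, 10)
  for (case in 1:15) {
    sc <- with_seed(case, c(stats::rnorm(40, 0, 0.3),
                            stats::rnorm(15, 3, 0.5)))
    expect_equal(otsu_threshold(sc), otsu_scan(sc), tolerance = 1e-12)
  }
  ## affine equivariance
  sc <- with_seed(33, stats::runif(100))
  expect_equal(otsu_threshold(2 * sc + 5), 2 * otsu_threshold(sc) + 5,
               tolerance = 1e-9)
  expect_error(otsu_threshold(rep(1, 5)), "constant")
})

test_that("weight recovery is exact for proportional estimates, null for noise", {
  net <- assign_weights(fixed_in_degree_network(40, 4, seed = 31),
                        "uniform", 1, 3, seed = 32)
  expect_equal(weight_recovery(net$weights * 2.7, net), 1)
  expect_equal(weight_recovery((net$weights * 2.7)^2, net, "sqrt"), 1)
  noise <- with_seed(33, matrix(stats::runif(1600), 40))
  diag(noise) <- 0
  expect_lt(weight_recovery(noise, net), 0.05)
  expect_error(weight_recovery(matrix(1, 40, 40) - diag(40), net), "variance")
})

test_that("the Kuramoto order parameter behaves at the synchrony extremes", {
  t <- seq(0, 20 * 2 * pi, length.out = 2000)
  sync <- trajectory_set(list(cbind(sin(t), sin(t), sin(t))), dt = 1)
  R <- kuramoto_order(sync)
  interior <- 100:1900
  expect_gt(mean(R[interior]), 0.999)
  anti <- trajectory_set(list(cbind(sin(t), -sin(t))), dt = 1)
  expect_lt(mean(kuramoto_order(anti)[interior]), 0.05)
  ## amplitude scaling of a node does not move its phase
  scaled <- trajectory_set(list(cbind(sin(t), 5 * sin(t), sin(t))), dt = 1)
  expect_equal(kuramoto_order(scaled)[interior], R[interior],
               tolerance = 1e-9)
})

test_that("samples_to_target scans the grid lazily and honours trivial cases", {
  sc <- default_scenario("rulkov", n_nodes = 25)
  sc$topology$n_edges <- 35L
  sc$simulation$n_steps <- 300L
  ## target 0: the first grid entry always passes
  out <- samples_to_target(sc, 0, grid = c(300, 600), n_seeds = 1)
  expect_equal(as.integer(out), 300L)
  expect_length(attr(out, "auroc"), 1)
  ## unreachable target: sentinel NA with the full profile attached
  expect_warning(
    miss <- samples_to_target(sc, 1.01, grid = c(300, 600), n_seeds = 1),
    "not reached")
  expect_true(is.na(miss))
  expect_length(attr(miss, "auroc"), 2)
  ## a realistic target on this easy scenario passes at the first entry
  hit <- samples_to_target(sc, 0.8, grid = c(300, 600), n_seeds = 2)
  expect_equal(as.integer(hit), 300L)
})
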