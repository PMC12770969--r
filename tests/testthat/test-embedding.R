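test_that("AMI of white noise is near zero at every lag", {
  x <- with_seed(1, stats::runif(1e5))
  am <- average_mutual_information(x, max_lag = 20)
  expect_true(all(am >= 0))
  expect_true(all(am < 0.02))
  ## shuffled surrogate of a structured signal hits the same bias floor
  y <- sin(2 * pi * (1:1e5) / 100)
  ys <- with_seed(2, sample(y))
  expect_true(all(average_mutual_information(ys, 20) < 0.02))
})

test_that("AMI at an exact period equals the histogram entropy", {
  x <- rep(c(0.1, 0.4, 0.6, 0.9), 2500)
  am <- average_mutual_information(x, max_lag = 8, n_bins = 8)
  ## I(X; X) = H(X); four equiprobable values
  expect_equal(am[4], log(4), tolerance = 1e-12)
  expect_equal(am[8], log(4), tolerance = 1e-12)
})

test_that("sinusoid AMI has its first minimum near the quarter period", {
  ## a noiseless sinusoid gives a singular joint histogram whose sampling
  ## wiggles produce spurious early minima; a realistically noisy one has
  ## the classic quarter-period minimum
  x <- sin(2 * pi * (0:9999) / 100) + with_seed(2, stats::rnorm(1e4, 0, 0.2))
  am <- average_mutual_information(x, max_lag = 40)
  tau <- select_delay(am)
  expect_gte(tau, 18); expect_lte(tau, 28)
  ## matches a brute-force scan for the first strict interior minimum
  brute <- NA
  for (l in 2:39) {
    if (am[l - 1] > am[l] && am[l] < am[l + 1]) { brute <- l; break }
  }
  expect_identical(tau, brute)
})

test_that("delay selection follows the minimum-then-decay rule", {
  expect_identical(select_delay(c(3, 2, 1, 2, 3)), 3L)
  ## monotone decay: fall back to the 1/e rule (first crossing at lag 8)
  am <- 0.85^(0:19)
  expect_identical(select_delay(am), 8L)
  expect_identical(which(am <= am[1] / exp(1))[1], 8L)
  expect_warning(out <- select_delay(c(5, 4, 3.9, 3.8)), "maximum lag")
  expect_identical(out, 4L)
})

test_that("delay selection is invariant to affine rescaling of the series", {
  x <- with_seed(3, cumsum(stats::rnorm(3000)))
  a1 <- average_mutual_information(x, 30)
  a2 <- average_mutual_information(5 * x - 2, 30)
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("delay vectors follow the newest-first layout and row count", {
  dv <- delay_vectors(0:9, tau = 2, k = 3)
  expect_equal(nrow(dv$rows), 6)
  expect_equal(dv$rows[1, ], c(4, 2, 0))
  expect_equal(dv$rows[6, ], c(9, 7, 5))
  expect_equal(dv$row_times, 5:10)
  ## k = 1 reproduces the series
  expect_equal(delay_vectors(0:9, 3, 1)$rows[, 1], 0:9)
  ## too-short segment contributes nothing
  expect_warning(empty <- delay_vectors(0:2, tau = 2, k = 3), "short")
  expect_equal(nrow(empty$rows), 0)
  ## row-count formula max(0, T - (k-1) tau) over random cases
  for (case in 1:50) {
    prm <- with_seed(100 + case,
                     c(T = sample(2:40, 1), tau = sample(1:5, 1),
                       k = sample(1:5, 1)))
    n_expect <- max(0, prm["T"] - (prm["k"] - 1) * prm["tau"])
    rows <- suppressWarnings(
      delay_vectors(seq_len(prm["T"]), prm["tau"], prm["k"]))$rows
    expect_equal(nrow(rows), as.integer(n_expect))
  }
})

test_that("delay vectors are shift equivariant within a segment", {
  x <- with_seed(4, stats::rnorm(60))
  full <- delay_vectors(x, 3, 3)$rows
  shifted <- delay_vectors(x[-1], 3, 3)$rows
  expect_equal(shifted[1:(nrow(full) - 1), ], full[-1, ])
})

test_that("per-node delays track each node's own time scale", {
  ## two noisy sinusoids with different periods: the slower node gets the
  ## longer delay, both in the quarter-period ballpark
  t <- 0:4999
  noise <- with_seed(6, matrix(stats::rnorm(10000, 0, 0.2), ncol = 2))
  segs <- list(cbind(sin(2 * pi * t / 100), sin(2 * pi * t / 60)) + noise)
  ts <- trajectory_set(segs, dt = 1)
  taus <- select_delays(ts, max_lag = 40)
  expect_gt(taus[1], taus[2])
  expect_gte(taus[1], 15); expect_lte(taus[1], 30)
  expect_gte(taus[2], 8); expect_lte(taus[2], 20)
})
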