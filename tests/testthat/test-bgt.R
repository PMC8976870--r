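test_that("striatum forward/value agree and start at zero", {
  p <- striatum(20, 10)
  s <- sdr(c(0, 5), 20)
  r <- sdr(c(1, 2), 10)
  fw <- striatum_forward(p, s)
  expect_equal(fw$d1, numeric(10))
  expect_equal(fw$d2, numeric(10))
  expect_equal(striatum_value(p, s, r), 0)
})

test_that("a TD update moves the pair value by exactly alpha * delta", {
  p <- striatum(20, 10, alpha = 0.1, gamma = 0.9)
  s <- sdr(c(0, 5), 20); r <- sdr(c(1, 2), 10)
  striatum_observe(p, s, r)
  delta <- td_learn(p, reward = 1, new_value_estimate = 0)
  expect_equal(delta, 1)
  expect_equal(striatum_value(p, s, r), 0.1)
  # D1 strengthened, D2 weakened on the eligibility cells only
  expect_equal(p$W1[1, 2], 0.1)
  expect_equal(p$W2[1, 2], -0.1)
  expect_equal(p$W1[2, 2], 0)
  # second update bootstraps from the learned value
  striatum_observe(p, s, r)
  delta2 <- td_learn(p, 1, 0)
  expect_equal(delta2, 1 - 0.1)
})

test_that("td_learn without an eligibility pair is a silent no-op", {
  p <- striatum(10, 5)
  expect_null(td_learn(p, 1, 0))
  expect_true(all(p$W1 == 0))
})

test_that("negative TD errors weaken the go pathway", {
  p <- striatum(10, 5, alpha = 0.5)
  s <- sdr(0, 10); r <- sdr(0, 5)
  striatum_observe(p, s, r)
  td_learn(p, -1, 0)
  expect_lt(striatum_value(p, s, r), 0)
  expect_lt(p$W1[1, 1], 0)
  expect_gt(p$W2[1, 1], 0)
})

test_that("priorities start balanced and shift toward the dominant signal", {
  pr <- priorities(ema_rate = 0.1)
  expect_equal(pr$pr_int + pr$pr_ext, 1)
  expect_equal(pr$pr_ext, 0.5)
  # stream of good rewards after an early minimum: extrinsic takes over
  update_priorities(pr, -0.5)
  for (i in 1:200) update_priorities(pr, 1)
  expect_gt(pr$pr_ext, 0.9)
  expect_equal(pr$pr_int + pr$pr_ext, 1)
  expect_equal(pr$eta, 1)  # extrinsic dominates -> eta reset
})

test_that("eta decays while the intrinsic pathway dominates", {
  pr <- priorities(ema_rate = 0.1, eta_decay = 0.9)
  # constant zero reward: avg == avg_min -> target 0 -> intrinsic dominates
  for (i in 1:10) update_priorities(pr, 0)
  expect_gt(pr$pr_int, pr$pr_ext)
  expect_lt(pr$eta, 1)
  expect_equal(pr$eta, 0.9^10)
})

test_that("combine_pathways is the eta-weighted convex blend", {
  pr <- priorities()
  pr$pr_int <- 0.3; pr$pr_ext <- 0.7; pr$eta <- 0.5
  d_int <- list(d1 = c(1, 0), d2 = c(0, 1))
  d_ext <- list(d1 = c(0, 2), d2 = c(2, 0))
  d <- combine_pathways(d_int, d_ext, pr)
  expect_equal(d$d1, 0.5 * c(1, 0) * 0.3 + c(0, 2) * 0.7)
  expect_equal(d$d2, 0.5 * c(0, 1) * 0.3 + c(2, 0) * 0.7)
  expect_error(combine_pathways(list(d1 = 1, d2 = 1), d_ext, pr), "mismatch")
})

test_that("gpi_select samples bits with the normalized d2-d1 probabilities", {
  set.seed(31)
  d1 <- c(1, 0, 0.5, 0.25)
  d2 <- c(0, 1, 0.5, 0.25)
  g <- (d2 - d1)
  p_true <- (g - min(g)) / (max(g) - min(g))
  n <- 20000
  counts <- numeric(4)
  for (i in 1:n) {
    g <- gpi_select(d1, d2)
    counts[g$active + 1L] <- counts[g$active + 1L] + 1
  }
  freq <- counts / n
  sig <- sqrt(p_true * (1 - p_true) / n)
  expect_equal(freq[1], 0)       # bit with minimal g never included
  expect_equal(freq[2], 1)       # bit with maximal g always included
  expect_lt(abs(freq[3] - p_true[3]), 3 * sig[3] + 1e-9)
  expect_lt(abs(freq[4] - p_true[4]), 3 * sig[4] + 1e-9)
  # degenerate case: all equal -> every bit has probability 0.5
  expect_true(all(abs(colMeans(t(replicate(2000,
    sdr_dense(gpi_select(c(1, 1), c(1, 1)))))) - 0.5) < 0.05))
})

test_that("thalamus_select frequencies match thalamus_probs", {
  set.seed(32)
  resp <- lapply(0:3, function(a) sdr((a * 5):(a * 5 + 4), 20))
  gpi <- sdr(c(0, 1, 7, 12, 19), 20)
  p <- thalamus_probs(resp, gpi, beta = 1.5)
  expect_equal(sum(p), 1)
  n <- 20000
  draws <- replicate(n, thalamus_select(resp, gpi, beta = 1.5))
  freq <- tabulate(draws, 4) / n
  sig <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < 3 * sig + 1e-9))
  # weights scale the scores
  p_w <- thalamus_probs(resp, gpi, weights = c(3, 1, 1, 1), beta = 1.5)
  expect_gt(p_w[1], p[1])
})

test_that("beta = 0 gives uniform selection probabilities", {
  resp <- lapply(0:2, function(a) sdr((a * 3):(a * 3 + 2), 9))
  p <- thalamus_probs(resp, sdr(0, 9), beta = 0)
  expect_equal(p, rep(1 / 3, 3))
})
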