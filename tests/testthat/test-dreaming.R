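test_that("action SDRs occupy disjoint muscle blocks", {
  dm <- dreaming_models(100, 5, 4, action_sparsity = 5, seed = 1)
  sdrs <- lapply(0:3, function(a) dm_action_sdr(dm, a))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(sdr_overlap(sdrs[[i]], sdrs[[j]]), 0L)
  expect_equal(sdrs[[1]]$active, 0:4)
})

test_that("anomaly starts maximal and falls as transitions are learned", {
  set.seed(2)
  dm <- dreaming_models(100, 5, 2, seed = 2)
  s1 <- random_sdr(100, 5); s2 <- random_sdr(100, 5)
  expect_equal(dm_anomaly(dm, 0, s2), 1)
  for (i in 1:30) dm_learn(dm, s1, 0, s2, 0.5)
  expect_lt(dm_anomaly(dm, 0, s2), 0.05)
  # the other action remains fully anomalous
  expect_equal(dm_anomaly(dm, 1, s2), 1)
  # reward readout converges to the EMA target
  expect_equal(dm_reward(dm, s2), 0.5, tolerance = 0.01)
})

test_that("the forward model predicts learned transitions", {
  set.seed(3)
  dm <- dreaming_models(100, 5, 2, seed = 3)
  s1 <- random_sdr(100, 5); s2 <- random_sdr(100, 5); s3 <- random_sdr(100, 5)
  for (i in 1:5) {
    dm_learn(dm, s1, 0, s2, 0)
    dm_learn(dm, s1, 1, s3, 0)
  }
  expect_true(dm_predict(dm, s1, 0) == s2)
  expect_true(dm_predict(dm, s1, 1) == s3)
  expect_equal(sdr_size(dm_predict(dm, s2, 1)), 0L)
})

test_that("switch probability follows (1-an)^alpha * p_max with a hard gate", {
  cfg <- dreaming_config(p_max = 0.12, alpha_exp = 2,
                         hard_anomaly_threshold = 0.6)
  set.seed(4)
  n <- 50000
  hits <- sum(replicate(n, dm_switch(0, cfg)))
  p <- 0.12
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
  # above the hard threshold dreaming is impossible
  expect_false(any(replicate(500, dm_switch(0.7, cfg))))
  # intermediate anomaly scales the probability
  hits2 <- sum(replicate(n, dm_switch(0.5, cfg)))
  p2 <- (1 - 0.5)^2 * 0.12
  expect_lt(abs(hits2 / n - p2), 3 * sqrt(p2 * (1 - p2) / n))
})

test_that("td_error mode scales with the TD error inside the band", {
  cfg <- dreaming_config(mode = "td_error", p_max = 0.2, td_scale = 0.5,
                         td_max = 1)
  set.seed(5)
  expect_false(any(replicate(200, dm_switch(0, cfg, td_error = 0))))
  expect_false(any(replicate(200, dm_switch(0, cfg, td_error = 2))))
  n <- 20000
  hits <- sum(replicate(n, dm_switch(0, cfg, td_error = 0.25)))
  p <- 0.2 * 0.5
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("rollouts on a learned corridor replay the true state sequence", {
  set.seed(6)
  corr <- parse_maze(c("11111"))
  fc <- maze_floor_cells(corr)
  codes <- maze_codes(corr, k = 200, m = 8, seed = 7)
  dm <- dreaming_models(200, 8, 4, seed = 8)
  for (rep in 1:10) for (i in seq_len(nrow(fc))) for (a in 0:3) {
    p <- fc[i, ]
    dm_learn(dm, code_of(codes, p), a, code_of(codes, maze_move(corr, p, a)),
             -0.02)
  }
  seen <- list()
  policy <- function(s, r) { seen[[length(seen) + 1L]] <<- s; 3L }
  cfg <- dreaming_config(max_rollout_steps = 4)
  steps <- dm_rollout(dm, code_of(codes, c(0, 0)), 0, policy, cfg)
  expect_equal(steps, 4L)
  truth <- lapply(0:4, function(cc) code_of(codes, c(0, cc)))
  for (i in seq_along(seen)) expect_true(seen[[i]] == truth[[i]])
})

test_that("dreaming never touches the environment", {
  set.seed(7)
  corr <- parse_maze(c("11111"))
  env <- grid_env(corr, goal = c(0, 4), time_limit = 20)
  env_reset(env, pos = c(0, 1))
  snapshot <- list(pos = env$pos, steps = env$steps, done = env$done)
  codes <- maze_codes(corr, k = 200, m = 8, seed = 9)
  dm <- dreaming_models(200, 8, 4, seed = 10)
  fc <- maze_floor_cells(corr)
  for (rep in 1:5) for (i in seq_len(nrow(fc))) for (a in 0:3) {
    p <- fc[i, ]
    dm_learn(dm, code_of(codes, p), a, code_of(codes, maze_move(corr, p, a)),
             0)
  }
  res <- dm_dream(dm, code_of(codes, c(0, 1)), 0,
                  function(s, r) sample(0:3, 1), dreaming_config())
  expect_gte(res$rollouts, 1L)
  expect_identical(env$pos, snapshot$pos)
  expect_identical(env$steps, snapshot$steps)
  expect_identical(env$done, snapshot$done)
})

test_that("rollouts stop at anomalous or unknown transitions", {
  set.seed(8)
  dm <- dreaming_models(100, 5, 2, seed = 11)
  s1 <- random_sdr(100, 5); s2 <- random_sdr(100, 5)
  for (i in 1:20) dm_learn(dm, s1, 0, s2, 0)
  # action 0 known from s1, but nothing known from s2: rollout length 1
  cfg <- dreaming_config(max_rollout_steps = 10)
  steps <- dm_rollout(dm, s1, 0, function(s, r) 0L, cfg)
  expect_equal(steps, 1L)
  # with a high-anomaly destination the rollout refuses the step
  dm$an[1, s2$active + 1L] <- 1
  expect_equal(dm_rollout(dm, s1, 0, function(s, r) 0L, cfg), 0L)
})
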