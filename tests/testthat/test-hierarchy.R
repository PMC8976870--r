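test_that("gate_up opens only on simultaneous anomaly and confidence", {
  p <- sdr(0:4, 50)
  mk <- function(an, co) structure(list(anomaly = an, confidence = co),
                                   class = "tm_step")
  expect_null(gate_up(mk(0.9, 0.2), p))
  expect_null(gate_up(mk(0.2, 0.9), p))
  expect_true(gate_up(mk(0.9, 0.9), p) == p)
  expect_true(gate_up(mk(0.7, 0.7), p) == p)
})

test_that("feedback from the upper level resolves a stalled lower prediction", {
  # two 3-step sequences Aa Ab Ac and Ba Bb Bc. The lower memory learns each
  # sub-sequence in isolation (context reset in between), the upper memory
  # learns the abstract order of their start patterns. When the joined
  # sequence is replayed, the lower memory stalls after Ac (confidence 0);
  # the upper prediction names B's start pattern, and injecting it apically
  # restores a nonzero confidence pointing at Ba.
  v <- disjoint_sdrs(6, 4, 120)
  lower <- temporal_memory(120, 4, apical_enabled = TRUE, apical_space = 120,
                           apical_threshold = 3, seed = 1)
  upper <- temporal_memory(120, 4, seed = 2)
  registry <- list(list(abs = v[[1]], start = v[[1]]),
                   list(abs = v[[4]], start = v[[4]]))
  for (r in 1:6) {
    tm_reset(upper)
    tm_compute(upper, v[[1]]); tm_compute(upper, v[[4]])
    for (seq_v in list(v[1:3], v[4:6])) {
      tm_reset(lower)
      for (p in seq_v) tm_compute(lower, p)
    }
  }
  # joint pass with feedback: at the boundary the apical wiring fb -> Ba grows
  for (r in 1:2) {
    tm_reset(lower); tm_reset(upper)
    for (p in c(v[1:3], v[4:6])) {
      out <- tm_compute(lower, p)
      g <- gate_up(out, p)
      if (!is.null(g)) tm_compute(upper, g)
      fb <- feedback_resolve(out, upper, registry)
      if (!is.null(fb)) {
        expect_true(fb == v[[4]]) # the upper level names B's start pattern
        tm_apical_boost(lower, fb)
      }
    }
  }
  # frozen replay of the joined sequence
  tm_reset(lower); tm_reset(upper)
  confs <- numeric(0)
  for (p in c(v[1:3], v[4])) {
    out <- tm_compute(lower, p, learn = FALSE)
    conf <- out$confidence
    g <- gate_up(out, p)
    if (!is.null(g)) tm_compute(upper, g, learn = FALSE)
    fb <- feedback_resolve(out, upper, registry)
    if (!is.null(fb)) conf <- tm_apical_boost(lower, fb)
    confs <- c(confs, conf)
  }
  expect_gt(confs[3], 0)   # boundary confidence restored by feedback
  expect_true(all(v[[4]]$active %in% lower$pred_cols) || confs[4] > 0)
  expect_equal(confs[4], 1) # Ba arrives predicted; Bb is then predicted
})

test_that("baseline construction contains no level-2 or intrinsic components", {
  ag <- hierarchical_agent(50, 4, level2 = FALSE, empowerment_mode = "off",
                           dreaming = FALSE, seed = 1)
  expect_false(ag$level2)
  expect_null(ag$b3_sp)
  expect_null(ag$b4_pm)
  expect_null(ag$b2_int)
  expect_null(ag$dm)
  expect_null(ag$em)
})

test_that("agent_act returns valid actions and NA on done", {
  set.seed(3)
  m <- four_corridors_maze()
  env <- grid_env(m, goal = c(4, 4), time_limit = 15)
  obs <- env_reset(env, pos = c(0, 4))
  ag <- hierarchical_agent(length(obs), 4, seed = 4)
  a <- agent_act(ag, obs, 0, pos = env$pos)
  for (t in 1:14) {
    expect_true(a %in% 0:3)
    st <- env_step(env, a)
    a <- agent_act(ag, st$obs, st$reward, done = st$done, pos = st$pos)
    if (st$done) break
  }
  if (st$done) {
    expect_true(is.na(a))
    expect_null(ag$prev_state) # episode context cleared
  }
})

test_that("a single motor response is always selected", {
  set.seed(5)
  ag <- hierarchical_agent(30, 1, level2 = FALSE, seed = 6)
  obs <- as.integer(runif(30) < 0.2)
  for (t in 1:10) expect_equal(agent_act(ag, obs, 0), 0L)
})

test_that("same seed and flags give identical action streams", {
  m <- four_corridors_maze()
  run <- function() {
    set.seed(77)
    env <- grid_env(m, goal = c(4, 4), time_limit = 30)
    obs <- env_reset(env)
    ag <- hierarchical_agent(length(obs), 4, level2 = TRUE, seed = 9)
    acts <- integer(0)
    a <- agent_act(ag, obs, 0, pos = env$pos)
    for (t in 1:29) {
      acts <- c(acts, a)
      st <- env_step(env, a)
      a <- agent_act(ag, st$obs, st$reward, done = st$done, pos = st$pos)
      if (st$done) break
    }
    acts
  }
  expect_identical(run(), run())
})

test_that("intrinsic modes produce the documented reward signals", {
  set.seed(10)
  m <- four_corridors_maze()
  fn <- make_ideal_empowerment_fn(m, n = 2)
  obs <- obs_vector(m, c(4, 4))
  ag <- hierarchical_agent(length(obs), 4, level2 = FALSE,
                           empowerment_mode = "ideal_pos", intrinsic_fn = fn,
                           em_depth = 2, seed = 11)
  expect_false(is.null(ag$b2_int))
  expect_false(is.null(ag$pr))
  r <- htmagent:::agent_intrinsic(ag, random_sdr(150, 10), 0.5, c(4, 4))
  expect_equal(r, fn(c(4, 4)) / 4)
  ag$empowerment_mode <- "anomaly_neg"
  expect_equal(htmagent:::agent_intrinsic(ag, random_sdr(150, 10), 0.3, NULL),
               0.3 - 1)
  ag$empowerment_mode <- "zero"
  expect_equal(htmagent:::agent_intrinsic(ag, random_sdr(150, 10), 0.3, NULL),
               0)
})

test_that("option statistics normalize initiations and terminations", {
  tr <- htmagent:::new_option_trace()
  tr$I <- htmagent:::trace_count(tr$I, 1L, c(0, 0))
  tr$I <- htmagent:::trace_count(tr$I, 1L, c(0, 0))
  tr$I <- htmagent:::trace_count(tr$I, 1L, c(2, 3))
  tr$beta <- htmagent:::trace_count(tr$beta, 1L, c(4, 4))
  for (i in 1:10) tr$heat <- htmagent:::trace_count(tr$heat, 1L, c(1, 1))
  st <- option_stats(tr)
  expect_named(st, "1")
  expect_equal(sum(st[["1"]]$I$value), 1)
  expect_equal(st[["1"]]$I$value[st[["1"]]$I$row == 0], 2 / 3)
  expect_equal(sum(st[["1"]]$beta$value), 1)
  expect_equal(st[["1"]]$heat$value, 10)
  expect_equal(option_stats(htmagent:::new_option_trace()), list())
})

test_that("the motor hierarchy learns action sequences while acting", {
  set.seed(12)
  m <- four_corridors_maze()
  env <- grid_env(m, goal = c(4, 4), time_limit = 30)
  ag <- hierarchical_agent(length(env_reset(env)), 4, level2 = TRUE,
                           seed = 13)
  for (ep in 1:15) {
    obs <- env_reset(env, pos = c(0, 4))
    a <- agent_act(ag, obs, 0, pos = env$pos)
    repeat {
      st <- env_step(env, a)
      a <- agent_act(ag, st$obs, st$reward, done = st$done, pos = st$pos)
      if (st$done) break
    }
  }
  expect_gt(ag$b2_tm$seg_n, 0L)     # motor transitions were learned
  expect_gt(ag$b1_tm$seg_n, 0L)     # visual transitions were learned
  st <- option_stats(ag$trace)      # option bookkeeping stays consistent
  for (o in st) {
    if (!is.null(o$I)) expect_equal(sum(o$I$value), 1)
    if (!is.null(o$beta)) expect_equal(sum(o$beta$value), 1)
  }
})
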