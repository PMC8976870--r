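test_that("parse_maze reads layout, spawns and goal", {
  m <- parse_maze(c("S12", "#G3"), legend = c(S = 1, G = 2))
  expect_equal(m$height, 2L)
  expect_equal(m$width, 3L)
  expect_true(m$obstacle[2, 1])
  expect_equal(m$color[1, ], c(1L, 1L, 2L))
  expect_equal(m$spawn, list(c(0L, 0L)))
  expect_equal(m$goal0, c(1L, 1L))
  expect_error(parse_maze(c("1", "22")), "equal length")
  expect_error(parse_maze("1x"), "unknown maze character")
})

test_that("moves into walls and borders leave the position unchanged", {
  m <- parse_maze(c("11", "1#"))
  expect_equal(maze_move(m, c(0, 0), 0), c(0, 0)) # border up
  expect_equal(maze_move(m, c(0, 0), 2), c(0, 0)) # border left
  expect_equal(maze_move(m, c(1, 0), 3), c(1, 0)) # wall right
  expect_equal(maze_move(m, c(0, 0), 1), c(1, 0)) # down ok
  expect_equal(maze_move(m, c(0, 1), 2), c(0, 0)) # left ok
})

test_that("observations have consistent channels", {
  m <- parse_maze(c("111", "121", "111"))
  obs <- render_obs(m, c(1, 1), radius = 1)
  expect_equal(dim(obs), c(3L, 3L, 4L)) # 2 colors + obstacle + resource
  # channels mutually exclusive per cell, each in-window cell marked once
  expect_true(all(apply(obs[, , 1:3], c(1, 2), sum) == 1))
  expect_equal(sum(obs[, , 4]), 0) # no goal passed
  obs_g <- render_obs(m, c(1, 1), radius = 1, goal = c(0, 0))
  expect_equal(obs_g[1, 1, 4], 1L)
  expect_equal(sum(obs_g[, , 4]), 1)
  # window fully inside uniform color-1 floor
  m1 <- parse_maze(rep("11111", 5))
  o1 <- render_obs(m1, c(2, 2), radius = 1)
  expect_true(all(o1[, , 1] == 1))
  expect_true(all(o1[, , 2:3] == 0))
  # border cells fall in the obstacle channel
  ob <- render_obs(m1, c(0, 0), radius = 1)
  expect_true(all(ob[1, , 2] == 1))
  expect_true(all(ob[, 1, 2] == 1))
})

test_that("env_step pays costs, rewards the goal, and terminates", {
  m <- parse_maze(c("1111"))
  env <- grid_env(m, goal = c(0, 3), cost = 0.02, time_limit = 10)
  env_reset(env, pos = c(0, 0))
  st <- env_step(env, 3)
  expect_equal(st$reward, -0.02)
  expect_false(st$done)
  st <- env_step(env, 3); st <- env_step(env, 3)
  expect_equal(st$reward, 0.98)
  expect_true(st$done)
  expect_true(st$reached_goal)
  expect_error(env_step(env, 3), "episode is over")
  # wall bump: position unchanged, cost still paid
  env_reset(env, pos = c(0, 0))
  st <- env_step(env, 0)
  expect_equal(st$pos, c(0L, 0L))
  expect_equal(st$reward, -0.02)
  expect_error(env_step(env, 7), "invalid action")
})

test_that("time limit ends episodes without goal reward", {
  m <- parse_maze(c("1111"))
  env <- grid_env(m, goal = c(0, 3), time_limit = 3)
  env_reset(env, pos = c(0, 0))
  st <- env_step(env, 2); st <- env_step(env, 2); st <- env_step(env, 2)
  expect_true(st$done)
  expect_false(st$reached_goal)
})

test_that("total episode reward never exceeds 1", {
  m <- four_corridors_maze()
  env <- grid_env(m, goal = c(4, 4), time_limit = 50)
  set.seed(3)
  for (rep in 1:5) {
    env_reset(env)
    tot <- 0
    repeat {
      st <- env_step(env, sample(0:3, 1))
      tot <- tot + st$reward
      if (st$done) break
    }
    expect_lte(tot, 1)
  }
})

test_that("built-in mazes have distinct observations at every floor cell", {
  for (m in list(four_rooms_maze(), four_corridors_maze())) {
    fc <- maze_floor_cells(m)
    keys <- apply(fc, 1, function(p) paste(obs_vector(m, p), collapse = ""))
    expect_equal(length(unique(keys)), nrow(fc))
  }
})

test_that("four-rooms landmarks have the expected structure", {
  m <- four_rooms_maze()
  lm <- maze_landmarks(m)
  expect_equal(nrow(lm$doorways), 4L)
  expect_equal(nrow(lm$deep_corners), 4L)
  expect_gte(nrow(lm$doorway_adjacent), 8L)
})

test_that("corridor protocol relocates the goal after each phase", {
  set.seed(5)
  pr <- protocol("four_corridors", episodes_per_phase = 3)
  g1 <- replicate(3, protocol_advance(pr)$goal)
  expect_true(all(g1 == c(4L, 4L)))
  e4 <- protocol_advance(pr)
  expect_false(all(e4$goal == c(4L, 4L)))
  mids <- list(c(2L, 4L), c(6L, 4L), c(4L, 2L), c(4L, 6L))
  expect_true(any(vapply(mids, function(p) all(p == e4$goal), logical(1))))
  e5 <- protocol_advance(pr); e6 <- protocol_advance(pr)
  expect_true(all(e6$goal == e4$goal))
  expect_true(isTRUE(protocol_advance(pr)$trial_done))
})

test_that("exhaustible protocol advances tasks and levels on visits", {
  set.seed(6)
  pr <- protocol("exhaustible_resource", levels = 2, tasks_per_level = 2,
                 visits_per_task = 2)
  e <- protocol_advance(pr)
  expect_equal(e$task, 1L); expect_equal(e$level, 1L)
  # two goal visits allowed; the third forces a new task
  protocol_advance(pr, goal_reached = TRUE)
  protocol_advance(pr, goal_reached = TRUE)
  e <- protocol_advance(pr, goal_reached = TRUE)
  expect_equal(e$task, 2L); expect_equal(e$level, 1L)
  for (i in 1:3) e <- protocol_advance(pr, goal_reached = TRUE)
  expect_equal(e$task, 3L); expect_equal(e$level, 2L)
  # level-1 goals are the spawn room's hallways
  pr2 <- protocol("exhaustible_resource")
  e2 <- protocol_advance(pr2)
  expect_true(all(e2$goal == c(4L, 2L)) || all(e2$goal == c(2L, 4L)))
  expect_error(protocol("exhaustible_resource", visits_per_task = 0),
               "positive")
})
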