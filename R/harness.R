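#' Experiment trial configuration
#'
#' Bundles a protocol, an agent variant and their parameters into a plain list
#' consumed by [run_trial()].
#'
#' @param protocol one of `"four_corridors"`, `"four_rooms_restricted"`,
#'   `"four_rooms_free"`, `"exhaustible_resource"`.
#' @param agent agent variant: `"baseline"` (one-level selector),
#'   `"two_level"` (hierarchical, no intrinsic drive, no dreaming),
#'   `"full"` (hierarchical + dual-pathway intrinsic empowerment + dreaming),
#'   `"td"` (basic distributed TD learner over pooled observations), or
#'   `"td_dreaming"` (the TD learner with the dreaming block).
#' @param episodes_per_phase,levels,tasks_per_level,visits_per_task schedule
#'   parameters (see [protocol()]).
#' @param time_limit step cap per episode.
#' @param max_episodes safety cap on total episodes per trial (the exhaustible
#'   schedule is open-ended when the agent never finds the goal).
#' @param window_radius observation window radius.
#' @param cost per-action energy cost.
#' @param empowerment_mode intrinsic mode for the `"full"` variant (see
#'   [hierarchical_agent()]); `ideal_*` modes get their lookup built from the
#'   protocol's maze automatically.
#' @param agent_params named list of extra arguments forwarded to the agent
#'   constructor.
#' @return A list of class `"trial_config"`.
#' @export
trial_config <- function(protocol = "four_corridors", agent = "baseline",
                         episodes_per_phase = 100, levels = 3,
                         tasks_per_level = 10, visits_per_task = 100,
                         time_limit = 200, max_episodes = 10000,
                         window_radius = 2, cost = 0.02,
                         empowerment_mode = "ideal_pos",
                         agent_params = list()) {
  structure(list(protocol = protocol, agent = agent,
                 episodes_per_phase = episodes_per_phase, levels = levels,
                 tasks_per_level = tasks_per_level,
                 visits_per_task = visits_per_task, time_limit = time_limit,
                 max_episodes = max_episodes,
                 window_radius = window_radius, cost = cost,
                 empowerment_mode = empowerment_mode,
                 agent_params = agent_params),
            class = "trial_config")
}

#' Read a trial configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [trial_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `"trial_config"` list.
#' @export
read_trial_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  vals <- yaml::read_yaml(path)
  known <- names(formals(trial_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  do.call(trial_config, vals)
}

# build the agent variant and return a step closure
# step(obs, reward, done, pos) -> action id or NA
harness_agent <- function(config, obs_size, maze, seed) {
  kind <- match.arg(config$agent, c("baseline", "two_level", "full", "td",
                                    "td_dreaming"))
  if (kind %in% c("baseline", "two_level", "full")) {
    args <- list(obs_size = obs_size, n_actions = 4L, seed = seed)
    if (kind == "baseline") {
      args$level2 <- FALSE
      args$empowerment_mode <- "off"
      args$dreaming <- FALSE
    } else if (kind == "two_level") {
      args$level2 <- TRUE
      args$empowerment_mode <- "off"
      args$dreaming <- FALSE
    } else {
      args$level2 <- TRUE
      args$empowerment_mode <- config$empowerment_mode
      if (args$empowerment_mode %in% c("ideal_pos", "ideal_neg"))
        args$intrinsic_fn <- make_ideal_empowerment_fn(maze, n = 4)
      args$dreaming <- TRUE
    }
    args[names(config$agent_params)] <- config$agent_params
    ag <- do.call(hierarchical_agent, args)
    return(list(object = ag,
                step = function(obs, reward, done, pos)
                  agent_act(ag, obs, reward, done = done, pos = pos)))
  }
  # TD variants: spatial pooler front end + distributed TD learner
  k_state <- 150L; m_state <- 10L
  sp <- spatial_pooler(obs_size, k_state, m_state, seed = seed)
  td_args <- list(k_state = k_state, n_actions = 4L)
  keep <- intersect(names(config$agent_params), names(formals(td_agent)))
  td_args[keep] <- config$agent_params[keep]
  ag <- do.call(td_agent, td_args)
  dm <- NULL; cfg <- NULL
  if (kind == "td_dreaming") {
    dm <- dreaming_models(k_state, m_state, 4L, seed = seed + 1L)
    cfg <- if (!is.null(config$agent_params$dream_config))
      config$agent_params$dream_config else dreaming_config()
  }
  prev <- new.env(parent = emptyenv())
  prev$s <- NULL; prev$a <- NULL
  step <- function(obs, reward, done, pos) {
    s <- sp_compute(sp, obs, learn = TRUE)
    a <- td_agent_step(ag, s, reward, done = done)
    if (!is.null(dm) && !is.null(prev$s) && !is.null(prev$a)) {
      dm_learn(dm, prev$s, prev$a, s, reward)
      if (!done && dm_switch(dm_anomaly(dm, prev$a, s), cfg,
                             td_error = ag$last_delta)) {
        real_s <- ag$prev_s; real_a <- ag$prev_a
        ag$prev_s <- NULL; ag$prev_a <- NULL
        dm_dream(dm, s, reward, function(si, ri) td_agent_step(ag, si, ri),
                 cfg)
        ag$prev_s <- real_s; ag$prev_a <- real_a
      }
    }
    if (done) { prev$s <- NULL; prev$a <- NULL } else {
      prev$s <- s; prev$a <- a
    }
    a
  }
  list(object = ag, dreaming = dm, step = step)
}

#' Run one trial (one agent, one protocol schedule, one seed)
#'
#' Seeds the RNG, builds the environment and the agent variant, and plays the
#' full protocol schedule episode by episode. Every interaction goes through
#' the observation window; positions are passed to the agent only for
#' bookkeeping/intrinsic lookup as documented in [agent_act()].
#'
#' @param config a [trial_config()].
#' @param seed integer RNG seed (< 2^31) controlling everything in the trial.
#' @return List with `episodes` (data frame: `episode`, `task`, `level`,
#'   `steps`, `reward`, `reached_goal`) and `agent` (the trained agent-variant
#'   bundle, for inspection).
#' @export
run_trial <- function(config, seed) {
  set.seed(as.integer(seed))
  proto <- protocol(config$protocol,
                    episodes_per_phase = config$episodes_per_phase,
                    levels = config$levels,
                    tasks_per_level = config$tasks_per_level,
                    visits_per_task = config$visits_per_task)
  maze <- proto$maze
  obs_size <- length(obs_vector(maze, maze_floor_cells(maze)[1L, ],
                                config$window_radius))
  bundle <- harness_agent(config, obs_size, maze, seed)
  rows <- list()
  goal_reached <- FALSE
  repeat {
    ep <- protocol_advance(proto, goal_reached)
    if (isTRUE(ep$trial_done) || length(rows) >= config$max_episodes) break
    env <- grid_env(maze, ep$goal, spawn_set = ep$spawn_set,
                    cost = config$cost, time_limit = config$time_limit,
                    window_radius = config$window_radius)
    obs <- env_reset(env)
    a <- bundle$step(obs, 0, FALSE, env$pos)
    total_r <- 0; steps <- 0L; st <- NULL
    repeat {
      st <- env_step(env, a)
      total_r <- total_r + st$reward
      steps <- steps + 1L
      a <- bundle$step(st$obs, st$reward, st$done, st$pos)
      if (st$done) break
    }
    goal_reached <- st$reached_goal
    rows[[length(rows) + 1L]] <-
      data.frame(episode = ep$episode, task = ep$task, level = ep$level,
                 steps = steps, reward = total_r,
                 reached_goal = goal_reached)
  }
  list(episodes = do.call(rbind, rows), agent = bundle)
}

#' Run a fixed single-goal task (no protocol schedule)
#'
#' Plays `episodes` episodes of one unchanging task: same maze, same goal,
#' spawns drawn from the given set. Used for the dreaming comparison, where
#' the quantity of interest is how fast one fixed task is mastered.
#'
#' @param config a [trial_config()] (only the agent settings, `time_limit`,
#'   `window_radius` and `cost` are used).
#' @param maze the maze to play on.
#' @param goal 0-based goal position.
#' @param episodes number of episodes.
#' @param seed RNG seed.
#' @param spawn_set list of start positions (default: the maze's `S` cells).
#' @return Data frame with `episode`, `steps`, `reward`, `reached_goal`.
#' @export
run_fixed_task <- function(config, maze, goal, episodes, seed,
                           spawn_set = NULL) {
  set.seed(as.integer(seed))
  obs_size <- length(obs_vector(maze, maze_floor_cells(maze)[1L, ],
                                config$window_radius))
  bundle <- harness_agent(config, obs_size, maze, seed)
  env <- grid_env(maze, goal, spawn_set = spawn_set, cost = config$cost,
                  time_limit = config$time_limit,
                  window_radius = config$window_radius)
  rows <- vector("list", episodes)
  for (e in seq_len(episodes)) {
    obs <- env_reset(env)
    a <- bundle$step(obs, 0, FALSE, env$pos)
    total_r <- 0; steps <- 0L; st <- NULL
    repeat {
      st <- env_step(env, a)
      total_r <- total_r + st$reward
      steps <- steps + 1L
      a <- bundle$step(st$obs, st$reward, st$done, st$pos)
      if (st$done) break
    }
    rows[[e]] <- data.frame(episode = e, steps = steps, reward = total_r,
                            reached_goal = st$reached_goal)
  }
  do.call(rbind, rows)
}

#' Aggregate episode records across trials
#'
#' Aligns per-trial episode tables by episode index and reports mean and
#' standard deviation of steps and reward at each index, with the trial count.
#'
#' @param trials list of [run_trial()] results (or of their `episodes` data
#'   frames).
#' @return Data frame: `episode`, `n`, `steps_mean`, `steps_sd`,
#'   `reward_mean`, `reward_sd`, `goal_rate`.
#' @export
aggregate_trials <- function(trials) {
  dfs <- lapply(trials, function(t) if (is.data.frame(t)) t else t$episodes)
  all <- do.call(rbind, dfs)
  eps <- sort(unique(all$episode))
  out <- lapply(eps, function(e) {
    d <- all[all$episode == e, , drop = FALSE]
    data.frame(episode = e, n = nrow(d),
               steps_mean = mean(d$steps),
               steps_sd = stats::sd(d$steps),
               reward_mean = mean(d$reward),
               reward_sd = stats::sd(d$reward),
               goal_rate = mean(d$reached_goal))
  })
  do.call(rbind, out)
}

#' Write episode metrics to CSV
#' @param df a data frame (e.g. from [aggregate_trials()]).
#' @param path output CSV path.
#' @export
write_metrics <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
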