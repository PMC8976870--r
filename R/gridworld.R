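#' Deterministic grid-world mazes
#'
#' A maze is a 2-D grid of cells, each either an obstacle or a floor of a given
#' color (a small positive integer). Everything outside the grid counts as
#' obstacle. Positions are 0-based `(row, col)` pairs with the origin at the
#' top-left; the four actions are `0 = up (-1,0)`, `1 = down (+1,0)`,
#' `2 = left (0,-1)`, `3 = right (0,+1)`.
#'
#' `parse_maze()` reads the ASCII fixture format: one character per cell,
#' `#` for obstacles, digits `1`-`9` for floor colors, and optionally `S`
#' (spawn-set cell) and `G` (initial goal) which are floors whose color is
#' given by `legend`.
#'
#' @param lines character vector of equal-length map rows.
#' @param legend named numeric vector giving the floor color of the special
#'   characters (default `c(S = 1, G = 1)`).
#' @return An object of class `"maze"`: list with `height`, `width`, `color`
#'   (integer matrix, 0 on obstacles), `obstacle` (logical matrix), `n_colors`,
#'   `spawn` (list of 0-based positions from `S` cells, possibly empty) and
#'   `goal0` (position of the `G` cell or `NULL`).
#' @export
parse_maze <- function(lines, legend = c(S = 1, G = 1)) {
  lines <- lines[nzchar(lines)]
  w <- unique(nchar(lines))
  if (length(w) != 1L) stop("maze rows must have equal length")
  h <- length(lines)
  chars <- do.call(rbind, strsplit(lines, ""))
  color <- matrix(0L, h, w)
  obstacle <- matrix(FALSE, h, w)
  spawn <- list(); goal0 <- NULL
  for (r in seq_len(h)) for (c in seq_len(w)) {
    ch <- chars[r, c]
    if (ch == "#") obstacle[r, c] <- TRUE
    else if (ch %in% as.character(1:9)) color[r, c] <- as.integer(ch)
    else if (ch %in% names(legend)) {
      color[r, c] <- as.integer(legend[[ch]])
      if (ch == "S") spawn[[length(spawn) + 1L]] <- c(r - 1L, c - 1L)
      if (ch == "G") goal0 <- c(r - 1L, c - 1L)
    } else stop(sprintf("unknown maze character '%s'", ch))
  }
  structure(list(height = h, width = w, color = color, obstacle = obstacle,
                 n_colors = max(color), spawn = spawn, goal0 = goal0),
            class = "maze")
}

#' @export
print.maze <- function(x, ...) {
  cat(sprintf("<maze> %dx%d, %d floor cells, %d colors\n", x$height, x$width,
              nrow(maze_floor_cells(x)), x$n_colors))
  invisible(x)
}

#' Read a maze from an ASCII fixture file
#' @param path file path.
#' @inheritParams parse_maze
#' @return A [parse_maze()] result.
#' @export
read_maze <- function(path, legend = c(S = 1, G = 1)) {
  parse_maze(readLines(path), legend = legend)
}

maze_is_floor <- function(maze, pos) {
  r <- pos[1L]; c <- pos[2L]
  r >= 0L && r < maze$height && c >= 0L && c < maze$width &&
    !maze$obstacle[r + 1L, c + 1L]
}

#' All floor-cell positions of a maze
#' @param maze a [parse_maze()] object.
#' @return Integer matrix with columns `row`, `col` (0-based).
#' @export
maze_floor_cells <- function(maze) {
  idx <- which(!maze$obstacle, arr.ind = TRUE)
  out <- cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Action deltas
#' @return Integer 4x2 matrix of (drow, dcol) per action 0..3.
#' @export
action_deltas <- function() {
  matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L), 4, 2, byrow = TRUE,
         dimnames = list(c("up", "down", "left", "right"), c("drow", "dcol")))
}

#' Deterministic transition function
#'
#' @param maze a maze.
#' @param pos 0-based `(row, col)` position.
#' @param action integer 0..3.
#' @return The successor position; unchanged when the move hits an obstacle or
#'   the maze border.
#' @export
maze_move <- function(maze, pos, action) {
  d <- action_deltas()[action + 1L, ]
  nxt <- c(pos[1L] + d[[1L]], pos[2L] + d[[2L]])
  if (maze_is_floor(maze, nxt)) nxt else pos
}

#' Render the windowed multi-channel binary observation
#'
#' A `(2r+1) x (2r+1)` square window centered on the agent, with one binary
#' channel per floor color, one obstacle channel (cells outside the maze count
#' as obstacles) and one resource channel marking the goal cell.
#'
#' @param maze a maze.
#' @param pos agent position (0-based).
#' @param radius window radius `r`.
#' @param goal goal position or `NULL` (empty resource channel).
#' @return 3-d 0/1 array of shape `(2r+1, 2r+1, n_colors + 2)`.
#' @export
render_obs <- function(maze, pos, radius = 2, goal = NULL) {
  side <- 2L * radius + 1L
  nch <- maze$n_colors + 2L
  obs <- array(0L, dim = c(side, side, nch))
  for (dr in -radius:radius) for (dc in -radius:radius) {
    r <- pos[1L] + dr; c <- pos[2L] + dc
    wr <- dr + radius + 1L; wc <- dc + radius + 1L
    if (r < 0L || r >= maze$height || c < 0L || c >= maze$width ||
        maze$obstacle[r + 1L, c + 1L]) {
      obs[wr, wc, maze$n_colors + 1L] <- 1L
    } else {
      obs[wr, wc, maze$color[r + 1L, c + 1L]] <- 1L
      if (!is.null(goal) && r == goal[1L] && c == goal[2L])
        obs[wr, wc, maze$n_colors + 2L] <- 1L
    }
  }
  obs
}

#' Flattened observation vector
#' @inheritParams render_obs
#' @return Integer 0/1 vector of length `(2r+1)^2 * (n_colors + 2)`.
#' @export
obs_vector <- function(maze, pos, radius = 2, goal = NULL) {
  as.integer(render_obs(maze, pos, radius, goal))
}

#' Grid-world episode environment
#'
#' Wraps a maze with a goal, a spawn set, per-action energy costs and a time
#' limit. Reaching the goal yields reward `+1`; every action costs
#' `cost(action)`; moving into a wall leaves the position unchanged (the cost
#' is still paid). An episode ends on the goal or at the time limit.
#'
#' @param maze a maze.
#' @param goal 0-based goal position.
#' @param spawn_set list of candidate start positions (defaults to the maze's
#'   `S` cells, else all floor cells).
#' @param cost scalar cost, or numeric vector of length 4 (per action).
#' @param time_limit maximum steps per episode.
#' @param window_radius observation window radius.
#' @return An object of class `"grid_env"` (an environment). Call
#'   [env_reset()] before stepping.
#' @export
grid_env <- function(maze, goal, spawn_set = NULL, cost = 0.02,
                     time_limit = 500, window_radius = 2) {
  if (!maze_is_floor(maze, goal)) stop("goal must be a floor cell")
  env <- new.env(parent = emptyenv())
  env$maze <- maze
  env$goal <- as.integer(goal)
  env$spawn_set <- if (!is.null(spawn_set)) spawn_set
    else if (length(maze$spawn)) maze$spawn
    else apply(maze_floor_cells(maze), 1L, identity, simplify = FALSE)
  env$cost <- if (length(cost) == 1L) rep(cost, 4L) else cost
  env$time_limit <- as.integer(time_limit)
  env$radius <- as.integer(window_radius)
  env$pos <- NULL
  env$steps <- 0L
  env$done <- TRUE
  class(env) <- "grid_env"
  env
}

#' @export
print.grid_env <- function(x, ...) {
  cat(sprintf("<grid_env> goal=(%d,%d) pos=%s steps=%d\n", x$goal[1L],
              x$goal[2L], paste(x$pos, collapse = ","), x$steps))
  invisible(x)
}

#' Start a new episode
#' @param env a [grid_env].
#' @param pos optional fixed start position; by default one is sampled
#'   uniformly from the spawn set with the current RNG.
#' @return The initial observation vector, invisibly the environment holds the
#'   new state.
#' @export
env_reset <- function(env, pos = NULL) {
  env$pos <- if (!is.null(pos)) as.integer(pos)
    else as.integer(env$spawn_set[[sample.int(length(env$spawn_set), 1L)]])
  if (!maze_is_floor(env$maze, env$pos)) stop("spawn position is not a floor")
  env$steps <- 0L
  env$done <- FALSE
  obs_vector(env$maze, env$pos, env$radius, env$goal)
}

#' Take one environment step
#' @param env a [grid_env].
#' @param action integer 0..3 (up, down, left, right).
#' @return List with `obs` (flattened observation at the new position),
#'   `reward`, `done` and `pos`.
#' @export
env_step <- function(env, action) {
  if (env$done) stop("episode is over; call env_reset()")
  if (!(action %in% 0:3)) stop("invalid action id (must be 0..3)")
  env$pos <- maze_move(env$maze, env$pos, action)
  env$steps <- env$steps + 1L
  at_goal <- all(env$pos == env$goal)
  reward <- (if (at_goal) 1 else 0) - env$cost[action + 1L]
  env$done <- at_goal || env$steps >= env$time_limit
  list(obs = obs_vector(env$maze, env$pos, env$radius, env$goal),
       reward = reward, done = env$done, pos = env$pos,
       reached_goal = at_goal)
}

#' Built-in canonical mazes
#'
#' `four_rooms_maze()`: a 9x9 grid split into four 4x4 rooms by a cross of
#' walls with four doorways; each room has its own floor color, doorways a
#' fifth. The restricted spawn set is the 2x2 block in the top-left room and
#' the initial goal sits in the left doorway. `four_corridors_maze()`: a 9x9
#' radial cross of four one-cell-wide arms with distinct colors meeting at a
#' central crossing; spawn set = the four arm ends, initial goal = the center.
#'
#' @return A maze object.
#' @export
four_rooms_maze <- function() {
  path <- system.file("extdata", "four_rooms.txt", package = "htmagent")
  m <- read_maze(path, legend = c(S = 1, G = 5))
  m
}

#' @rdname four_rooms_maze
#' @export
four_corridors_maze <- function() {
  path <- system.file("extdata", "four_corridors.txt", package = "htmagent")
  read_maze(path, legend = c(S = 1, G = 5))
}

#' Structural landmarks of a maze
#'
#' Doorways are floor cells whose only two floor neighbors lie opposite each
#' other inside a wall line; doorway-adjacent cells are the floor neighbors of
#' doorways; deep corners are the four extreme grid corners (when floor).
#' These landmark sets describe the expected shape of the empowerment field:
#' its n-step values peak near doorways (the epsilon-ring) and bottom out in
#' deep corners.
#'
#' @param maze a maze.
#' @return List of 0-based position matrices: `doorways`, `doorway_adjacent`,
#'   `deep_corners`.
#' @export
maze_landmarks <- function(maze) {
  fc <- maze_floor_cells(maze)
  is_floor <- function(r, c) maze_is_floor(maze, c(r, c))
  doorways <- list(); adj <- list()
  for (i in seq_len(nrow(fc))) {
    r <- fc[i, 1L]; c <- fc[i, 2L]
    nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    fl <- vapply(seq_len(4L), function(k) is_floor(nb[k, 1L], nb[k, 2L]),
                 logical(1))
    if (sum(fl) == 2L && ((fl[1L] && fl[2L]) || (fl[3L] && fl[4L]))) {
      doorways[[length(doorways) + 1L]] <- c(r, c)
      for (k in which(fl)) adj[[length(adj) + 1L]] <- nb[k, ]
    }
  }
  corners <- list()
  for (p in list(c(0L, 0L), c(0L, maze$width - 1L), c(maze$height - 1L, 0L),
                 c(maze$height - 1L, maze$width - 1L)))
    if (maze_is_floor(maze, p)) corners[[length(corners) + 1L]] <- p
  list(doorways = do.call(rbind, doorways),
       doorway_adjacent = unique(do.call(rbind, adj)),
       deep_corners = do.call(rbind, corners))
}

room_of <- function(pos) {
  # quadrant index for the built-in 9x9 four rooms: 1=TL 2=TR 3=BL 4=BR,
  # 0 for doorway/wall-line cells
  r <- pos[1L]; c <- pos[2L]
  if (r == 4L || c == 4L) return(0L)
  1L + (r > 4L) * 2L + (c > 4L)
}

#' Episode/task protocols
#'
#' Drives the multi-episode schedules used in the experiments:
#' * `four_corridors`: spawn at a random arm end each episode; the goal sits at
#'   the central crossing for `episodes_per_phase` episodes, then moves to the
#'   middle of one randomly chosen arm for another `episodes_per_phase`.
#' * `four_rooms_restricted` / `four_rooms_free`: spawn from the restricted
#'   2x2 set (or any floor cell); goal in the left doorway, relocated after
#'   `episodes_per_phase` episodes to a random corner of the bottom-left room.
#' * `exhaustible_resource`: `levels` difficulty levels of `tasks_per_level`
#'   tasks each; a task fixes a goal until the agent has collected it more than
#'   `visits_per_task` times. Level 1 goals sit in the two hallways of the
#'   agent's spawn room, level 2 goals anywhere in the two adjacent rooms,
#'   level 3 goals anywhere outside the spawn room.
#'
#' @param kind one of `"four_corridors"`, `"four_rooms_restricted"`,
#'   `"four_rooms_free"`, `"exhaustible_resource"`.
#' @param maze the maze the protocol runs on (defaults to the built-in maze
#'   matching the kind).
#' @param episodes_per_phase episodes before the goal relocation (corridor /
#'   four-rooms kinds).
#' @param levels,tasks_per_level,visits_per_task exhaustible-resource schedule.
#' @return An object of class `"protocol"` (an environment). Use
#'   [protocol_advance()] to obtain each episode's spawn set and goal.
#' @export
protocol <- function(kind, maze = NULL, episodes_per_phase = 1000,
                     levels = 3, tasks_per_level = 10, visits_per_task = 100) {
  kind <- match.arg(kind, c("four_corridors", "four_rooms_restricted",
                            "four_rooms_free", "exhaustible_resource"))
  if (episodes_per_phase <= 0 || levels <= 0 || tasks_per_level <= 0 ||
      visits_per_task <= 0) stop("schedule parameters must be positive")
  if (is.null(maze))
    maze <- if (kind == "four_corridors") four_corridors_maze()
            else four_rooms_maze()
  pr <- new.env(parent = emptyenv())
  pr$kind <- kind
  pr$maze <- maze
  pr$episodes_per_phase <- as.integer(episodes_per_phase)
  pr$levels <- as.integer(levels)
  pr$tasks_per_level <- as.integer(tasks_per_level)
  pr$visits_per_task <- as.integer(visits_per_task)
  pr$episode <- 0L
  pr$task <- 0L
  pr$level <- 1L
  pr$visits <- 0L
  pr$goal <- NULL
  pr$phase2_goal <- NULL
  class(pr) <- "protocol"
  pr
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %s: episode %d task %d level %d\n", x$kind,
              x$episode, x$task, x$level))
  invisible(x)
}

# goal candidates of the built-in four rooms, by exhaustible level, for a
# spawn room in the top-left quadrant
four_rooms_level_goals <- function(maze, level) {
  if (level == 1L) return(list(c(4L, 2L), c(2L, 4L)))
  fc <- maze_floor_cells(maze)
  rooms <- apply(fc, 1L, room_of)
  keep <- if (level == 2L) rooms %in% c(2L, 3L) else rooms %in% c(2L, 3L, 4L)
  lapply(which(keep), function(i) fc[i, ])
}

#' Advance a protocol to the next episode
#'
#' @param proto a [protocol].
#' @param goal_reached did the previous episode end on the goal? (Drives the
#'   exhaustible-resource visit counter; ignored by the other kinds.)
#' @return List with `spawn_set` (list of positions), `goal`, `episode`,
#'   `task`, `level` and `trial_done` (TRUE when the schedule is exhausted —
#'   no further episode is issued).
#' @export
protocol_advance <- function(proto, goal_reached = FALSE) {
  m <- proto$maze
  if (proto$kind == "four_corridors") {
    proto$episode <- proto$episode + 1L
    n <- proto$episodes_per_phase
    if (proto$episode > 2L * n)
      return(list(trial_done = TRUE))
    if (proto$episode <= n) {
      goal <- c(4L, 4L)
    } else {
      if (is.null(proto$phase2_goal)) {
        arm <- sample.int(4L, 1L) # up, down, left, right mid-arm
        proto$phase2_goal <- switch(arm, c(2L, 4L), c(6L, 4L), c(4L, 2L),
                                    c(4L, 6L))
      }
      goal <- proto$phase2_goal
    }
    return(list(spawn_set = m$spawn, goal = goal, episode = proto$episode,
                task = if (proto$episode <= n) 1L else 2L, level = 1L,
                trial_done = FALSE))
  }
  if (proto$kind %in% c("four_rooms_restricted", "four_rooms_free")) {
    proto$episode <- proto$episode + 1L
    n <- proto$episodes_per_phase
    if (proto$episode > 2L * n) return(list(trial_done = TRUE))
    if (proto$episode <= n) goal <- m$goal0
    else {
      if (is.null(proto$phase2_goal)) {
        corners <- list(c(5L, 0L), c(8L, 0L), c(5L, 3L), c(8L, 3L))
        proto$phase2_goal <- corners[[sample.int(4L, 1L)]]
      }
      goal <- proto$phase2_goal
    }
    spawn <- if (proto$kind == "four_rooms_restricted") m$spawn
             else apply(maze_floor_cells(m), 1L, identity, simplify = FALSE)
    return(list(spawn_set = spawn, goal = goal, episode = proto$episode,
                task = if (proto$episode <= n) 1L else 2L, level = 1L,
                trial_done = FALSE))
  }
  # exhaustible_resource
  if (goal_reached) proto$visits <- proto$visits + 1L
  new_task <- proto$task == 0L || proto$visits > proto$visits_per_task
  if (new_task) {
    proto$task <- proto$task + 1L
    proto$visits <- 0L
    proto$level <- 1L + (proto$task - 1L) %/% proto$tasks_per_level
    if (proto$level > proto$levels) return(list(trial_done = TRUE))
    cands <- four_rooms_level_goals(m, proto$level)
    proto$goal <- cands[[sample.int(length(cands), 1L)]]
  }
  proto$episode <- proto$episode + 1L
  list(spawn_set = m$spawn, goal = proto$goal, episode = proto$episode,
       task = proto$task, level = proto$level, trial_done = FALSE)
}
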