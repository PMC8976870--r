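#' Empowerment estimator over a learned transition memory
#'
#' Empowerment of a state is the information-channel capacity between an
#' n-step action sequence and the resulting state. In a deterministic
#' environment it reduces to the entropy of the distribution over states
#' reachable in exactly n steps under uniformly distributed action sequences.
#' The estimator learns state-to-state transitions with a dedicated
#' [temporal_memory] (each pair trained after a context reset, so the memory is
#' first-order), then propagates distributed visit statistics through n
#' prediction steps: a vector `nu` over the state-SDR bit space counts, per
#' column, how many predicted paths arrive there. After n steps the
#' superposition is split into known states by masking with pattern-memory
#' clusters, and the entropy of the normalized per-cluster statistics is the
#' empowerment estimate in bits.
#'
#' @param k_in state SDR space dimension.
#' @param pattern_size active bits per state SDR.
#' @param depth prediction depth n (4 highlights the doorway ring in four-room
#'   mazes; deeper fields are cleaner but cost exponentially more to verify).
#' @param statistic the per-segment averaging statistic `Lambda`: `"mode"`
#'   (default; most robust to cluster interference), `"median"` or `"mean"`.
#' @param mask_theta overlap threshold for keeping a cluster from the
#'   superposition (defaults to the pattern-memory default, half the pattern
#'   size).
#' @param cells_per_column,seed transition-memory settings.
#' @return An object of class `"empowerment"` (an environment) whose `tm`
#'   field is the transition memory.
#' @export
empowerment <- function(k_in, pattern_size, depth = 4, statistic = "mode",
                        mask_theta = 0.5 * pattern_size,
                        cells_per_column = 4, seed = 0) {
  if (depth < 1) stop("depth must be >= 1")
  em <- new.env(parent = emptyenv())
  em$k_in <- as.integer(k_in)
  em$pattern_size <- as.integer(pattern_size)
  em$depth <- as.integer(depth)
  em$statistic <- match.arg(statistic, c("mode", "median", "mean"))
  em$mask_theta <- mask_theta
  em$tm <- temporal_memory(num_columns = k_in,
                           expected_sparsity = pattern_size,
                           cells_per_column = cells_per_column,
                           seed = seed)
  class(em) <- "empowerment"
  em
}

#' @export
print.empowerment <- function(x, ...) {
  cat(sprintf("<empowerment> depth=%d statistic=%s over %d bits\n",
              x$depth, x$statistic, x$k_in))
  invisible(x)
}

# Lambda: averaging statistic over a multiset of visit values.
# mode ties resolve to the smallest value.
stat_lambda <- function(values, statistic) {
  switch(statistic,
    mean = mean(values),
    median = stats::median(values),
    mode = {
      u <- sort(unique(values))
      u[which.max(tabulate(match(values, u)))]
    })
}

#' Learn one state-to-state transition
#'
#' Presents `s_prev` after a context reset and then `s_next` with learning on,
#' so the transition memory stores `s_prev -> s_next` independently of longer
#' history. Distinct predecessors of the same state end up on distinct
#' segments, which is what lets the visit-statistics propagation count paths.
#'
#' @param em an [empowerment] estimator.
#' @param s_prev,s_next [sdr]s over the `k_in` space.
#' @export
em_learn <- function(em, s_prev, s_next) {
  tm_reset(em$tm)
  tm_compute(em$tm, s_prev, learn = TRUE)
  out <- tm_compute(em$tm, s_next, learn = TRUE)
  tm_reset(em$tm)
  invisible(out$anomaly)
}

all_cells_of_columns <- function(tm, cols) {
  M <- tm$cells
  as.integer(outer(0:(M - 1L), cols * M, `+`))
}

#' Propagate visit statistics through n prediction steps
#'
#' Starting from `nu_0 = indicator(s0)`, repeatedly queries the transition
#' memory in prediction-only mode. At each step every active segment `psi`
#' receives the statistic `Lambda` of the visit values of its presynaptic
#' columns, and each predicted column accumulates the sum of its active
#' segments' values. The returned `sigma_n` is the superposition (SDR) of all
#' states reachable in n steps and `nu_n` the distributed visit counts.
#'
#' @param em an [empowerment] estimator.
#' @param s0 starting state [sdr].
#' @param n number of prediction steps (default: the estimator's depth).
#' @param statistic override the estimator's `Lambda`.
#' @return List with `sigma` ([sdr]), `nu` (numeric vector of length `k_in`)
#'   and `step` (the number of steps actually taken; propagation stops early
#'   if the prediction dies out).
#' @export
em_propagate <- function(em, s0, n = em$depth, statistic = em$statistic) {
  if (n < 0) stop("n must be >= 0")
  tm <- em$tm
  nu <- numeric(em$k_in)
  nu[s0$active + 1L] <- 1
  sigma <- s0$active
  t_done <- 0L
  # queries run at column level (all cells of the superposition's columns):
  # the transition memory is first-order, so no within-column context applies
  if (n > 0) for (t in seq_len(n)) {
    cells <- all_cells_of_columns(tm, sigma)
    pred <- tm_predict(tm, new_sdr(cells, n = tm$n_cells))
    segs <- pred$segments
    if (!length(segs)) break
    pre_cols <- tm_segment_columns(tm, segs)
    own_cols <- tm_segment_owner_columns(tm, segs)
    lam <- vapply(pre_cols, function(cc) stat_lambda(nu[cc + 1L], statistic),
                  numeric(1))
    nu_new <- numeric(em$k_in)
    for (i in seq_along(segs))
      nu_new[own_cols[i] + 1L] <- nu_new[own_cols[i] + 1L] + lam[i]
    nu <- nu_new
    sigma <- sort.int(unique(own_cols))
    t_done <- t
  }
  list(sigma = new_sdr(sigma, n = em$k_in), nu = nu, step = t_done)
}

#' Mask a superposition by pattern-memory clusters
#'
#' Keeps the clusters whose representation overlaps `sigma` by more than
#' `theta` and evaluates the statistic of the visit values on each kept
#' cluster's bits.
#'
#' @param sigma [sdr] superposition of reachable states.
#' @param nu numeric visit-statistics vector.
#' @param pm a [pattern_memory] holding the state vocabulary.
#' @param theta overlap threshold.
#' @param statistic the averaging statistic.
#' @return Named numeric vector: per-cluster visit statistic `nu_hat`, names
#'   are cluster ids. Empty when no cluster clears the threshold.
#' @export
em_mask <- function(sigma, nu, pm, theta, statistic = "mode") {
  out <- numeric(0)
  ids <- character(0)
  for (q in seq_len(pm$n_clusters)) {
    f <- pm_representation(pm, q)
    if (sdr_overlap(sigma, f) > theta) {
      out <- c(out, stat_lambda(nu[f$active + 1L], statistic))
      ids <- c(ids, as.character(q))
    }
  }
  stats::setNames(out, ids)
}

#' Entropy of normalized visit statistics (empowerment in bits)
#'
#' Normalizes `nu_hat` to a probability distribution over reachable states and
#' returns its Shannon entropy in bits. An empty or all-zero input yields 0
#' with a warning (no reachable state was recognized).
#'
#' @param nu_hat non-negative per-cluster visit statistics.
#' @return Empowerment value in bits.
#' @export
em_value <- function(nu_hat) {
  if (!length(nu_hat) || sum(nu_hat) <= 0) {
    warning("empty or all-zero visit statistics; empowerment set to 0")
    return(0)
  }
  p <- nu_hat / sum(nu_hat)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Full TM-based empowerment of one state
#'
#' Convenience wrapper: propagate, mask, and take the entropy.
#'
#' @param em an [empowerment] estimator.
#' @param s0 state [sdr].
#' @param pm the state-vocabulary [pattern_memory].
#' @param n depth override.
#' @param statistic statistic override.
#' @return Empowerment in bits.
#' @export
em_estimate <- function(em, s0, pm, n = em$depth, statistic = em$statistic) {
  pr <- em_propagate(em, s0, n = n, statistic = statistic)
  nu_hat <- em_mask(pr$sigma, pr$nu, pm, theta = em$mask_theta,
                    statistic = statistic)
  if (!length(nu_hat) || sum(nu_hat) <= 0) return(0)
  em_value(nu_hat)
}

#' Ideal empowerment by exhaustive action-sequence enumeration
#'
#' Enumerates all `4^n` action sequences from a position in a deterministic
#' maze, counts how often each terminal state occurs, normalizes the counts and
#' returns the entropy in bits. With `restricted = TRUE`, transitions by
#' different actions into the same successor state are merged into one edge
#' before counting (state-graph walks instead of action sequences); this is the
#' correct comparator for the transition-memory estimate, which cannot see how
#' many distinct actions produce a self-loop.
#'
#' @param maze a maze.
#' @param pos 0-based starting position.
#' @param n horizon.
#' @param restricted merge duplicate `(s, a) -> s'` transitions.
#' @return Empowerment in bits.
#' @export
ideal_empowerment <- function(maze, pos, n, restricted = FALSE) {
  counts <- new.env(parent = emptyenv())
  key <- function(p) paste(p[1L], p[2L])
  recurse <- function(p, depth) {
    if (depth == 0L) {
      k <- key(p)
      assign(k, (if (exists(k, counts)) get(k, counts) else 0) + 1, counts)
      return(invisible(NULL))
    }
    nxt <- lapply(0:3, function(a) maze_move(maze, p, a))
    if (restricted) nxt <- unique(nxt)
    for (q in nxt) recurse(q, depth - 1L)
  }
  recurse(as.integer(pos), as.integer(n))
  cnt <- unlist(as.list(counts))
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

#' Empowerment field of a maze
#'
#' Evaluates an empowerment variant at every floor cell.
#'
#' @param maze a maze.
#' @param n depth.
#' @param variant `"ideal"`, `"ideal_restricted"`, or a function
#'   `f(pos) -> bits` for learned estimates.
#' @param path optional CSV output (`row, col, value`).
#' @return `data.frame` with columns `row`, `col`, `value`.
#' @export
empowerment_field <- function(maze, n = 4, variant = "ideal", path = NULL) {
  fc <- maze_floor_cells(maze)
  f <- if (is.function(variant)) variant
    else if (variant == "ideal")
      function(p) ideal_empowerment(maze, p, n, restricted = FALSE)
    else if (variant == "ideal_restricted")
      function(p) ideal_empowerment(maze, p, n, restricted = TRUE)
    else stop("unknown variant")
  vals <- vapply(seq_len(nrow(fc)), function(i) f(fc[i, ]), numeric(1))
  out <- data.frame(row = fc[, 1L], col = fc[, 2L], value = vals)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
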