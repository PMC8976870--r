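#' Dreaming: learning in imagination with an anomaly-gated forward model
#'
#' The dreaming block learns, during awake steps, (i) a forward model — a
#' [temporal_memory] over the joint encoding of (state SDR, action SDR), state
#' bits first, trained on `(s_t + a_t) -> s_{t+1}` pairs; (ii) a distributed
#' reward model: per-state-bit running reward values, read out as the median
#' over a pattern's active bits; (iii) a distributed anomaly model: per
#' (action, state bit) running prediction miss rates `An`, read out the same
#' way — the state anomaly `an(s)` tells how reliable the model is around `s`;
#' and (iv) a pattern memory of seen states used for pattern completion during
#' rollouts.
#'
#' At each real step the agent may switch into dreaming: blocked outright when
#' the local anomaly exceeds a hard threshold, otherwise with probability
#' `(1 - an)^alpha * p_max`. While dreaming, the agent is detached from the
#' environment and interacts with the forward model instead, learning exactly
#' as if awake; each rollout starts from the current real state and ends when
#' the model predicts nothing, the imagined transition anomaly is too high, or
#' the step cap is reached.
#'
#' @param k_state state SDR space dimension.
#' @param state_sparsity active bits per state SDR.
#' @param n_actions number of elementary actions.
#' @param action_sparsity active bits per action SDR.
#' @param update_rate EMA rate of the reward and anomaly accumulators.
#' @param cells_per_column,seed forward-model settings.
#' @return An object of class `"dreaming_models"` (an environment) with fields
#'   `fm` (the forward temporal memory), `reward`, `an` (anomaly matrix
#'   `n_actions x k_state`, initialized at 1: everything unseen is maximally
#'   anomalous) and `pm`.
#' @export
dreaming_models <- function(k_state, state_sparsity, n_actions,
                            action_sparsity = 5, update_rate = 0.2,
                            cells_per_column = 4, seed = 0) {
  dm <- new.env(parent = emptyenv())
  dm$k_state <- as.integer(k_state)
  dm$m_state <- as.integer(state_sparsity)
  dm$n_actions <- as.integer(n_actions)
  dm$m_action <- as.integer(action_sparsity)
  dm$k_action <- dm$n_actions * dm$m_action
  dm$k_joint <- dm$k_state + dm$k_action
  dm$update_rate <- update_rate
  dm$fm <- temporal_memory(
    num_columns = dm$k_joint,
    expected_sparsity = state_sparsity,
    cells_per_column = cells_per_column,
    activation_threshold = ceiling(0.8 * (dm$m_state + dm$m_action)),
    seed = seed)
  dm$reward <- numeric(k_state)
  dm$an <- matrix(1, n_actions, k_state)
  dm$pm <- pattern_memory(k_state, state_sparsity)
  class(dm) <- "dreaming_models"
  dm
}

#' @export
print.dreaming_models <- function(x, ...) {
  cat(sprintf("<dreaming_models> %d state bits, %d actions, %d fm segments\n",
              x$k_state, x$n_actions, x$fm$seg_n))
  invisible(x)
}

#' Action SDR in the dreaming block's fixed muscles layout
#'
#' Each elementary action owns a disjoint block of `action_sparsity` bits.
#'
#' @param dm a [dreaming_models] (or any list with `m_action`, `k_action`).
#' @param action integer action id (0-based).
#' @return [sdr] over the action space.
#' @export
dm_action_sdr <- function(dm, action) {
  start <- action * dm$m_action
  sdr(start:(start + dm$m_action - 1L), n = dm$k_action)
}

dm_joint_sdr <- function(dm, s, action) {
  a <- dm_action_sdr(dm, action)
  new_sdr(c(s$active, dm$k_state + a$active), n = dm$k_joint)
}

dm_embed_state <- function(dm, s) new_sdr(s$active, n = dm$k_joint)

#' Dreaming switch / rollout configuration
#'
#' @param p_max maximum probability to enter dreaming (at zero anomaly).
#' @param alpha_exp exponent shaping the anomaly dependence.
#' @param hard_anomaly_threshold anomaly above which dreaming is blocked.
#' @param rollout_anomaly_threshold imagined-transition anomaly that stops a
#'   rollout early.
#' @param max_rollout_steps,max_rollouts_per_entry rollout caps.
#' @param mode `"anomaly"` (default) or `"td_error"` (ablation: switch
#'   probability scales with the last TD error magnitude inside a band).
#' @param td_scale,td_max td_error-mode band parameters.
#' @return A list of class `"dreaming_config"`.
#' @export
dreaming_config <- function(p_max = 0.12, alpha_exp = 2,
                            hard_anomaly_threshold = 0.6,
                            rollout_anomaly_threshold = 0.5,
                            max_rollout_steps = 20,
                            max_rollouts_per_entry = 5,
                            mode = c("anomaly", "td_error"),
                            td_scale = 0.25, td_max = 1) {
  stopifnot(p_max >= 0, p_max <= 1)
  structure(list(p_max = p_max, alpha_exp = alpha_exp,
                 hard_anomaly_threshold = hard_anomaly_threshold,
                 rollout_anomaly_threshold = rollout_anomaly_threshold,
                 max_rollout_steps = max_rollout_steps,
                 max_rollouts_per_entry = max_rollouts_per_entry,
                 mode = match.arg(mode), td_scale = td_scale,
                 td_max = td_max),
            class = "dreaming_config")
}

#' Learn one real transition into the dreaming models
#'
#' Trains the forward memory on `(s_prev + a_prev) -> s_now` (context reset
#' around the pair), updates the per-bit anomaly accumulators for
#' `(a_prev, s_now)` with each state bit's prediction miss, moves the per-bit
#' reward values on `s_now` toward `r_now`, and files `s_now` into the pattern
#' memory.
#'
#' @param dm a [dreaming_models].
#' @param s_prev,s_now state [sdr]s over `k_state`.
#' @param a_prev integer action id (0-based).
#' @param r_now reward received on arrival at `s_now`.
#' @return The transition anomaly (fraction of `s_now` columns the model did
#'   not predict), invisibly.
#' @export
dm_learn <- function(dm, s_prev, a_prev, s_now, r_now) {
  tm_reset(dm$fm)
  out1 <- tm_compute(dm$fm, dm_joint_sdr(dm, s_prev, a_prev), learn = TRUE)
  predicted <- out1$predicted_columns$active
  out2 <- tm_compute(dm$fm, dm_embed_state(dm, s_now), learn = TRUE)
  tm_reset(dm$fm)
  trans_anom <- out2$anomaly
  u <- dm$update_rate
  miss <- as.numeric(!(s_now$active %in% predicted))
  cols <- s_now$active + 1L
  dm$an[a_prev + 1L, cols] <- (1 - u) * dm$an[a_prev + 1L, cols] + u * miss
  dm$reward[cols] <- (1 - u) * dm$reward[cols] + u * r_now
  pm_update(dm$pm, s_now)
  invisible(trans_anom)
}

#' Distributed reward readout
#' @param dm a [dreaming_models].
#' @param s non-empty state [sdr].
#' @return Median of the per-bit reward values over `s`'s active bits.
#' @export
dm_reward <- function(dm, s) {
  if (!length(s$active)) stop("empty state SDR")
  stats::median(dm$reward[s$active + 1L])
}

#' Distributed anomaly readout for a transition
#' @param dm a [dreaming_models].
#' @param action integer action id.
#' @param s state [sdr] (the transition's destination).
#' @return Median of `An[action, j]` over `s`'s active bits.
#' @export
dm_anomaly <- function(dm, action, s) {
  if (!length(s$active)) return(1)
  stats::median(dm$an[action + 1L, s$active + 1L])
}

#' Decide whether to enter dreaming
#'
#' @param state_anomaly local anomaly `an(s)` in `[0, 1]`.
#' @param config a [dreaming_config].
#' @param td_error last TD error (used only in `td_error` mode).
#' @return `TRUE` to enter dreaming. Anomaly mode: blocked above the hard
#'   threshold, else Bernoulli with probability
#'   `(1 - an)^alpha_exp * p_max`.
#' @export
dm_switch <- function(state_anomaly, config, td_error = 0) {
  if (config$mode == "td_error") {
    a <- abs(td_error)
    if (a > config$td_max) return(FALSE)
    p <- config$p_max * min(1, a / config$td_scale)
    return(stats::runif(1) < p)
  }
  if (state_anomaly > config$hard_anomaly_threshold) return(FALSE)
  p <- (1 - state_anomaly)^config$alpha_exp * config$p_max
  stats::runif(1) < p
}

#' Predict the next state from the forward model
#'
#' Prediction-only query of the forward memory with the joint (state, action)
#' pattern; the output always lies in the state sub-space.
#'
#' @param dm a [dreaming_models].
#' @param s state [sdr].
#' @param action integer action id.
#' @return [sdr] over `k_state` (possibly empty).
#' @export
dm_predict <- function(dm, s, action) {
  joint <- dm_joint_sdr(dm, s, action)
  cells <- all_cells_of_columns(dm$fm, joint$active)
  pred <- tm_predict(dm$fm, new_sdr(cells, n = dm$fm$n_cells))
  cols <- pred$predicted_columns$active
  new_sdr(cols[cols < dm$k_state], n = dm$k_state)
}

#' Run one imagined rollout
#'
#' Starting from the current real state and reward, repeatedly feeds the
#' imagined (state, reward) to the agent callback, receives an action, and
#' advances through the forward model. The predicted pattern is snapped onto
#' the pattern memory's best cluster when recognized; the rollout stops when
#' the prediction is empty, the imagined transition anomaly exceeds the
#' threshold, or `max_rollout_steps` is reached. The callback learns during the
#' rollout exactly as if awake; the environment is never touched.
#'
#' @param dm a [dreaming_models].
#' @param s_start,r_start current real state [sdr] and reward.
#' @param agent_act callback `function(s, reward) -> action id`; it must also
#'   perform the agent's own learning update.
#' @param config a [dreaming_config].
#' @return Number of imagined steps taken.
#' @export
dm_rollout <- function(dm, s_start, r_start, agent_act, config) {
  s <- s_start; r <- r_start
  steps <- 0L
  while (steps < config$max_rollout_steps) {
    a <- agent_act(s, r)
    s_p <- dm_predict(dm, s, a)
    if (!length(s_p$active)) break
    s_next <- pm_complete(dm$pm, s_p)
    if (is.null(s_next)) s_next <- s_p
    if (dm_anomaly(dm, a, s_next) > config$rollout_anomaly_threshold) break
    r <- dm_reward(dm, s_next)
    s <- s_next
    steps <- steps + 1L
  }
  steps
}

#' Run one dreaming entry (a bounded set of rollouts)
#'
#' @inheritParams dm_rollout
#' @return List with `rollouts` and `imagined_steps`.
#' @export
dm_dream <- function(dm, s_start, r_start, agent_act, config) {
  total <- 0L; nroll <- 0L
  for (i in seq_len(config$max_rollouts_per_entry)) {
    k <- dm_rollout(dm, s_start, r_start, agent_act, config)
    if (k == 0L) break
    total <- total + k
    nroll <- nroll + 1L
  }
  list(rollouts = nroll, imagined_steps = total)
}
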