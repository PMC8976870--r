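#' Anomaly-confidence gating between hierarchy levels
#'
#' A lower-level temporal memory passes its current pattern up exactly when the
#' step's anomaly and confidence are simultaneously high: the pattern was
#' unexpected (a learned sub-sequence just ended) yet the memory already knows
#' what follows (another learned sub-sequence started). The passed pattern
#' becomes the representative of the started sequence on the upper level.
#'
#' @param out a `"tm_step"` result from [tm_compute()].
#' @param pattern the current input pattern (the [sdr] that produced `out`).
#' @param anomaly_threshold,confidence_threshold gate thresholds in `[0, 1]`.
#' @return `pattern` when the gate opens, else `NULL`.
#' @export
gate_up <- function(out, pattern, anomaly_threshold = 0.7,
                    confidence_threshold = 0.7) {
  if (out$anomaly >= anomaly_threshold &&
      out$confidence >= confidence_threshold) pattern else NULL
}

#' Resolve a stalled lower-level prediction through upper-level feedback
#'
#' When the lower memory's confidence is 0 (the learned sub-trajectory ended),
#' the upper memory may still predict the next abstract item; its starting
#' pattern — looked up in the registry built while gating up — is returned as
#' apical input for the lower memory.
#'
#' @param lower_out the lower level's `"tm_step"`.
#' @param upper_tm the upper [temporal_memory] (its pending prediction is
#'   used).
#' @param registry list of `list(abs = <sdr>, start = <sdr>)` entries mapping
#'   upper-level patterns to the lower-level starting pattern they represent.
#' @param min_overlap_frac fraction of an abstract pattern that must be
#'   predicted for a match (default 0.5).
#' @return The starting-pattern [sdr] of the best-matching predicted abstract
#'   item, or `NULL`.
#' @export
feedback_resolve <- function(lower_out, upper_tm, registry,
                             min_overlap_frac = 0.5) {
  if (lower_out$confidence > 0) return(NULL)
  pred <- upper_tm$pred_cols
  if (!length(pred) || !length(registry)) return(NULL)
  pred_sdr <- sdr(pred, n = upper_tm$n_cols)
  ov <- vapply(registry, function(e) sdr_overlap(pred_sdr, e$abs), numeric(1))
  best <- which.max(ov)
  need <- min_overlap_frac * length(registry[[best]]$abs$active)
  if (ov[best] >= need) registry[[best]]$start else NULL
}

new_option_trace <- function() {
  tr <- new.env(parent = emptyenv())
  tr$I <- list(); tr$beta <- list(); tr$heat <- list()
  class(tr) <- "option_trace"
  tr
}

trace_count <- function(lst, opt, pos) {
  key <- as.character(opt)
  pkey <- paste(pos[1L], pos[2L], sep = ",")
  if (is.null(lst[[key]])) lst[[key]] <- numeric(0)
  lst[[key]][pkey] <- (if (pkey %in% names(lst[[key]]))
    lst[[key]][[pkey]] else 0) + 1
  lst
}

#' Normalized option statistics
#'
#' Turns the raw per-option counters accumulated during runs (initiations,
#' terminations and per-position transition heat during option execution) into
#' the option-framework quantities: `I` (probability to initiate the option in
#' a state), `beta` (termination probability profile) and the raw heat counts.
#'
#' @param trace an option trace (from a hierarchical agent's `$trace` field).
#' @return Named list per option id: each with data frames `I`, `beta`
#'   (columns `row`, `col`, `p`, each summing to 1) and `heat` (`row`, `col`,
#'   `count`). Empty list for an empty trace.
#' @export
option_stats <- function(trace) {
  opts <- union(names(trace$I), union(names(trace$beta), names(trace$heat)))
  out <- list()
  to_df <- function(v, normalize) {
    if (is.null(v) || !length(v)) return(NULL)
    rc <- do.call(rbind, lapply(strsplit(names(v), ","), as.integer))
    val <- if (normalize) unname(v) / sum(v) else unname(v)
    data.frame(row = rc[, 1L], col = rc[, 2L], value = val)
  }
  for (o in opts) {
    out[[o]] <- list(I = to_df(trace$I[[o]], TRUE),
                     beta = to_df(trace$beta[[o]], TRUE),
                     heat = to_df(trace$heat[[o]], FALSE))
  }
  out
}

#' Hierarchical sensorimotor agent
#'
#' Wires the sub-blocks into the two-level architecture: a visual hierarchy
#' (level-1 spatial pooler + temporal memory over observations; a gated level-2
#' pooler + memory over abstract states) and a motor hierarchy (level-1
#' temporal memory over elementary-action SDRs with a basal-ganglia selector;
#' a gated level-2 pattern memory of abstract-action start patterns with its
#' own selector). Abstract actions arise from anomaly-confidence gating of the
#' motor memory; the selected abstract action is fed back apically, so the
#' motor memory predicts the sequence's next elementary action, whose thalamic
#' weight is boosted — the level-1 selector follows the option with increased
#' probability but can still interrupt it. Each selector carries dual
#' (extrinsic/intrinsic) striatal pathways combined by motivation priorities;
#' an optional dreaming block trains the level-1 value function in imagination.
#'
#' With `level2 = FALSE`, `empowerment_mode = "off"` and `dreaming = FALSE`
#' this constructs the one-level baseline: a single selector with one
#' extrinsic striatal pathway.
#'
#' @param obs_size length of the flattened observation vector.
#' @param n_actions number of elementary actions.
#' @param k_state,m_state level-1 state space size / sparsity.
#' @param m_action bits per elementary-action SDR (disjoint blocks).
#' @param k_abs,m_abs level-2 abstract state space size / sparsity.
#' @param cells_per_column temporal-memory depth.
#' @param alpha,gamma,beta TD rate, discount, inverse softmax temperature.
#' @param gate_anomaly,gate_confidence gating thresholds.
#' @param predicted_boost thalamic weight multiplier of the option-predicted
#'   action.
#' @param level2 enable the second hierarchy level (abstract actions).
#' @param empowerment_mode intrinsic signal: `"off"` (single extrinsic
#'   pathway), `"zero"`, `"random_pos"`, `"random_neg"`, `"anomaly_pos"`,
#'   `"anomaly_neg"`, `"ideal_pos"`, `"ideal_neg"` (ideal empowerment via
#'   `intrinsic_fn`), or `"tm"` (empowerment estimated from the agent's own
#'   transition memory).
#' @param intrinsic_fn for the `ideal_*` modes: `function(pos) -> bits`
#'   (see [make_ideal_empowerment_fn()]).
#' @param em_depth empowerment depth for scaling and the `"tm"` mode.
#' @param dreaming enable the dreaming block.
#' @param dream_config a [dreaming_config].
#' @param seed structural seed (pooler pools, memory tie-breaks).
#' @return An object of class `"hierarchical_agent"` (an environment).
#' @export
hierarchical_agent <- function(obs_size, n_actions,
                               k_state = 150, m_state = 10,
                               m_action = 5,
                               k_abs = 100, m_abs = 8,
                               cells_per_column = 6,
                               alpha = 0.1, gamma = 0.9, beta = 4,
                               gate_anomaly = 0.7, gate_confidence = 0.7,
                               predicted_boost = 3,
                               level2 = TRUE,
                               empowerment_mode = "off",
                               intrinsic_fn = NULL,
                               em_depth = 4,
                               dreaming = FALSE,
                               dream_config = dreaming_config(),
                               seed = 0) {
  ag <- new.env(parent = emptyenv())
  ag$n_actions <- as.integer(n_actions)
  ag$m_action <- as.integer(m_action)
  ag$k_act <- ag$n_actions * ag$m_action
  ag$k_state <- as.integer(k_state)
  ag$m_state <- as.integer(m_state)
  ag$alpha <- alpha; ag$gamma <- gamma; ag$beta <- beta
  ag$gate_anomaly <- gate_anomaly
  ag$gate_confidence <- gate_confidence
  ag$predicted_boost <- predicted_boost
  ag$level2 <- isTRUE(level2)
  ag$empowerment_mode <- match.arg(empowerment_mode,
    c("off", "zero", "random_pos", "random_neg", "anomaly_pos", "anomaly_neg",
      "ideal_pos", "ideal_neg", "tm"))
  ag$intrinsic_fn <- intrinsic_fn
  ag$em_depth <- em_depth
  ag$dreaming_enabled <- isTRUE(dreaming)
  ag$dream_config <- dream_config

  ag$b1_sp <- spatial_pooler(obs_size, k_state, m_state, seed = seed)
  ag$b1_tm <- temporal_memory(k_state, m_state,
                              cells_per_column = cells_per_column,
                              apical_enabled = level2, apical_space = k_state,
                              seed = seed + 1L)
  ag$action_sdrs <- lapply(0:(n_actions - 1L), function(a)
    sdr((a * m_action):((a + 1L) * m_action - 1L), n = ag$k_act))
  ag$b2_tm <- temporal_memory(ag$k_act, m_action,
                              cells_per_column = cells_per_column,
                              activation_threshold = ceiling(0.8 * m_action),
                              apical_enabled = level2,
                              apical_space = ag$k_act,
                              apical_threshold = ceiling(0.8 * m_action),
                              seed = seed + 2L)
  ag$b2_ext <- striatum(k_state, ag$k_act, alpha = alpha, gamma = gamma)
  ag$use_intrinsic <- ag$empowerment_mode != "off"
  if (ag$use_intrinsic) {
    ag$b2_int <- striatum(k_state, ag$k_act, alpha = alpha, gamma = gamma)
    ag$pr <- priorities()
  }
  if (ag$level2) {
    ag$b3_sp <- spatial_pooler(k_state, k_abs, m_abs, seed = seed + 3L)
    ag$b3_tm <- temporal_memory(k_abs, m_abs,
                                cells_per_column = cells_per_column,
                                seed = seed + 4L)
    ag$b4_pm <- pattern_memory(ag$k_act, m_action)
    ag$b4_ext <- striatum(k_abs, ag$k_act, alpha = alpha, gamma = gamma)
    if (ag$use_intrinsic)
      ag$b4_int <- striatum(k_abs, ag$k_act, alpha = alpha, gamma = gamma)
    ag$vis_registry <- list()
  }
  if (ag$empowerment_mode == "tm") {
    ag$em <- empowerment(k_state, m_state, depth = em_depth,
                         seed = seed + 5L)
    ag$em_pm <- pattern_memory(k_state, m_state)
  }
  if (ag$dreaming_enabled)
    ag$dm <- dreaming_models(k_state, m_state, n_actions,
                             action_sparsity = m_action, seed = seed + 6L)
  ag$trace <- new_option_trace()
  ag$dream_log <- list()
  agent_episode_reset(ag)
  class(ag) <- "hierarchical_agent"
  ag
}

#' @export
print.hierarchical_agent <- function(x, ...) {
  cat(sprintf(
    "<hierarchical_agent> level2=%s intrinsic=%s dreaming=%s (%d actions)\n",
    x$level2, x$empowerment_mode, x$dreaming_enabled, x$n_actions))
  invisible(x)
}

#' Clear the agent's episode context (called automatically on `done`)
#' @param ag a [hierarchical_agent].
#' @export
agent_episode_reset <- function(ag) {
  tm_reset(ag$b1_tm)
  tm_reset(ag$b2_tm)
  if (ag$level2) tm_reset(ag$b3_tm)
  ag$prev_state <- NULL
  ag$prev_action <- NULL
  ag$abs_state <- NULL
  ag$option <- NULL
  ag$opt_acc_ext <- 0; ag$opt_acc_int <- 0; ag$opt_tau <- 0L
  invisible(ag)
}

# intrinsic reward for the current step
agent_intrinsic <- function(ag, p_t, anomaly, pos) {
  mode <- ag$empowerment_mode
  if (mode %in% c("off", "zero")) return(0)
  if (mode == "random_pos") return(stats::runif(1))
  if (mode == "random_neg") return(stats::runif(1) - 1)
  if (mode == "anomaly_pos") return(anomaly)
  if (mode == "anomaly_neg") return(anomaly - 1)
  if (mode %in% c("ideal_pos", "ideal_neg")) {
    if (is.null(ag$intrinsic_fn) || is.null(pos)) return(0)
    e <- ag$intrinsic_fn(pos) / (ag$em_depth * 2) # scale by n*log2|A|
    return(if (mode == "ideal_pos") e else e - 1)
  }
  # "tm": estimate from the agent's own transition memory
  pm_update(ag$em_pm, p_t)
  if (!is.null(ag$prev_state)) em_learn(ag$em, ag$prev_state, p_t)
  e <- suppressWarnings(em_estimate(ag$em, p_t, ag$em_pm))
  e / (ag$em_depth * 2)
}

# one-level selection + TD learning given a state SDR; shared by awake and
# imagined steps. Returns the selected action (or NA at terminal states).
agent_level1_step <- function(ag, p_t, r_ext, r_int, done,
                              boost_actions = integer(0)) {
  a_t <- NA_integer_
  if (!done) {
    d_ext <- striatum_forward(ag$b2_ext, p_t)
    d <- if (ag$use_intrinsic)
      combine_pathways(striatum_forward(ag$b2_int, p_t), d_ext, ag$pr)
    else d_ext
    gpi <- gpi_select(d$d1, d$d2)
    w <- rep(1, ag$n_actions)
    if (length(boost_actions)) w[boost_actions + 1L] <- ag$predicted_boost
    a_t <- thalamus_select(ag$action_sdrs, gpi, weights = w,
                           beta = ag$beta) - 1L
  }
  a_sdr <- if (!done) ag$action_sdrs[[a_t + 1L]] else NULL
  v_ext <- if (done) 0 else striatum_value(ag$b2_ext, p_t, a_sdr)
  td_learn(ag$b2_ext, r_ext, v_ext)
  if (ag$use_intrinsic) {
    v_int <- if (done) 0 else striatum_value(ag$b2_int, p_t, a_sdr)
    td_learn(ag$b2_int, r_int, v_int)
    update_priorities(ag$pr, r_ext)
  }
  if (!done) {
    striatum_observe(ag$b2_ext, p_t, a_sdr)
    if (ag$use_intrinsic) striatum_observe(ag$b2_int, p_t, a_sdr)
  } else {
    ag$b2_ext$elig_stim <- NULL
    if (ag$use_intrinsic) ag$b2_int$elig_stim <- NULL
  }
  a_t
}

# abstract (level-2) selection at sequence boundaries
agent_level2_select <- function(ag, r_gamma_acc, pos) {
  if (!ag$level2 || is.null(ag$abs_state) || ag$b4_pm$n_clusters == 0L)
    return(invisible(NULL))
  reps <- lapply(seq_len(ag$b4_pm$n_clusters),
                 function(i) pm_representation(ag$b4_pm, i))
  d_ext <- striatum_forward(ag$b4_ext, ag$abs_state)
  d <- if (ag$use_intrinsic)
    combine_pathways(striatum_forward(ag$b4_int, ag$abs_state), d_ext, ag$pr)
  else d_ext
  gpi <- gpi_select(d$d1, d$d2)
  sel <- thalamus_select(reps, gpi, beta = ag$beta)
  o_sdr <- reps[[sel]]
  disc <- ag$gamma^ag$opt_tau
  v_ext <- striatum_value(ag$b4_ext, ag$abs_state, o_sdr) * disc
  td_learn(ag$b4_ext, ag$opt_acc_ext, v_ext)
  striatum_observe(ag$b4_ext, ag$abs_state, o_sdr)
  if (ag$use_intrinsic) {
    v_int <- striatum_value(ag$b4_int, ag$abs_state, o_sdr) * disc
    td_learn(ag$b4_int, ag$opt_acc_int, v_int)
    striatum_observe(ag$b4_int, ag$abs_state, o_sdr)
  }
  ag$opt_acc_ext <- 0; ag$opt_acc_int <- 0; ag$opt_tau <- 0L
  ag$option <- list(id = sel, pattern = o_sdr)
  if (!is.null(pos)) ag$trace$I <- trace_count(ag$trace$I, sel, pos)
  invisible(sel)
}

#' One full agent step
#'
#' Encodes the observation, advances the visual hierarchy (with gating to the
#' abstract level), computes the intrinsic reward, lets the motor hierarchy
#' select and learn, optionally dreams, and returns the chosen elementary
#' action. Call with `done = TRUE` for the terminal observation of an episode
#' (the final TD update runs and the episode context is cleared; `NA` is
#' returned).
#'
#' @param ag a [hierarchical_agent].
#' @param obs flattened binary observation vector.
#' @param reward extrinsic reward received on arriving at this observation.
#' @param done whether this observation ends the episode.
#' @param pos optional 0-based environment position, used only for option
#'   bookkeeping and ideal-empowerment lookup, never for decisions beyond the
#'   configured intrinsic signal.
#' @return Integer elementary action id (0-based), or `NA` when `done`.
#' @export
agent_act <- function(ag, obs, reward, done = FALSE, pos = NULL) {
  p_t <- sp_compute(ag$b1_sp, obs, learn = TRUE)
  # visual feedback: when level-1 cannot predict, ask the abstract level
  apical_vis <- NULL
  v1 <- tm_compute(ag$b1_tm, p_t, learn = TRUE)
  if (ag$level2) {
    gated <- gate_up(v1, p_t, ag$gate_anomaly, ag$gate_confidence)
    if (!is.null(gated)) {
      ag$abs_state <- sp_compute(ag$b3_sp, sdr_dense(gated), learn = TRUE)
      tm_compute(ag$b3_tm, ag$abs_state, learn = TRUE)
      ag$vis_registry <- register_pattern(ag$vis_registry, ag$abs_state,
                                          gated)
    }
    apical_vis <- feedback_resolve(v1, ag$b3_tm, ag$vis_registry)
    if (!is.null(apical_vis)) tm_apical_boost(ag$b1_tm, apical_vis)
  }
  r_int <- agent_intrinsic(ag, p_t, v1$anomaly, pos)

  # option accounting for the reward accrued since the last abstract choice
  ag$opt_acc_ext <- ag$opt_acc_ext + ag$gamma^ag$opt_tau * reward
  ag$opt_acc_int <- ag$opt_acc_int + ag$gamma^ag$opt_tau * r_int
  ag$opt_tau <- ag$opt_tau + 1L

  # which elementary action does the motor memory predict next? An action is
  # boosted only when its columns carry BOTH distal support (the sequence
  # context names it as the next element) and apical support (the running
  # option's feedback matches); once the feedback no longer matches, the
  # boost set empties and the option terminates below.
  boosted <- integer(0)
  if (!is.null(ag$option)) {
    M2 <- ag$b2_tm$cells
    dcols <- if (length(ag$b2_tm$pred_segs))
      unique(ag$b2_tm$seg_cell[ag$b2_tm$pred_segs] %/% M2) else integer(0)
    acols <- if (length(ag$b2_tm$apred_segs))
      unique(ag$b2_tm$aseg_cell[ag$b2_tm$apred_segs] %/% M2) else integer(0)
    both <- intersect(dcols, acols)
    if (length(both)) {
      pc <- new_sdr(sort.int(both), n = ag$k_act)
      ov <- vapply(ag$action_sdrs, function(s) sdr_overlap(pc, s), numeric(1))
      boosted <- which(ov >= 0.5 * ag$m_action) - 1L
    }
  }

  a_t <- agent_level1_step(ag, p_t, reward, r_int, done,
                           boost_actions = boosted)

  if (!done) {
    # option termination: interrupted or the learned sequence ended
    if (!is.null(ag$option) &&
        (!length(boosted) || !(a_t %in% boosted))) {
      if (!is.null(pos))
        ag$trace$beta <- trace_count(ag$trace$beta, ag$option$id, pos)
      ag$option <- NULL
    }
    if (!is.null(ag$option) && !is.null(pos))
      ag$trace$heat <- trace_count(ag$trace$heat, ag$option$id, pos)

    # motor memory step (with the option pattern as apical feedback)
    m_out <- tm_compute(ag$b2_tm, ag$action_sdrs[[a_t + 1L]],
                        apical_input = if (!is.null(ag$option))
                          ag$option$pattern else NULL,
                        learn = TRUE)
    if (ag$level2) {
      mg <- gate_up(m_out, ag$action_sdrs[[a_t + 1L]],
                    ag$gate_anomaly, ag$gate_confidence)
      boundary <- !is.null(mg) || is.null(ag$option)
      if (!is.null(mg)) pm_update(ag$b4_pm, mg)
      if (boundary) {
        agent_level2_select(ag, ag$opt_acc_ext, pos)
        # make the new option's feedback live immediately, so its first
        # predicted action can be boosted on the very next step
        if (!is.null(ag$option))
          tm_apical_boost(ag$b2_tm, ag$option$pattern)
      }
    }
  }

  # dreaming: learn the world models from the real transition, maybe detach
  if (ag$dreaming_enabled && !is.null(ag$prev_state) &&
      !is.null(ag$prev_action)) {
    dm_learn(ag$dm, ag$prev_state, ag$prev_action, p_t, reward)
    if (!done) {
      an_s <- dm_anomaly(ag$dm, ag$prev_action, p_t)
      if (dm_switch(an_s, ag$dream_config)) {
        saved_ext <- list(ag$b2_ext$elig_stim, ag$b2_ext$elig_resp)
        saved_int <- if (ag$use_intrinsic)
          list(ag$b2_int$elig_stim, ag$b2_int$elig_resp) else NULL
        cb <- function(s, r) {
          a <- agent_level1_step(ag, s, r, 0, FALSE)
          a
        }
        res <- dm_dream(ag$dm, p_t, reward, cb, ag$dream_config)
        ag$dream_log[[length(ag$dream_log) + 1L]] <-
          c(rollouts = res$rollouts, steps = res$imagined_steps)
        ag$b2_ext$elig_stim <- saved_ext[[1L]]
        ag$b2_ext$elig_resp <- saved_ext[[2L]]
        if (ag$use_intrinsic) {
          ag$b2_int$elig_stim <- saved_int[[1L]]
          ag$b2_int$elig_resp <- saved_int[[2L]]
        }
      }
    }
  }

  if (done) {
    if (!is.null(ag$option) && !is.null(pos))
      ag$trace$beta <- trace_count(ag$trace$beta, ag$option$id, pos)
    # terminal SMDP update: credit the accumulated option return (including
    # the goal reward) to the pending abstract choice, mirroring the level-1
    # terminal update
    if (ag$level2 && !is.null(ag$b4_ext$elig_stim)) {
      td_learn(ag$b4_ext, ag$opt_acc_ext, 0)
      ag$b4_ext$elig_stim <- NULL
      if (ag$use_intrinsic) {
        td_learn(ag$b4_int, ag$opt_acc_int, 0)
        ag$b4_int$elig_stim <- NULL
      }
    }
    agent_episode_reset(ag)
    return(NA_integer_)
  }
  ag$prev_state <- p_t
  ag$prev_action <- a_t
  a_t
}

register_pattern <- function(registry, abs_sdr, start_sdr) {
  for (e in registry)
    if (sdr_overlap(e$abs, abs_sdr) >= 0.8 * length(abs_sdr$active))
      return(registry)
  registry[[length(registry) + 1L]] <- list(abs = abs_sdr, start = start_sdr)
  registry
}

#' Ideal-empowerment lookup function for a maze
#'
#' Precomputes the n-step ideal empowerment field and returns a closure
#' mapping a position to its value in bits (0 off the floor).
#'
#' @param maze a maze.
#' @param n depth.
#' @param restricted use the deduplicated-transition variant.
#' @return `function(pos) -> bits`.
#' @export
make_ideal_empowerment_fn <- function(maze, n = 4, restricted = FALSE) {
  fld <- empowerment_field(maze, n = n,
                           variant = if (restricted) "ideal_restricted"
                                     else "ideal")
  key <- paste(fld$row, fld$col)
  vals <- stats::setNames(fld$value, key)
  function(pos) {
    k <- paste(pos[1L], pos[2L])
    if (k %in% names(vals)) vals[[k]] else 0
  }
}
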