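#' Basic distributed TD(Q) agent over state SDRs
#'
#' A minimal softmax reinforcement learner used to study the dreaming block in
#' isolation: a Q table distributed over state bits (`k_state x n_actions`),
#' read out as the mean over a state SDR's active bits, with 1-step Q-learning
#' updates and a softmax policy. Values start at zero, so with per-step action
#' costs the agent carries a built-in optimistic-initialization exploration
#' drive.
#'
#' @param k_state state SDR space dimension.
#' @param n_actions number of actions.
#' @param alpha learning rate.
#' @param gamma discount factor.
#' @param beta inverse softmax temperature.
#' @return An object of class `"td_agent"` (an environment).
#' @export
td_agent <- function(k_state, n_actions, alpha = 0.1, gamma = 0.95,
                     beta = 4) {
  ag <- new.env(parent = emptyenv())
  ag$k_state <- as.integer(k_state)
  ag$n_actions <- as.integer(n_actions)
  ag$alpha <- alpha
  ag$gamma <- gamma
  ag$beta <- beta
  ag$Q <- matrix(0, k_state, n_actions)
  ag$prev_s <- NULL
  ag$prev_a <- NULL
  ag$last_delta <- 0
  class(ag) <- "td_agent"
  ag
}

#' @export
print.td_agent <- function(x, ...) {
  cat(sprintf("<td_agent> %d state bits x %d actions (beta=%.2g)\n",
              x$k_state, x$n_actions, x$beta))
  invisible(x)
}

td_agent_q <- function(ag, s) {
  if (!length(s$active)) return(numeric(ag$n_actions))
  colMeans(ag$Q[s$active + 1L, , drop = FALSE])
}

#' One agent step: learn from the arrival and pick the next action
#'
#' Applies the Q-learning update for the previously taken action using the
#' just-received reward and the value of the new state, then samples the next
#' action from the softmax policy.
#'
#' @param ag a [td_agent].
#' @param s current state [sdr].
#' @param reward reward received on arriving at `s`.
#' @param done the episode ended at `s` (bootstrap value 0; the internal
#'   eligibility is cleared).
#' @return Integer action id (0-based); when `done`, no action is taken and
#'   `NA` is returned.
#' @export
td_agent_step <- function(ag, s, reward, done = FALSE) {
  q <- td_agent_q(ag, s)
  if (!is.null(ag$prev_s)) {
    v_new <- if (done) 0 else max(q)
    v_old <- mean(ag$Q[ag$prev_s$active + 1L, ag$prev_a + 1L])
    delta <- reward + ag$gamma * v_new - v_old
    ag$Q[ag$prev_s$active + 1L, ag$prev_a + 1L] <-
      ag$Q[ag$prev_s$active + 1L, ag$prev_a + 1L] + ag$alpha * delta
    ag$last_delta <- delta
  }
  if (done) {
    ag$prev_s <- NULL
    ag$prev_a <- NULL
    return(NA_integer_)
  }
  z <- ag$beta * q
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  a <- sample.int(ag$n_actions, 1L, prob = p) - 1L
  ag$prev_s <- s
  ag$prev_a <- a
  a
}

#' Reset the agent's episode context (between episodes or rollouts)
#' @param ag a [td_agent].
#' @export
td_agent_reset <- function(ag) {
  ag$prev_s <- NULL
  ag$prev_a <- NULL
  invisible(ag)
}
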