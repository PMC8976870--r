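#' Striatal pathway: dual D1/D2 value store with TD-dopamine learning
#'
#' One striatal zone, serving one dopamine source (extrinsic reward or
#' intrinsic signal). It holds two value matrices `W_D1`, `W_D2` of shape
#' `k_in x k_out` over (stimulus bit, response bit) pairs: D1 is the "go"
#' channel, D2 the "no-go" channel. Forward evaluation of a stimulus SDR
#' returns the two vectors `d1`, `d2` (each entry the mean over the stimulus'
#' active rows). The scalar value of a (stimulus, response) pair — used for TD
#' bootstrapping — is the mean of `(W_D1 - W_D2)/2` over the pair's active
#' cells, so that a TD update of magnitude `alpha * delta` applied with
#' opposite signs to the two matrices moves the pair value by exactly
#' `alpha * delta`.
#'
#' @param k_in stimulus space dimension.
#' @param k_out response space dimension.
#' @param alpha TD learning rate.
#' @param gamma discount factor.
#' @return An object of class `"striatum"` (an environment) with matrices
#'   initialized at zero (optimistic initialization: together with per-step
#'   action costs this makes untried responses look better than tried ones,
#'   giving a built-in exploration drive).
#' @export
striatum <- function(k_in, k_out, alpha = 0.1, gamma = 0.9) {
  p <- new.env(parent = emptyenv())
  p$k_in <- as.integer(k_in)
  p$k_out <- as.integer(k_out)
  p$alpha <- alpha
  p$gamma <- gamma
  p$W1 <- matrix(0, k_in, k_out)
  p$W2 <- matrix(0, k_in, k_out)
  p$elig_stim <- NULL
  p$elig_resp <- NULL
  class(p) <- "striatum"
  p
}

#' @export
print.striatum <- function(x, ...) {
  cat(sprintf("<striatum> %d x %d, alpha=%.3g gamma=%.3g\n",
              x$k_in, x$k_out, x$alpha, x$gamma))
  invisible(x)
}

#' Evaluate a stimulus through a striatal pathway
#'
#' @param p a [striatum].
#' @param stimulus [sdr] over the `k_in` space.
#' @return List with numeric vectors `d1` and `d2` of length `k_out`: for each
#'   response bit, the mean of the corresponding column of `W_D1` / `W_D2` over
#'   the stimulus' active rows (zero vectors for an empty stimulus).
#' @export
striatum_forward <- function(p, stimulus) {
  if (stimulus$n != p$k_in) stop("stimulus dimension mismatch")
  if (!length(stimulus$active))
    return(list(d1 = numeric(p$k_out), d2 = numeric(p$k_out)))
  rows <- stimulus$active + 1L
  list(d1 = colMeans(p$W1[rows, , drop = FALSE]),
       d2 = colMeans(p$W2[rows, , drop = FALSE]))
}

#' Scalar value of a (stimulus, response) pair
#' @param p a [striatum].
#' @param stimulus,response [sdr]s over `k_in` / `k_out`.
#' @return Mean of `(W_D1 - W_D2)/2` over the pair's active cells (0 if either
#'   SDR is empty).
#' @export
striatum_value <- function(p, stimulus, response) {
  if (!length(stimulus$active) || !length(response$active)) return(0)
  rows <- stimulus$active + 1L
  cols <- response$active + 1L
  mean((p$W1[rows, cols, drop = FALSE] - p$W2[rows, cols, drop = FALSE]) / 2)
}

#' Record the pair the pathway is currently committed to
#'
#' Stores the (stimulus, response) eligibility pair that the next [td_learn()]
#' call will credit.
#'
#' @param p a [striatum].
#' @param stimulus,response [sdr]s.
#' @export
striatum_observe <- function(p, stimulus, response) {
  p$elig_stim <- stimulus
  p$elig_resp <- response
  invisible(p)
}

#' One TD-dopamine learning step
#'
#' Computes the 1-step TD error `delta = r + gamma * v_new - v_old`, where
#' `v_old` is the value of the stored eligibility pair, then applies the
#' dopamine update on that pair's active cells: `W_D1 += alpha * delta`,
#' `W_D2 -= alpha * delta` (positive errors strengthen the go pathway and
#' weaken the no-go pathway; negative errors do the opposite).
#'
#' @param p a [striatum].
#' @param reward scalar reward received after taking the eligibility pair.
#' @param new_value_estimate bootstrapped value of the successor
#'   (stimulus, response) pair; 0 at terminal states.
#' @return The TD error `delta`, invisibly `NULL` when no eligibility pair is
#'   stored (no-op).
#' @export
td_learn <- function(p, reward, new_value_estimate) {
  if (is.null(p$elig_stim)) return(invisible(NULL))
  v_old <- striatum_value(p, p$elig_stim, p$elig_resp)
  delta <- reward + p$gamma * new_value_estimate - v_old
  rows <- p$elig_stim$active + 1L
  cols <- p$elig_resp$active + 1L
  if (length(rows) && length(cols)) {
    p$W1[rows, cols] <- p$W1[rows, cols] + p$alpha * delta
    p$W2[rows, cols] <- p$W2[rows, cols] - p$alpha * delta
  }
  delta
}

#' Pathway priorities between intrinsic and extrinsic motivation
#'
#' Tracks exponential moving averages of the extrinsic reward and of the
#' running per-step minimum extrinsic reward. When the average reward exceeds
#' the average minimum, the agent "finds the resource well" and the extrinsic
#' priority grows toward `clip01((avg_reward - avg_min_reward)/scale)`;
#' otherwise the intrinsic priority takes over. The pair always satisfies
#' `pr_int + pr_ext = 1`. The intrinsic scale factor `eta` decays by
#' `eta_decay` on every update while the intrinsic pathway dominates (breaking
#' the vicious circle of walking the empowerment ridge forever) and resets to 1
#' as soon as the extrinsic pathway dominates again.
#'
#' @param ema_rate EMA rate for both averages and the priority smoothing.
#' @param eta_decay multiplicative decay of `eta` per update while
#'   `pr_int > pr_ext`.
#' @param scale reward scale (the magnitude of the goal reward).
#' @return An object of class `"priorities"` (an environment) with fields
#'   `pr_int`, `pr_ext` (starting at 0.5/0.5) and `eta` (starting at 1).
#' @export
priorities <- function(ema_rate = 0.01, eta_decay = 0.99, scale = 1) {
  pr <- new.env(parent = emptyenv())
  pr$ema_rate <- ema_rate
  pr$eta_decay <- eta_decay
  pr$scale <- scale
  pr$pr_ext <- 0.5
  pr$pr_int <- 0.5
  pr$eta <- 1
  pr$avg_reward <- NULL
  pr$avg_min_reward <- NULL
  pr$min_reward <- NULL
  class(pr) <- "priorities"
  pr
}

#' @export
print.priorities <- function(x, ...) {
  cat(sprintf("<priorities> pr_ext=%.3f pr_int=%.3f eta=%.3f\n",
              x$pr_ext, x$pr_int, x$eta))
  invisible(x)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Update the motivation priorities with one extrinsic reward
#' @param pr a [priorities] object.
#' @param extrinsic_reward the reward just received from the environment.
#' @return The updated [priorities], invisibly.
#' @export
update_priorities <- function(pr, extrinsic_reward) {
  r <- extrinsic_reward
  lam <- pr$ema_rate
  if (is.null(pr$avg_reward)) {
    pr$avg_reward <- r
    pr$min_reward <- r
    pr$avg_min_reward <- r
  } else {
    pr$min_reward <- min(pr$min_reward, r)
    pr$avg_reward <- (1 - lam) * pr$avg_reward + lam * r
    pr$avg_min_reward <- (1 - lam) * pr$avg_min_reward + lam * pr$min_reward
  }
  target <- clip01((pr$avg_reward - pr$avg_min_reward) / pr$scale)
  pr$pr_ext <- (1 - lam) * pr$pr_ext + lam * target
  pr$pr_int <- 1 - pr$pr_ext
  if (pr$pr_int > pr$pr_ext) pr$eta <- pr$eta * pr$eta_decay
  else pr$eta <- 1
  invisible(pr)
}

#' Combine intrinsic and extrinsic striatal outputs
#'
#' `d_a = eta * d_a_int * pr_int + d_a_ext * pr_ext` for `a in {1, 2}`.
#'
#' @param d_int,d_ext lists with `d1`, `d2` vectors (from
#'   [striatum_forward()]).
#' @param pr a [priorities] object.
#' @return List with combined `d1`, `d2`.
#' @export
combine_pathways <- function(d_int, d_ext, pr) {
  if (length(d_int$d1) != length(d_ext$d1))
    stop("pathway output length mismatch")
  list(d1 = pr$eta * d_int$d1 * pr$pr_int + d_ext$d1 * pr$pr_ext,
       d2 = pr$eta * d_int$d2 * pr$pr_int + d_ext$d2 * pr$pr_ext)
}

#' Pallidal aggregation and Bernoulli binarization
#'
#' Computes `g = d2 - d1` (the external segment's sign flip is already folded
#' in), min-max normalizes `g` to `[0, 1]` (all 0.5 when `max == min`), and
#' samples each output bit independently as `Bernoulli(g_j)`. A bit with high
#' inhibition (`d2` dominating) is likely included in the pallidal output and
#' therefore *suppresses* the responses it covers downstream.
#'
#' @param d1,d2 numeric vectors of equal length `k_out`.
#' @return [sdr] over the response space: the sampled pallidal output.
#' @export
gpi_select <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("d1/d2 length mismatch")
  g <- d2 - d1
  rng <- range(g)
  p <- if (rng[1] == rng[2]) rep(0.5, length(g))
       else (g - rng[1]) / (rng[2] - rng[1])
  sdr(which(stats::runif(length(g)) < p) - 1L, n = length(g))
}

#' Thalamic response selection
#'
#' Each cortical response candidate is scored by how much of it survives the
#' pallidal inhibition: `v_i = w_i * |complement(gpi) n res_i|`. Scores are
#' passed through a softmax with inverse temperature `beta` and one response is
#' sampled from the resulting categorical distribution.
#'
#' @param responses list of [sdr] response candidates over the `k_out` space.
#' @param weights numeric significance weights `w_i` (default all 1).
#' @param gpi [sdr]: the pallidal output from [gpi_select()].
#' @param beta inverse softmax temperature (0 gives uniform selection).
#' @return Integer index of the selected response.
#' @export
thalamus_select <- function(responses, gpi, weights = NULL, beta = 1) {
  if (!length(responses)) stop("no responses to select among")
  if (is.null(weights)) weights <- rep(1, length(responses))
  open <- sdr_complement(gpi)
  v <- vapply(seq_along(responses), function(i)
    weights[i] * sdr_overlap(open, responses[[i]]), numeric(1))
  z <- beta * v
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  sample.int(length(responses), 1L, prob = p)
}

#' Softmax selection probabilities used by the thalamus
#'
#' Deterministic counterpart of [thalamus_select()]; exposed for calibration
#' checks of empirical selection frequencies.
#'
#' @inheritParams thalamus_select
#' @return Numeric probability vector summing to 1.
#' @export
thalamus_probs <- function(responses, gpi, weights = NULL, beta = 1) {
  if (is.null(weights)) weights <- rep(1, length(responses))
  open <- sdr_complement(gpi)
  v <- vapply(seq_along(responses), function(i)
    weights[i] * sdr_overlap(open, responses[[i]]), numeric(1))
  z <- beta * v
  z <- z - max(z)
  exp(z) / sum(exp(z))
}
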