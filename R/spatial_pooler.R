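#' Spatial pooler: k-winners Hebbian SDR encoder
#'
#' Encodes dense binary input patterns into fixed-sparsity SDRs of active
#' minicolumns. Each column owns one proximal segment: a fixed "potential pool"
#' of input bits sampled at construction, each with a permanence in `[0, 1]`.
#' A synapse is connected when its permanence reaches `connect_threshold`. On
#' each step the `k_active` columns with the most connected synapses onto
#' active input bits win (ties broken by ascending column index, so the output
#' is deterministic given the state). With learning on, winners reinforce
#' synapses to active inputs (`+perm_inc`) and weaken synapses to inactive
#' inputs (`-perm_dec`), clipped to `[0, 1]`.
#'
#' Duty-cycle boosting is off by default; when enabled, column overlaps are
#' multiplied by `exp(boost_strength * (k_active/num_columns - duty))` where
#' `duty` is an EMA of each column's activity.
#'
#' @param input_size length of the dense binary input vector.
#' @param num_columns number of output minicolumns.
#' @param k_active winners per step (output sparsity; must be <= num_columns).
#' @param potential_fraction fraction of input bits in each column's pool.
#' @param connect_threshold permanence at which a synapse conducts.
#' @param perm_inc,perm_dec Hebbian increment/decrement.
#' @param boosting enable duty-cycle homeostasis.
#' @param boost_strength,duty_rate boosting parameters (used when `boosting`).
#' @param seed integer seed controlling pool sampling and permanence init
#'   (permanences start uniform in `[0.4, 0.6]`).
#' @return An object of class `"spatial_pooler"` (an environment).
#' @export
spatial_pooler <- function(input_size, num_columns, k_active,
                           potential_fraction = 0.75,
                           connect_threshold = 0.5,
                           perm_inc = 0.1, perm_dec = 0.02,
                           boosting = FALSE, boost_strength = 1,
                           duty_rate = 0.01, seed = 0) {
  if (k_active > num_columns) stop("k_active must not exceed num_columns")
  sp <- new.env(parent = emptyenv())
  sp$input_size <- as.integer(input_size)
  sp$num_columns <- as.integer(num_columns)
  sp$k_active <- as.integer(k_active)
  sp$connect_threshold <- connect_threshold
  sp$perm_inc <- perm_inc
  sp$perm_dec <- perm_dec
  sp$boosting <- isTRUE(boosting)
  sp$boost_strength <- boost_strength
  sp$duty_rate <- duty_rate
  sp$duty <- rep(k_active / num_columns, num_columns)
  pool_size <- max(1L, round(potential_fraction * input_size))
  old <- local_rng_seed(seed)
  on.exit(restore_rng(old))
  pp_in <- integer(0); pp_col <- integer(0)
  for (c in seq_len(num_columns)) {
    pool <- sort.int(sample.int(input_size, pool_size))
    pp_in <- c(pp_in, pool)
    pp_col <- c(pp_col, rep.int(c, pool_size))
  }
  sp$pp_in <- pp_in                      # 1-based input indices
  sp$pp_col <- pp_col                    # 1-based column ids
  sp$pp_perm <- stats::runif(length(pp_in), 0.4, 0.6)
  class(sp) <- "spatial_pooler"
  sp
}

#' @export
print.spatial_pooler <- function(x, ...) {
  cat(sprintf("<spatial_pooler> %d -> %d columns, %d winners, %d synapses\n",
              x$input_size, x$num_columns, x$k_active, length(x$pp_in)))
  invisible(x)
}

# RNG scoping helpers: run a block under a given seed, then restore the
# caller's RNG stream untouched.
local_rng_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Encode one input through the spatial pooler
#'
#' @param sp a [spatial_pooler].
#' @param input dense binary vector of length `input_size`, or an [sdr] over
#'   the input space.
#' @param learn apply the Hebbian permanence update to the winning columns.
#' @return [sdr] over the column space with exactly `k_active` active bits
#'   (0-based column indices).
#' @export
sp_compute <- function(sp, input, learn = TRUE) {
  if (is_sdr(input)) {
    if (input$n != sp$input_size) stop("input SDR dimension mismatch")
    act_mask <- logical(sp$input_size)
    act_mask[input$active + 1L] <- TRUE
  } else {
    if (length(input) != sp$input_size)
      stop(sprintf("input length %d != input_size %d",
                   length(input), sp$input_size))
    act_mask <- input != 0
  }
  conn <- sp$pp_perm >= sp$connect_threshold
  hit <- conn & act_mask[sp$pp_in]
  ov <- tabulate(sp$pp_col[hit], nbins = sp$num_columns)
  score <- if (sp$boosting)
    ov * exp(sp$boost_strength * (sp$k_active / sp$num_columns - sp$duty))
  else ov
  ord <- order(-score, seq_len(sp$num_columns))
  winners <- ord[seq_len(sp$k_active)]
  if (learn) {
    wmask <- logical(sp$num_columns)
    wmask[winners] <- TRUE
    idx <- which(wmask[sp$pp_col])
    on_in <- act_mask[sp$pp_in[idx]]
    sp$pp_perm[idx] <- pmin(1, pmax(0, sp$pp_perm[idx] +
      ifelse(on_in, sp$perm_inc, -sp$perm_dec)))
    if (sp$boosting) {
      act <- numeric(sp$num_columns); act[winners] <- 1
      sp$duty <- (1 - sp$duty_rate) * sp$duty + sp$duty_rate * act
    }
  }
  sdr(sort.int(winners) - 1L, n = sp$num_columns)
}
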