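#' Temporal memory: online SDR sequence learning
#'
#' A simplified minicolumn-and-cell sequence memory. The layer has
#' `num_columns` minicolumns of `cells_per_column` cells each. Cells carry
#' distal segments (synapses onto other cells of the layer) and, optionally,
#' apical segments (synapses onto an external feedback space). A segment is
#' active when its count of connected synapses (permanence >=
#' `connect_threshold`) onto currently active presynaptic bits reaches
#' `activation_threshold`. Cells with an active segment enter the predicted
#' state for the next step.
#'
#' On each step, every active column activates its predicted cells; a column
#' with no predicted cell "bursts" (all cells become active) and, with learning
#' on, grows a new distal segment on its least-used cell wired to the previous
#' step's winner cells. Correctly predicting segments are reinforced
#' (Hebbian `+perm_inc` to active presynapses, `-perm_dec` to the rest),
#' segments that predicted a column that did not activate are punished by
#' `perm_punish`. Two scalar signals summarize each step: the anomaly (fraction
#' of active columns that were not predicted; the degree of surprise) and the
#' confidence (`min(1, predicted columns / expected_sparsity)`; how strongly
#' the layer predicts the next pattern, 0 when it predicts nothing).
#'
#' Apical feedback is treated like distal context: apical segments grow and
#' learn by the same Hebbian rules, and a cell with an active apical segment is
#' predicted even without distal support, so top-down feedback can resolve
#' predictions when the lateral context is silent.
#'
#' @param num_columns number of minicolumns.
#' @param expected_sparsity typical number of active columns per input pattern
#'   (used for the default activation threshold and the confidence scale).
#' @param cells_per_column cells per minicolumn.
#' @param activation_threshold active presynaptic count that activates a
#'   segment; default `ceiling(0.8 * expected_sparsity)`.
#' @param connect_threshold permanence at which a synapse conducts.
#' @param perm_init initial permanence of grown synapses (connected by
#'   default, so one presentation of a transition suffices to predict it).
#' @param perm_inc,perm_dec,perm_punish learning rates.
#' @param max_segments_per_cell,max_synapses_per_segment growth caps.
#' @param apical_enabled accept apical feedback input.
#' @param apical_space dimension of the apical input space.
#' @param apical_threshold active-presynapse count activating an apical
#'   segment (defaults to `activation_threshold`).
#' @param seed integer seed for the per-cell tie-break priorities.
#' @return An object of class `"temporal_memory"` (an environment).
#' @export
temporal_memory <- function(num_columns, expected_sparsity,
                            cells_per_column = 8,
                            activation_threshold =
                              ceiling(0.8 * expected_sparsity),
                            connect_threshold = 0.5, perm_init = 0.6,
                            perm_inc = 0.1, perm_dec = 0.05,
                            perm_punish = 0.01,
                            max_segments_per_cell = 64,
                            max_synapses_per_segment = 64,
                            apical_enabled = FALSE, apical_space = 0,
                            apical_threshold = activation_threshold,
                            seed = 0) {
  tm <- new.env(parent = emptyenv())
  tm$n_cols <- as.integer(num_columns)
  tm$cells <- as.integer(cells_per_column)
  tm$n_cells <- tm$n_cols * tm$cells
  tm$expected_sparsity <- expected_sparsity
  tm$act_threshold <- as.integer(activation_threshold)
  tm$connect_threshold <- connect_threshold
  tm$perm_init <- perm_init
  tm$perm_inc <- perm_inc
  tm$perm_dec <- perm_dec
  tm$perm_punish <- perm_punish
  tm$max_seg <- as.integer(max_segments_per_cell)
  tm$max_syn <- as.integer(max_synapses_per_segment)
  tm$apical_enabled <- isTRUE(apical_enabled)
  tm$apical_space <- as.integer(apical_space)
  tm$apical_threshold <- as.integer(apical_threshold)
  # distal synapse store (flat, capacity-doubled)
  tm$d_pre <- integer(0); tm$d_seg <- integer(0); tm$d_perm <- numeric(0)
  tm$d_n <- 0L
  tm$seg_cell <- integer(0); tm$seg_n <- 0L
  # apical synapse store
  tm$a_pre <- integer(0); tm$a_seg <- integer(0); tm$a_perm <- numeric(0)
  tm$a_n <- 0L
  tm$aseg_cell <- integer(0); tm$aseg_n <- 0L
  tm$cell_seg_count <- integer(tm$n_cells)
  old <- local_rng_seed(seed)
  tm$cell_priority <- stats::runif(tm$n_cells)
  restore_rng(old)
  tm_reset(tm)
  class(tm) <- "temporal_memory"
  tm
}

#' @export
print.temporal_memory <- function(x, ...) {
  cat(sprintf(
    "<temporal_memory> %d columns x %d cells, %d segments, %d synapses\n",
    x$n_cols, x$cells, x$seg_n, x$d_n))
  invisible(x)
}

#' Reset the temporal context of a temporal memory
#'
#' Clears active/winner cells and pending predictions; learned segments are
#' kept. Use between independent sequences (e.g., when training pairwise
#' transitions).
#'
#' @param tm a [temporal_memory].
#' @export
tm_reset <- function(tm) {
  tm$active_cells <- integer(0)
  tm$winner_cells <- integer(0)
  tm$pred_cells <- integer(0)
  tm$pred_cols <- integer(0)
  tm$pred_segs <- integer(0)
  tm$apred_segs <- integer(0)
  tm$prev_apical <- NULL
  invisible(tm)
}

# active distal segments given active cells (0-based ids)
tm_active_segments <- function(tm, cells) {
  dn <- tm$d_n
  if (dn == 0L || length(cells) == 0L) return(integer(0))
  amask <- logical(tm$n_cells)
  amask[cells + 1L] <- TRUE
  hit <- (tm$d_perm >= tm$connect_threshold) & amask[tm$d_pre + 1L]
  cnt <- tabulate(tm$d_seg[hit], nbins = tm$seg_n)
  which(cnt >= tm$act_threshold)
}

tm_active_apical_segments <- function(tm, bits) {
  an <- tm$a_n
  if (an == 0L || length(bits) == 0L) return(integer(0))
  amask <- logical(tm$apical_space)
  amask[bits + 1L] <- TRUE
  hit <- (tm$a_perm >= tm$connect_threshold) & amask[tm$a_pre + 1L]
  cnt <- tabulate(tm$a_seg[hit], nbins = tm$aseg_n)
  which(cnt >= tm$apical_threshold)
}

tm_grow_segment <- function(tm, cell, presyn) {
  if (length(presyn) == 0L) return(invisible(NULL))
  if (tm$cell_seg_count[cell + 1L] >= tm$max_seg) return(invisible(NULL))
  if (length(presyn) > tm$max_syn) {
    ord <- order(-tm$cell_priority[presyn + 1L])
    presyn <- presyn[ord[seq_len(tm$max_syn)]]
  }
  tm$seg_n <- tm$seg_n + 1L
  tm$seg_cell <- c(tm$seg_cell, cell)
  tm$cell_seg_count[cell + 1L] <- tm$cell_seg_count[cell + 1L] + 1L
  m <- length(presyn)
  tm$d_pre <- c(tm$d_pre, presyn)
  tm$d_seg <- c(tm$d_seg, rep.int(tm$seg_n, m))
  tm$d_perm <- c(tm$d_perm, rep.int(tm$perm_init, m))
  tm$d_n <- tm$d_n + m
  invisible(tm$seg_n)
}

tm_grow_apical_segment <- function(tm, cell, presyn) {
  if (length(presyn) == 0L) return(invisible(NULL))
  if (length(presyn) > tm$max_syn) presyn <- presyn[seq_len(tm$max_syn)]
  tm$aseg_n <- tm$aseg_n + 1L
  tm$aseg_cell <- c(tm$aseg_cell, cell)
  m <- length(presyn)
  tm$a_pre <- c(tm$a_pre, presyn)
  tm$a_seg <- c(tm$a_seg, rep.int(tm$aseg_n, m))
  tm$a_perm <- c(tm$a_perm, rep.int(tm$perm_init, m))
  tm$a_n <- tm$a_n + m
  invisible(tm$aseg_n)
}

# Hebbian update on the given distal segments toward the given presyn cells.
tm_adapt_segments <- function(tm, segs, presyn_cells) {
  if (length(segs) == 0L) return(invisible(NULL))
  smask <- logical(tm$seg_n); smask[segs] <- TRUE
  idx <- which(smask[tm$d_seg[seq_len(tm$d_n)]])
  if (!length(idx)) return(invisible(NULL))
  pmask <- logical(tm$n_cells)
  if (length(presyn_cells)) pmask[presyn_cells + 1L] <- TRUE
  on <- pmask[tm$d_pre[idx] + 1L]
  tm$d_perm[idx] <- pmin(1, pmax(0, tm$d_perm[idx] +
    ifelse(on, tm$perm_inc, -tm$perm_dec)))
  invisible(NULL)
}

tm_punish_segments <- function(tm, segs) {
  if (length(segs) == 0L) return(invisible(NULL))
  smask <- logical(tm$seg_n); smask[segs] <- TRUE
  idx <- which(smask[tm$d_seg[seq_len(tm$d_n)]])
  tm$d_perm[idx] <- pmax(0, tm$d_perm[idx] - tm$perm_punish)
  invisible(NULL)
}

tm_adapt_apical <- function(tm, segs, presyn_bits) {
  if (length(segs) == 0L) return(invisible(NULL))
  smask <- logical(tm$aseg_n); smask[segs] <- TRUE
  idx <- which(smask[tm$a_seg[seq_len(tm$a_n)]])
  if (!length(idx)) return(invisible(NULL))
  pmask <- logical(tm$apical_space)
  if (length(presyn_bits)) pmask[presyn_bits + 1L] <- TRUE
  on <- pmask[tm$a_pre[idx] + 1L]
  tm$a_perm[idx] <- pmin(1, pmax(0, tm$a_perm[idx] +
    ifelse(on, tm$perm_inc, -tm$perm_dec)))
  invisible(NULL)
}

#' Advance the temporal memory by one input pattern
#'
#' @param tm a [temporal_memory].
#' @param active_columns [sdr] over the column space: the current feedforward
#'   pattern.
#' @param apical_input optional [sdr] over the apical space (top-down
#'   feedback); it biases the prediction for the next step.
#' @param learn apply segment growth and Hebbian updates.
#' @return A list of class `"tm_step"` with `active_cells`, `active_columns`,
#'   `predicted_columns` (prediction for the next step), `anomaly` and
#'   `confidence`.
#' @export
tm_compute <- function(tm, active_columns, apical_input = NULL, learn = TRUE) {
  if (active_columns$n != tm$n_cols)
    stop("active_columns is over a different column space")
  cols <- active_columns$active
  M <- tm$cells
  prev_active <- tm$active_cells
  prev_winners <- tm$winner_cells
  pred_cells <- tm$pred_cells
  pred_cols <- tm$pred_cols

  anomaly <- if (length(pred_cols) == 0L || length(cols) == 0L) 1 else
    1 - length(intersect(cols, pred_cols)) / length(cols)

  pmask <- logical(tm$n_cells)
  if (length(pred_cells)) pmask[pred_cells + 1L] <- TRUE
  active_cells <- integer(0); winners <- integer(0); burst_cols <- integer(0)
  for (j in cols) {
    cellrange <- (j * M):(j * M + M - 1L)
    pc <- cellrange[pmask[cellrange + 1L]]
    if (length(pc)) {
      active_cells <- c(active_cells, pc)
      winners <- c(winners, pc)
    } else {
      active_cells <- c(active_cells, cellrange)
      segc <- tm$cell_seg_count[cellrange + 1L]
      w <- cellrange[order(segc, -tm$cell_priority[cellrange + 1L])][1L]
      winners <- c(winners, w)
      burst_cols <- c(burst_cols, j)
    }
  }

  if (learn) {
    # reinforce segments whose prediction came true; punish the rest
    if (length(tm$pred_segs)) {
      owner_col <- tm$seg_cell[tm$pred_segs] %/% M
      correct <- tm$pred_segs[owner_col %in% cols]
      wrong <- setdiff(tm$pred_segs, correct)
      tm_adapt_segments(tm, correct, prev_active)
      tm_punish_segments(tm, wrong)
    }
    if (length(tm$apred_segs)) {
      owner_col <- tm$aseg_cell[tm$apred_segs] %/% M
      correct <- tm$apred_segs[owner_col %in% cols]
      tm_adapt_apical(tm, correct, if (is.null(tm$prev_apical)) integer(0)
                      else tm$prev_apical$active)
    }
    # bursting columns grow a distal segment on the least-used cell
    if (length(burst_cols) && length(prev_winners)) {
      bmask <- logical(tm$n_cols); bmask[burst_cols + 1L] <- TRUE
      for (w in winners[bmask[(winners %/% M) + 1L]])
        tm_grow_segment(tm, w, prev_winners)
    }
    # apical growth: wire current winners to the previous feedback pattern
    if (tm$apical_enabled && !is.null(tm$prev_apical) &&
        length(tm$prev_apical$active) && length(burst_cols)) {
      bmask <- logical(tm$n_cols); bmask[burst_cols + 1L] <- TRUE
      for (w in winners[bmask[(winners %/% M) + 1L]])
        tm_grow_apical_segment(tm, w, tm$prev_apical$active)
    }
  }

  # prediction for the next step
  asegs <- tm_active_segments(tm, active_cells)
  apsegs <- if (tm$apical_enabled && !is.null(apical_input))
    tm_active_apical_segments(tm, apical_input$active) else integer(0)
  pred_next_cells <- unique(c(
    if (length(asegs)) tm$seg_cell[asegs] else integer(0),
    if (length(apsegs)) tm$aseg_cell[apsegs] else integer(0)))
  pred_next_cols <- sort.int(unique(pred_next_cells %/% M))
  confidence <- min(1, length(pred_next_cols) / tm$expected_sparsity)

  tm$active_cells <- active_cells
  tm$winner_cells <- winners
  tm$pred_cells <- pred_next_cells
  tm$pred_cols <- pred_next_cols
  tm$pred_segs <- asegs
  tm$apred_segs <- apsegs
  tm$prev_apical <- apical_input

  structure(list(
    active_cells = new_sdr(active_cells, n = tm$n_cells),
    active_columns = active_columns,
    predicted_columns = new_sdr(pred_next_cols, n = tm$n_cols),
    anomaly = anomaly,
    confidence = confidence), class = "tm_step")
}

#' Pure one-step prediction (superposition query)
#'
#' Computes which columns the layer would predict next given an arbitrary set
#' of active cells, without learning and without touching the layer state.
#' Because segments activate independently, querying the union of several
#' states' cells yields the superposition (union) of their individual
#' predictions.
#'
#' @param tm a [temporal_memory].
#' @param active_cells [sdr] over the cell space.
#' @return List with `predicted_columns` ([sdr] over columns),
#'   `predicted_cells` ([sdr] over cells) and `segments` (integer ids of the
#'   active distal segments, usable with [tm_segment_columns()]).
#' @export
tm_predict <- function(tm, active_cells) {
  if (active_cells$n != tm$n_cells)
    stop("active_cells is over a different cell space")
  asegs <- tm_active_segments(tm, active_cells$active)
  cells <- if (length(asegs)) sort.int(unique(tm$seg_cell[asegs]))
           else integer(0)
  list(predicted_columns = new_sdr(sort.int(unique(cells %/% tm$cells)),
                                   n = tm$n_cols),
       predicted_cells = new_sdr(cells, n = tm$n_cells),
       segments = asegs)
}

#' Inject top-down feedback into the pending prediction
#'
#' Activates the layer's apical segments with the given feedback pattern and
#' unions their owner cells into the pending prediction, resolving a stalled
#' (empty) prediction when the feedback names a learned continuation. The
#' pattern is also stored as the previous apical input, so segment growth on
#' the next step wires the actually-arriving pattern to this feedback.
#'
#' @param tm a [temporal_memory] with `apical_enabled`.
#' @param apical_sdr [sdr] over the apical space (e.g. from
#'   [feedback_resolve()]); `NULL` is a no-op.
#' @return The updated confidence (`min(1, predicted_columns /
#'   expected_sparsity)`), invisibly.
#' @export
tm_apical_boost <- function(tm, apical_sdr) {
  if (is.null(apical_sdr) || !tm$apical_enabled)
    return(invisible(min(1, length(tm$pred_cols) / tm$expected_sparsity)))
  asegs <- tm_active_apical_segments(tm, apical_sdr$active)
  if (length(asegs)) {
    cells <- unique(c(tm$pred_cells, tm$aseg_cell[asegs]))
    tm$pred_cells <- cells
    tm$pred_cols <- sort.int(unique(cells %/% tm$cells))
    tm$apred_segs <- unique(c(tm$apred_segs, asegs))
  }
  tm$prev_apical <- apical_sdr
  invisible(min(1, length(tm$pred_cols) / tm$expected_sparsity))
}

#' Presynaptic columns of distal segments
#'
#' @param tm a [temporal_memory].
#' @param segments integer segment ids.
#' @return List (one element per segment) of 0-based presynaptic column index
#'   vectors.
#' @export
tm_segment_columns <- function(tm, segments) {
  if (!length(segments)) return(list())
  idx <- seq_len(tm$d_n)
  keep <- tm$d_seg[idx] %in% segments
  pre_col <- tm$d_pre[idx][keep] %/% tm$cells
  seg_of <- tm$d_seg[idx][keep]
  out <- split(pre_col, factor(seg_of, levels = segments))
  lapply(out, unique)
}

#' Owner columns of distal segments
#' @param tm a [temporal_memory].
#' @param segments integer segment ids.
#' @return 0-based column index of each segment's owner cell.
#' @export
tm_segment_owner_columns <- function(tm, segments) {
  tm$seg_cell[segments] %/% tm$cells
}

#' Snapshot / restore a temporal memory
#'
#' `tm_state()` returns a plain list with every field of the layer (synapse
#' arrays, segment tables, step context), suitable for JSON/RDS checkpoints;
#' `tm_restore()` rebuilds a layer from such a list.
#'
#' @param tm a [temporal_memory].
#' @return `tm_state()`: a named list; `tm_restore()`: a [temporal_memory].
#' @export
tm_state <- function(tm) {
  nm <- ls(tm, all.names = TRUE)
  stats::setNames(mget(nm, envir = tm), nm)
}

#' @rdname tm_state
#' @param state a list from [tm_state()].
#' @export
tm_restore <- function(state) {
  tm <- new.env(parent = emptyenv())
  for (nm in names(state)) assign(nm, state[[nm]], envir = tm)
  class(tm) <- "temporal_memory"
  tm
}
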