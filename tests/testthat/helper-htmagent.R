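# Shared test helpers.

# Disjoint SDR vocabulary: k patterns of m bits each over n bits.
disjoint_sdrs <- function(k, m, n = k * m) {
  lapply(0:(k - 1L), function(i) sdr((i * m):((i + 1L) * m - 1L), n = n))
}

# Fixed per-cell random state codes for a maze (seeded, pairwise checked).
maze_codes <- function(maze, k = 300, m = 10, seed = 7) {
  fc <- maze_floor_cells(maze)
  set.seed(seed)
  codes <- lapply(seq_len(nrow(fc)), function(i) random_sdr(k, m))
  names(codes) <- paste(fc[, 1L], fc[, 2L])
  codes
}

code_of <- function(codes, pos) codes[[paste(pos[1L], pos[2L])]]

# Train an empowerment estimator on every transition of a maze, `reps` times.
train_em_full <- function(em, maze, codes, reps = 10) {
  fc <- maze_floor_cells(maze)
  for (r in seq_len(reps))
    for (i in seq_len(nrow(fc)))
      for (a in 0:3) {
        p <- fc[i, ]
        q <- maze_move(maze, p, a)
        em_learn(em, code_of(codes, p), code_of(codes, q))
      }
  invisible(em)
}

# Exact terminal-state path counts by direct |A|^n enumeration.
enumerate_counts <- function(maze, pos, n) {
  counts <- new.env(parent = emptyenv())
  rec <- function(p, d) {
    if (d == 0L) {
      k <- paste(p[1L], p[2L])
      assign(k, (if (exists(k, counts)) get(k, counts) else 0) + 1, counts)
      return(invisible(NULL))
    }
    for (a in 0:3) rec(maze_move(maze, p, a), d - 1L)
  }
  rec(as.integer(pos), as.integer(n))
  unlist(as.list(counts))
}
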