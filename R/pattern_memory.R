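#' Pattern memory: online clustering of SDRs
#'
#' Stores the vocabulary of patterns an encoder has emitted, as clusters. Each
#' cluster keeps a per-bit density vector `chi` in `[0,1]^k_in` (the
#' probability that each bit belongs to the cluster) and a representation: the
#' `pattern_size` highest-density bits (ties by ascending index). An incoming
#' SDR `s` is compared to every cluster by the scalar-product similarity
#' `sum_{j in s} chi[j]`; if the best similarity strictly exceeds `theta` the
#' winning cluster's density moves toward the indicator of `s` by an
#' exponential moving average with rate `density_rate`, otherwise a new cluster
#' is created with `chi = indicator(s)`.
#'
#' @param k_in dimension of the input SDR space.
#' @param pattern_size representation size `m` (normally the output sparsity of
#'   the feeding spatial pooler).
#' @param theta similarity threshold; default `0.5 * pattern_size`, the point
#'   at which two stored patterns start to interfere.
#' @param density_rate EMA rate for the density update.
#' @return An object of class `"pattern_memory"` (an environment).
#' @export
pattern_memory <- function(k_in, pattern_size,
                           theta = 0.5 * pattern_size,
                           density_rate = 0.1) {
  pm <- new.env(parent = emptyenv())
  pm$k_in <- as.integer(k_in)
  pm$pattern_size <- as.integer(pattern_size)
  pm$theta <- theta
  pm$density_rate <- density_rate
  pm$density <- matrix(numeric(0), nrow = 0, ncol = k_in)
  pm$hit_count <- integer(0)
  pm$n_clusters <- 0L
  class(pm) <- "pattern_memory"
  pm
}

#' @export
print.pattern_memory <- function(x, ...) {
  cat(sprintf("<pattern_memory> %d clusters over %d bits (theta=%.2f)\n",
              x$n_clusters, x$k_in, x$theta))
  invisible(x)
}

#' Similarity between an SDR and stored clusters
#'
#' The scalar product of the SDR with a cluster's density:
#' `sum over active bits j of chi[j]`.
#'
#' @param pm a [pattern_memory].
#' @param s an [sdr] over the `k_in` space.
#' @param id cluster id; if `NULL`, similarities to all clusters are returned.
#' @return Numeric similarity (or vector over all clusters).
#' @export
pm_similarity <- function(pm, s, id = NULL) {
  if (s$n != pm$k_in) stop("SDR dimension mismatch with pattern memory")
  if (pm$n_clusters == 0L)
    return(if (is.null(id)) numeric(0) else stop("no such cluster"))
  sims <- if (length(s$active))
    rowSums(pm$density[, s$active + 1L, drop = FALSE]) else
    numeric(pm$n_clusters)
  if (is.null(id)) sims else sims[[id]]
}

pm_representation_from_density <- function(chi, m) {
  ord <- order(-chi, seq_along(chi))
  top <- ord[seq_len(min(m, length(chi)))]
  sort.int(top[chi[top] > 0] - 1L)
}

#' Representation SDR of a cluster
#' @param pm a [pattern_memory].
#' @param id cluster id.
#' @return [sdr]: the `pattern_size` highest-density bits of the cluster.
#' @export
pm_representation <- function(pm, id) {
  if (id < 1L || id > pm$n_clusters) stop("no such cluster")
  sdr(pm_representation_from_density(pm$density[id, ], pm$pattern_size),
      n = pm$k_in)
}

#' Assign an SDR to a cluster (creating one if needed)
#'
#' @param pm a [pattern_memory].
#' @param s a non-empty [sdr] over the `k_in` space.
#' @return The id (integer, stable across the memory's lifetime) of the
#'   updated or newly created cluster.
#' @export
pm_update <- function(pm, s) {
  if (!length(s$active)) stop("cannot cluster an empty SDR")
  sims <- pm_similarity(pm, s)
  best <- if (length(sims)) which.max(sims) else integer(0)
  if (length(best) && sims[best] > pm$theta) {
    rho <- pm$density_rate
    ind <- numeric(pm$k_in); ind[s$active + 1L] <- 1
    pm$density[best, ] <- (1 - rho) * pm$density[best, ] + rho * ind
    pm$hit_count[best] <- pm$hit_count[best] + 1L
    return(best)
  }
  chi <- numeric(pm$k_in); chi[s$active + 1L] <- 1
  pm$density <- rbind(pm$density, chi, deparse.level = 0)
  pm$hit_count <- c(pm$hit_count, 1L)
  pm$n_clusters <- pm$n_clusters + 1L
  pm$n_clusters
}

#' Pattern completion
#'
#' Returns the representation of the best-matching stored cluster if its
#' similarity strictly exceeds `theta`, else `NULL`. Never mutates the memory.
#' Used during imagined rollouts to snap a noisy predicted pattern back onto a
#' known state.
#'
#' @param pm a [pattern_memory].
#' @param s an [sdr].
#' @return An [sdr] or `NULL`.
#' @export
pm_complete <- function(pm, s) {
  if (pm$n_clusters == 0L) return(NULL)
  sims <- pm_similarity(pm, s)
  best <- which.max(sims)
  if (sims[best] > pm$theta) pm_representation(pm, best) else NULL
}

#' Export clusters as a plain list (JSON-ready)
#'
#' @param pm a [pattern_memory].
#' @param path optional file; when given (and `jsonlite` is installed) the
#'   clusters are written as JSON.
#' @return List with one element per cluster: `id`, `density`, `hit_count`,
#'   `representation` (0-based active indices).
#' @export
pm_export <- function(pm, path = NULL) {
  out <- lapply(seq_len(pm$n_clusters), function(i) list(
    id = i,
    density = unname(pm$density[i, ]),
    hit_count = pm$hit_count[i],
    representation = pm_representation(pm, i)$active))
  if (!is.null(path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to write JSON cluster dumps")
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Pairwise cluster similarity matrix
#'
#' Entry `[i, j]` is the similarity of cluster `i`'s representation against
#' cluster `j`'s density. For a well-separated vocabulary the matrix is
#' diagonally dominant; off-diagonal values approaching `theta` flag clusters
#' whose visit statistics will interfere during empowerment masking.
#'
#' @param pm a [pattern_memory].
#' @param path optional CSV file to write the matrix to.
#' @return Numeric matrix `n_clusters x n_clusters`.
#' @export
pm_similarity_matrix <- function(pm, path = NULL) {
  n <- pm$n_clusters
  m <- matrix(0, n, n)
  for (i in seq_len(n))
    m[i, ] <- pm_similarity(pm, pm_representation(pm, i))
  if (!is.null(path))
    utils::write.csv(m, path, row.names = FALSE)
  m
}
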