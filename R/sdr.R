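#' Sparse distributed representations (SDRs)
#'
#' An SDR is a fixed-dimension binary vector stored sparsely as the ordered set
#' of its active (one) bit indices. Indices are 0-based and must lie in
#' `[0, n)`. SDRs are the common currency between all modules: encoder outputs,
#' memory states, striatal stimuli and responses are all SDRs. Equality is set
#' equality, independent of the order indices were supplied in.
#'
#' @param active integer vector of active bit indices (0-based), duplicates
#'   removed, sorted on construction.
#' @param n positive integer, the dimension of the binary space.
#' @return An object of class `"sdr"`: a list with elements `n` and `active`.
#' @examples
#' a <- sdr(c(1, 3, 5), n = 10)
#' b <- sdr(c(3, 5, 7), n = 10)
#' sdr_overlap(a, b) # 2
#' @export
sdr <- function(active = integer(), n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n <= 0L)
    stop("`n` must be a single positive integer")
  active <- as.integer(active)
  if (anyNA(active)) stop("active indices must not contain NA")
  active <- sort.int(unique(active))
  if (length(active) && (active[1L] < 0L || active[length(active)] >= n))
    stop("active indices must lie in [0, n)")
  structure(list(n = n, active = active), class = "sdr")
}

#' @export
print.sdr <- function(x, ...) {
  cat(sprintf("<sdr> %d/%d active: %s\n", length(x$active), x$n,
              paste(utils::head(x$active, 20L), collapse = ",")))
  invisible(x)
}

#' @export
`==.sdr` <- function(e1, e2) {
  e1$n == e2$n && length(e1$active) == length(e2$active) &&
    all(e1$active == e2$active)
}

is_sdr <- function(x) inherits(x, "sdr")

# internal trusted constructor: `active` must already be sorted, unique,
# integer and in range — used on hot paths where that is guaranteed
new_sdr <- function(active, n) {
  structure(list(n = n, active = active), class = "sdr")
}

check_same_space <- function(a, b) {
  if (a$n != b$n)
    stop(sprintf("incompatible SDR spaces: %d vs %d", a$n, b$n))
}

#' Number of active bits of an SDR
#' @param x an [sdr].
#' @return Integer count of active bits.
#' @export
sdr_size <- function(x) length(x$active)

#' Overlap (set intersection size) of two SDRs
#'
#' The dot product of the dense binary vectors; a semantically meaningful
#' similarity between SDRs.
#'
#' @param a,b [sdr] objects over the same space.
#' @return Non-negative integer `|a.active n b.active|`.
#' @export
sdr_overlap <- function(a, b) {
  check_same_space(a, b)
  length(intersect(a$active, b$active))
}

#' Union of two SDRs
#' @param a,b [sdr] objects over the same space.
#' @return [sdr] whose active set is the union of the inputs' active sets.
#' @export
sdr_union <- function(a, b) {
  check_same_space(a, b)
  sdr(union(a$active, b$active), n = a$n)
}

#' Complement of an SDR
#' @param a an [sdr].
#' @return [sdr] active exactly on the bits where `a` is inactive.
#' @export
sdr_complement <- function(a) {
  sdr(setdiff(0:(a$n - 1L), a$active), n = a$n)
}

#' Convert an SDR to a dense 0/1 integer vector
#' @param a an [sdr].
#' @return Integer vector of length `a$n` with ones at the active indices.
#' @export
sdr_dense <- function(a) {
  v <- integer(a$n)
  v[a$active + 1L] <- 1L
  v
}

#' Build an SDR from a dense binary vector
#' @param v numeric/integer/logical vector; nonzero entries become active bits.
#' @return An [sdr] of dimension `length(v)`.
#' @export
sdr_from_dense <- function(v) {
  sdr(which(v != 0) - 1L, n = length(v))
}

#' Read / write SDR fixture files
#'
#' One SDR per line in the plain-text format `"n: i1,i2,..."` (0-based
#' indices; an empty index list encodes the empty SDR). The format is diffable
#' and is used for small test fixtures.
#'
#' @param path file path.
#' @return `read_sdr_file()` returns a list of [sdr] objects.
#' @export
read_sdr_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    n <- as.integer(trimws(parts[1L]))
    idx <- if (length(parts) < 2L || !nzchar(trimws(parts[2L]))) integer()
           else as.integer(strsplit(trimws(parts[2L]), ",", fixed = TRUE)[[1L]])
    sdr(idx, n = n)
  })
}

#' @rdname read_sdr_file
#' @param x list of [sdr] objects to write.
#' @export
write_sdr_file <- function(x, path) {
  lines <- vapply(x, function(s)
    sprintf("%d: %s", s$n, paste(s$active, collapse = ",")), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Random SDR with a fixed number of active bits
#'
#' Draws `k` distinct active indices uniformly from `[0, n)` using the current
#' RNG state; useful for building synthetic pattern vocabularies.
#'
#' @param n space dimension.
#' @param k number of active bits.
#' @return An [sdr].
#' @export
random_sdr <- function(n, k) {
  sdr(sample.int(n, k) - 1L, n = n)
}
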