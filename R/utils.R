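#' Canonical edge ordering of an undirected graph on `n` nodes
#'
#' Every edge-vector representation in this package uses the same total order
#' on region pairs: all pairs `(i, j)` with `i < j`, sorted first by `i`, then
#' by `j` (row-major traversal of the upper triangle). This is the ordering
#' written to and read from all edge-list files.
#'
#' @param n Number of regions (nodes); must be >= 2.
#' @return Integer matrix with `n * (n - 1) / 2` rows and columns `i`, `j`.
#' @examples
#' edge_pairs(4)
#' @export
edge_pairs <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) {
    stop("edge_pairs() needs at least 2 regions, got ", n)
  }
  lens <- rev(seq_len(n - 1L))
  cbind(
    i = rep.int(seq_len(n - 1L), lens),
    j = sequence(lens, from = seq.int(2L, n))
  )
}

#' Map (i, j) pairs to positions in the canonical edge order
#'
#' Inverse of [edge_pairs()]: for pairs with `i < j` on `n` nodes, returns the
#' row index each pair occupies in `edge_pairs(n)`.
#'
#' @param i,j Integer vectors of node indices, `i < j`.
#' @param n Number of nodes.
#' @return Integer vector of edge positions.
#' @export
edge_id <- function(i, j, n) {
  stopifnot(all(i >= 1L), all(j <= n), all(i < j))
  # edges before row block i: sum_{k<i} (n - k)
  as.integer((i - 1L) * n - i * (i - 1L) / 2 + (j - i))
}

# Derive a bounded child seed from a base seed and a stream index.
# Keeps results inside the 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647)
}

# Min-max scale a numeric vector to [0, 1] within groups; constant groups
# map to 0.5 (no information), NA preserved.
minmax_by <- function(x, group) {
  out <- rep(NA_real_, length(x))
  for (g in unique(group)) {
    idx <- which(group == g & !is.na(x))
    if (!length(idx)) next
    rng <- range(x[idx])
    out[idx] <- if (diff(rng) == 0) 0.5 else (x[idx] - rng[1]) / diff(rng)
  }
  out
}

# Clip correlations away from +/-1 before arctanh.
clip_r <- function(r, eps = 1e-7) {
  pmin(pmax(r, -1 + eps), 1 - eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable integer seed derived from a character id (e.g. a subject or
# dataset name), so the same id maps to the same random stream everywhere.
string_seed <- function(s) {
  v <- utf8ToInt(s)
  as.integer(sum(v * (seq_along(v) %% 7L + 1L) * 131) %% 1000003L)
}
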