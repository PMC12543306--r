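#' Node strength of a weighted network
#'
#' Strength of region `i` is the sum of its weighted connections,
#' `sum_j w_ij` over `j != i`. When a region/network label table is given,
#' region and canonical-network names are attached.
#'
#' @param network A `"weighted_network"` or a square symmetric matrix.
#' @param labels Optional label table as read by [read_network_labels()]
#'   (columns `region_id` 0-based, `region_name`, `network_name`).
#' @return Data frame with `region_id` (0-based), `region_name`,
#'   `network_name` (NA when unlabeled), `strength`.
#' @export
node_strength <- function(network, labels = NULL) {
  m <- weight_matrix(network)
  diag(m) <- 0
  strength <- rowSums(m)
  out <- data.frame(
    region_id = seq_len(nrow(m)) - 1L,
    region_name = rownames(m) %||% sprintf("region_%03d", seq_len(nrow(m))),
    network_name = NA_character_,
    strength = unname(strength)
  )
  if (!is.null(labels)) {
    out$network_name <- labels$network_name[match(out$region_id,
                                                  labels$region_id)]
    named <- labels$region_name[match(out$region_id, labels$region_id)]
    out$region_name <- ifelse(is.na(named), out$region_name, named)
  }
  out
}

#' Aggregate edge weights into canonical-network blocks
#'
#' Block `(a, b)` sums the weights of all edges with one endpoint in
#' network `a` and the other in network `b`; with `normalize = TRUE` each
#' block is divided by the number of possible edges between (or within) the
#' two networks, giving a density-corrected mean edge weight.
#'
#' @param network A `"weighted_network"` or square symmetric matrix.
#' @param labels Label table (columns `region_id` 0-based, `network_name`);
#'   every region must be labeled.
#' @param normalize Divide block sums by the block's possible edge count?
#' @return Symmetric network-by-network matrix.
#' @export
aggregate_by_network <- function(network, labels, normalize = FALSE) {
  m <- weight_matrix(network)
  diag(m) <- 0
  n <- nrow(m)
  net <- labels$network_name[match(seq_len(n) - 1L, labels$region_id)]
  if (anyNA(net)) {
    stop("unlabeled region(s): ",
         paste(which(is.na(net)) - 1L, collapse = ", "))
  }
  nets <- sort(unique(net))
  sizes <- table(factor(net, nets))
  block <- matrix(0, length(nets), length(nets), dimnames = list(nets, nets))
  pairs <- edge_pairs(n)
  w <- m[pairs]
  na <- factor(net[pairs[, 1]], nets)
  nb <- factor(net[pairs[, 2]], nets)
  for (k in which(w != 0)) {
    block[na[k], nb[k]] <- block[na[k], nb[k]] + w[k]
    if (na[k] != nb[k]) block[nb[k], na[k]] <- block[nb[k], na[k]] + w[k]
  }
  if (normalize) {
    possible <- outer(as.numeric(sizes), as.numeric(sizes))
    diag(possible) <- as.numeric(sizes) * (as.numeric(sizes) - 1) / 2
    possible[possible == 0] <- NA
    block <- block / possible
  }
  block
}

#' Top edges of a weighted network
#'
#' Returns the `ceiling(fraction * n_possible)` highest-weight edges in
#' descending weight order, with ties broken by canonical edge index.
#'
#' @param network A `"weighted_network"` or square symmetric matrix.
#' @param fraction Fraction of all possible edges to keep, in (0, 1].
#' @return Data frame with `i`, `j`, `edge_id`, `weight`, sorted by
#'   descending weight.
#' @export
top_edges <- function(network, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  m <- weight_matrix(network)
  n <- nrow(m)
  pairs <- edge_pairs(n)
  w <- m[pairs]
  n_keep <- ceiling(fraction * length(w))
  ord <- order(-w, seq_along(w))[seq_len(n_keep)]
  data.frame(i = pairs[ord, 1], j = pairs[ord, 2], edge_id = ord,
             weight = w[ord])
}

# Extract the square symmetric weight matrix behind either input form.
weight_matrix <- function(network) {
  m <- if (inherits(network, "weighted_network")) {
    network$matrix
  } else {
    as.matrix(network)
  }
  if (nrow(m) != ncol(m)) stop("weight matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("weight matrix must be symmetric")
  m
}
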