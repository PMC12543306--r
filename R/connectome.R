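#' Construct a connectome object from a symmetric correlation matrix
#'
#' @param matrix Symmetric numeric matrix of region-by-region correlations.
#' @param labels Character vector of region labels (defaults to the matrix
#'   dimnames or `region_###`).
#' @return Object of class `"connectome"` with fields `labels` and `matrix`.
#' @export
connectome <- function(matrix, labels = NULL) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("connectome matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("connectome matrix must be symmetric")
  m <- (m + t(m)) / 2
  labels <- labels %||% rownames(m) %||% sprintf("region_%03d", seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  structure(list(labels = labels, matrix = m), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", length(x$labels), " regions, ",
      length(x$labels) * (length(x$labels) - 1) / 2, " edges\n", sep = "")
  invisible(x)
}

#' Flatten a connectome to its canonical edge vector
#'
#' Extracts the upper triangle (diagonal excluded) in the package's canonical
#' row-major `(i < j)` order; see [edge_pairs()].
#'
#' @param x A `"connectome"` or a square symmetric matrix.
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @export
vectorize <- function(x) {
  m <- if (inherits(x, "connectome")) x$matrix else as.matrix(x)
  m[edge_pairs(nrow(m))]
}

#' Rebuild a connectome from an edge vector
#'
#' Inverse of [vectorize()]: places the edge vector into both triangles of a
#' square matrix with unit diagonal.
#'
#' @param edges Numeric edge vector in canonical order.
#' @param labels Region labels; their number fixes the matrix size.
#' @param diag Diagonal value (default 1, a self-correlation).
#' @return A `"connectome"`.
#' @export
unvectorize <- function(edges, labels, diag = 1) {
  n <- length(labels)
  if (length(edges) != n * (n - 1) / 2) {
    stop("edge vector length ", length(edges), " does not match ",
         n * (n - 1) / 2, " for ", n, " regions")
  }
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  idx <- edge_pairs(n)
  m[idx] <- edges
  m[idx[, c(2, 1)]] <- edges
  diag(m) <- diag
  structure(list(labels = labels, matrix = m), class = "connectome")
}

#' Append backward-difference temporal derivatives to a confound table
#'
#' The derivative of each column is its first-order backward difference with
#' 0 in the first row, matching the fMRIPrep `*_derivative1` convention.
#'
#' @param confounds Data frame or matrix of confound time series.
#' @return Data frame with the original columns plus `<name>_derivative1`.
#' @export
add_temporal_derivatives <- function(confounds) {
  cf <- as.data.frame(confounds)
  der <- lapply(cf, function(x) c(0, diff(x)))
  names(der) <- paste0(names(cf), "_derivative1")
  cbind(cf, as.data.frame(der))
}

#' Estimate a functional connectome from parcellated BOLD time series
#'
#' Each region's time series is residualized against the confound columns by
#' ordinary least squares (with intercept), standardized to zero mean and
#' unit variance, and then correlated pairwise (Pearson). The result is
#' symmetrized by averaging with its transpose and given a unit diagonal.
#' Multiple runs of one session may be passed as lists: each run is
#' residualized against its own confounds, residuals are concatenated, and
#' correlation is computed once over the concatenated series.
#'
#' Exactly collinear confound columns are dropped (with a warning) before
#' fitting; an optional 0/1 `censor` vector drops flagged volumes (e.g. high
#' framewise displacement) before regression.
#'
#' @param series Timepoints-by-regions matrix/data frame, or a list of such
#'   matrices (one per run).
#' @param confounds Timepoints-by-k confound matrix/data frame (or list,
#'   matching `series`); `NULL` or zero columns means intercept-only
#'   (mean removal).
#' @param censor Optional 0/1 vector (or list) flagging volumes to drop
#'   (1 = drop).
#' @return A `"connectome"`.
#' @export
timeseries_to_connectome <- function(series, confounds = NULL, censor = NULL) {
  if (is.list(series) && !is.data.frame(series)) {
    runs <- seq_along(series)
    conf_list <- if (is.null(confounds)) vector("list", length(runs)) else confounds
    cens_list <- if (is.null(censor)) vector("list", length(runs)) else censor
    res <- lapply(runs, function(r)
      residualize_run(series[[r]], conf_list[[r]], cens_list[[r]]))
    labels <- colnames(as.matrix(series[[1]])) %||%
      sprintf("region_%03d", seq_len(ncol(as.matrix(series[[1]]))))
    resid <- do.call(rbind, res)
  } else {
    resid <- residualize_run(series, confounds, censor)
    labels <- colnames(as.matrix(series)) %||%
      sprintf("region_%03d", seq_len(ncol(as.matrix(series))))
  }
  resid <- scale(resid)  # standardize each region's residual series
  r <- stats::cor(resid)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  connectome(r, labels)
}

# Residualize every region in one run against the run's confounds.
residualize_run <- function(series, confounds, censor = NULL) {
  y <- as.matrix(series)
  if (anyNA(y)) stop("time series contain missing values")
  if (!is.null(censor)) {
    keep <- !(as.numeric(censor) > 0)
    y <- y[keep, , drop = FALSE]
    confounds <- if (!is.null(confounds)) {
      as.matrix(confounds)[keep, , drop = FALSE]
    }
  }
  k <- if (is.null(confounds)) 0L else ncol(as.matrix(confounds))
  if (nrow(y) < k + 2L) {
    stop("too few timepoints (", nrow(y), ") for ", k, " confounds")
  }
  x <- cbind(intercept = 1, if (k > 0) as.matrix(confounds))
  if (ncol(x) > 1L) {
    qrx <- qr(x)
    if (qrx$rank < ncol(x)) {
      drop <- qrx$pivot[seq.int(qrx$rank + 1L, ncol(x))]
      warning("dropping exactly-collinear confound column(s): ",
              paste(colnames(x)[drop], collapse = ", "))
      x <- x[, -drop, drop = FALSE]
      qrx <- qr(x)
    }
    y - x %*% qr.coef(qrx, y)
  } else {
    scale(y, scale = FALSE)
  }
}
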