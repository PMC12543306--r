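#' Configuration for cross-validated network-based predictive modeling
#'
#' @param outcome One of `"hc"` (hormonal-contraceptive use, classified by
#'   L2-logistic regression), `"e2"` or `"p4"` (hormone concentration,
#'   predicted by ridge regression).
#' @param n_folds Outer cross-validation folds (default 5).
#' @param n_iterations Number of resampled cross-validation repetitions
#'   (default 1000).
#' @param p_threshold Edge-level p-value threshold for component selection
#'   (default 0.05).
#' @param alpha_grid Candidate L2 penalties; default 20 log-spaced points on
#'   `[1e-4, 10]`.
#' @param retain_fraction Fraction of positively weighted edges kept when
#'   thresholding the performance-weighted network (default 0.5).
#' @param covariates Confounds regressed from the edges (and, for hormone
#'   outcomes, from the outcome): subset of `c("fd", "hc")`. `"hc"` is
#'   ignored for the HC outcome, which is never residualized on itself.
#' @param inner_folds Inner folds for the penalty search (default 3).
#' @param scale_outcome Min-max scale hormone outcomes to `[0, 1]` within
#'   dataset before modeling (default `TRUE`); HC use is always 0/1.
#' @param seed Integer seed; the full discovery run is deterministic given
#'   the config.
#' @return List of class `"cv_config"`.
#' @export
cv_config <- function(outcome = c("hc", "e2", "p4"), n_folds = 5L,
                      n_iterations = 1000L, p_threshold = 0.05,
                      alpha_grid = 10^seq(-4, 1, length.out = 20),
                      retain_fraction = 0.5, covariates = "fd",
                      inner_folds = 3L, scale_outcome = TRUE, seed = 1L) {
  outcome <- match.arg(outcome)
  stopifnot(n_folds >= 2, p_threshold > 0, p_threshold < 1,
            retain_fraction > 0, retain_fraction <= 1,
            all(alpha_grid > 0), all(covariates %in% c("fd", "hc")))
  structure(
    list(outcome = outcome, n_folds = as.integer(n_folds),
         n_iterations = as.integer(n_iterations), p_threshold = p_threshold,
         alpha_grid = sort(as.numeric(alpha_grid)),
         retain_fraction = retain_fraction,
         covariates = unique(covariates), inner_folds = as.integer(inner_folds),
         scale_outcome = isTRUE(scale_outcome), seed = as.integer(seed)),
    class = "cv_config"
  )
}

# Assemble (edge matrix, outcome, covariate matrix, family) for a config,
# dropping sessions missing the modeled outcome.
prepare_outcome <- function(study, config) {
  sess <- study$sessions
  y_raw <- switch(config$outcome,
                  hc = sess$hc_use,
                  e2 = sess$e2,
                  p4 = sess$p4)
  keep <- !is.na(y_raw)
  if (!all(keep)) {
    message(sum(!keep), " session(s) without ", config$outcome, " excluded")
  }
  sess <- sess[keep, , drop = FALSE]
  family <- if (config$outcome == "hc") "binomial" else "gaussian"
  y <- if (family == "binomial") {
    as.numeric(y_raw[keep])
  } else if (config$scale_outcome) {
    minmax_by(y_raw[keep], sess$dataset_id)
  } else {
    y_raw[keep]
  }
  covars <- NULL
  if ("fd" %in% config$covariates) {
    covars <- cbind(covars, fd = sess$mean_fd)
  }
  if ("hc" %in% config$covariates && family == "gaussian") {
    covars <- cbind(covars, hc = as.numeric(sess$hc_use))
  }
  E <- edge_matrix(study)[keep, , drop = FALSE]
  list(edges = E, y = y, covars = covars, family = family,
       sessions = sess, keep = keep)
}

#' Residualize edges (and outcome) on confounds without test-set leakage
#'
#' Fits one ordinary-least-squares regression (with intercept) per edge of
#' the covariate matrix on the *training* rows only, then removes the fitted
#' confound contribution from *all* rows, so held-out rows are cleaned with
#' training-fitted coefficients. The outcome is residualized the same way
#' when `residualize_outcome` is `TRUE` (hormone outcomes); a binary HC
#' outcome is never residualized.
#'
#' @param edges Session-by-edge numeric matrix.
#' @param outcome Numeric outcome vector.
#' @param covars Covariate matrix (may be `NULL` for intercept-only, i.e.
#'   train-mean centering).
#' @param train Logical or integer index of training rows.
#' @param residualize_outcome Residualize the outcome too?
#' @return List with `edges`, `outcome` (residualized values for all rows),
#'   `coef_edges` ((q+1)-by-p coefficient matrix), `coef_outcome`, and
#'   `kept_covars` (names of covariate columns retained on the training
#'   rows; constants are dropped with a warning).
#' @export
residualize_confounds <- function(edges, outcome, covars, train,
                                  residualize_outcome = TRUE) {
  edges <- as.matrix(edges)
  if (is.logical(train)) train <- which(train)
  q0 <- if (is.null(covars)) 0L else ncol(as.matrix(covars))
  kept <- character(0)
  if (q0 > 0) {
    cv <- as.matrix(covars)
    if (is.null(colnames(cv))) colnames(cv) <- paste0("covar", seq_len(ncol(cv)))
    const <- apply(cv[train, , drop = FALSE], 2, function(x) stats::sd(x) == 0)
    if (any(const)) {
      warning("dropping constant covariate(s) on training rows: ",
              paste(colnames(cv)[const], collapse = ", "))
      cv <- cv[, !const, drop = FALSE]
    }
    kept <- colnames(cv)
    x <- cbind(intercept = 1, cv)
  } else {
    x <- matrix(1, nrow(edges), 1, dimnames = list(NULL, "intercept"))
  }
  qrx <- qr(x[train, , drop = FALSE])
  coef_edges <- qr.coef(qrx, edges[train, , drop = FALSE])
  res_edges <- edges - x %*% coef_edges
  coef_outcome <- NULL
  res_outcome <- outcome
  if (residualize_outcome) {
    coef_outcome <- drop(qr.coef(qrx, outcome[train]))
    res_outcome <- outcome - drop(x %*% coef_outcome)
  }
  list(edges = res_edges, outcome = res_outcome,
       coef_edges = coef_edges, coef_outcome = coef_outcome,
       kept_covars = kept)
}

#' Edge-wise F statistics for outcome association
#'
#' For every edge, the F statistic of the single-predictor linear regression
#' of the edge on the outcome, computed through the correlation identity
#' `F = r^2 (n - 2) / (1 - r^2)` with p-values from `F(1, n - 2)`. For a
#' binary outcome this equals the two-group one-way ANOVA F. Constant edges
#' get `F = 0`, `p = 1`.
#'
#' @param edges Session-by-edge matrix (typically residualized).
#' @param outcome Numeric outcome vector (must not be constant).
#' @return List with numeric vectors `F`, `p`, and `r` (one entry per edge).
#' @export
edgewise_association <- function(edges, outcome) {
  edges <- as.matrix(edges)
  n <- length(outcome)
  if (n < 3) stop("need >= 3 sessions for edge-wise tests")
  if (stats::sd(outcome) == 0) stop("outcome is constant")
  sds <- apply(edges, 2, stats::sd)
  r <- unname(suppressWarnings(drop(stats::cor(outcome, edges))))
  r[sds == 0] <- 0
  r2 <- pmin(r^2, 1 - 1e-12)
  f <- r2 * (n - 2) / (1 - r2)
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[sds == 0] <- 1
  f[sds == 0] <- 0
  list(F = f, p = p, r = r)
}

#' Largest connected component of suprathreshold edges
#'
#' Among edges with `p < p_threshold`, finds the connected component (nodes
#' linked directly or indirectly) containing the most edges and returns the
#' ids of its edges in canonical order. Returns an empty set when no edge
#' passes. Ties between components of equal edge count are broken toward the
#' component containing the smallest node index.
#'
#' @param p_values Numeric vector of edge p-values in canonical edge order.
#' @param p_threshold Inclusion threshold.
#' @param n_regions Number of nodes in the graph.
#' @return Integer vector of canonical edge ids (possibly empty).
#' @export
largest_connected_component <- function(p_values, p_threshold, n_regions) {
  pairs <- edge_pairs(n_regions)
  if (length(p_values) != nrow(pairs)) {
    stop("expected ", nrow(pairs), " p-values for ", n_regions, " regions")
  }
  sup <- which(p_values < p_threshold)
  if (!length(sup)) return(integer(0))
  g <- igraph::graph_from_edgelist(pairs[sup, , drop = FALSE], directed = FALSE)
  comp <- igraph::components(g)
  edge_comp <- comp$membership[pairs[sup, 1]]
  counts <- tabulate(edge_comp, nbins = comp$no)
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    # tie: component whose smallest member node is smallest
    min_node <- vapply(best, function(cc)
      min(which(comp$membership == cc)), integer(1))
    best <- best[which.min(min_node)]
  }
  sort(sup[edge_comp == best])
}

# Performance of predictions vs truth: accuracy (binomial) or Spearman rho
# (gaussian); undefined rho (constant input) scores 0.
prediction_performance <- function(pred, truth, family) {
  if (family == "binomial") {
    mean(as.integer(pred > 0.5) == truth)
  } else {
    if (stats::sd(pred) == 0 || stats::sd(truth) == 0) return(0)
    stats::cor(pred, truth, method = "spearman")
  }
}

chance_level <- function(family) if (family == "binomial") 0.5 else 0

#' Fit a penalized model on a selected edge component with inner-CV penalty
#' choice
#'
#' Features are standardized on the supplied (training) rows; the L2 penalty
#' is chosen by inner cross-validation over `alpha_grid`, scoring accuracy
#' (binomial) or Spearman correlation (gaussian) and breaking ties toward
#' the smallest penalty; the winning penalty is then refit on all supplied
#' rows.
#'
#' @param x Training feature matrix (sessions by component edges), already
#'   residualized.
#' @param y Training outcome.
#' @param family `"binomial"` or `"gaussian"`.
#' @param alpha_grid Candidate penalties.
#' @param inner_folds Inner fold count (capped at `nrow(x)`).
#' @param seed Integer seed for the inner fold shuffle.
#' @return List of class `"component_fit"`: `beta`, `intercept`, `alpha`,
#'   `family`, `center`, `scale`, `alpha_performance` (mean inner score per
#'   candidate).
#' @export
fit_component_model <- function(x, y, family = c("gaussian", "binomial"),
                                alpha_grid = 10^seq(-4, 1, length.out = 20),
                                inner_folds = 3L, seed = 1L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  n <- nrow(x)
  if (!ncol(x)) stop("empty edge component")
  if (n < 2) stop("need >= 2 training sessions")
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  alpha_grid <- sort(alpha_grid)

  alpha_perf <- rep(NA_real_, length(alpha_grid))
  if (length(alpha_grid) > 1L) {
    k <- min(inner_folds, n)
    folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
    scores <- matrix(NA_real_, k, length(alpha_grid))
    for (f in seq_len(k)) {
      tr <- folds != f
      if (sum(tr) < 2 || (family == "binomial" && length(unique(y[tr])) < 2)) next
      if (family == "gaussian") {
        fits <- ridge_fit(xs[tr, , drop = FALSE], y[tr], alpha_grid)
      } else {
        fits <- vector("list", length(alpha_grid))
        warm <- NULL
        for (a in rev(seq_along(alpha_grid))) {  # strong to weak, warm-started
          fits[[a]] <- logistic_ridge_fit(xs[tr, , drop = FALSE], y[tr],
                                          alpha_grid[a], start = warm)
          warm <- c(fits[[a]]$intercept, fits[[a]]$beta)
        }
      }
      for (a in seq_along(alpha_grid)) {
        pred <- penalized_predict(fits[[a]], xs[!tr, , drop = FALSE])
        scores[f, a] <- prediction_performance(pred, y[!tr], family)
      }
    }
    alpha_perf <- colMeans(scores, na.rm = TRUE)
    alpha_perf[is.nan(alpha_perf)] <- -Inf
  }
  best <- if (all(!is.finite(alpha_perf))) 1L else which.max(alpha_perf)
  alpha <- alpha_grid[best]

  fit <- if (family == "gaussian") {
    ridge_fit(xs, y, alpha)
  } else {
    logistic_ridge_fit(xs, y, alpha)
  }
  structure(
    list(beta = fit$beta, intercept = fit$intercept, alpha = alpha,
         family = family, center = center, scale = scl,
         alpha_performance = stats::setNames(alpha_perf,
                                             signif(alpha_grid, 3))),
    class = "component_fit"
  )
}

# Apply a component fit to new (residualized) feature rows.
predict_component <- function(fit, x, type = "response") {
  xs <- sweep(sweep(as.matrix(x), 2, fit$center), 2, fit$scale, "/")
  penalized_predict(fit, xs, type)
}

#' Discover outcome-related connectivity by resampled cross-validation
#'
#' The discovery loop: in each iteration sessions are reshuffled (seeded)
#' into `n_folds` folds; per fold, confounds are regressed from edges (and a
#' hormone outcome) on the training rows, edge-wise F tests against the
#' outcome select suprathreshold edges (`p < p_threshold`), their largest
#' connected component forms the feature set for an L2-penalized model
#' (logistic for HC use, ridge for hormones) whose penalty is tuned by inner
#' cross-validation, and the model is scored on the held-out fold (accuracy,
#' or Spearman correlation between actual and predicted concentrations).
#' Iteration performance is the mean over folds; each edge accumulates the
#' iteration performance of every iteration in which it entered a component,
#' and the final weight divides by the total number of iterations, so edges
#' never selected have weight exactly 0. Folds with an empty component score
#' chance level (0.5 / 0) and select nothing.
#'
#' @param study An `"fc_study"`.
#' @param config A [cv_config()].
#' @return Object of class `"weighted_network"`: `weights` (canonical edge
#'   vector), `matrix` (symmetric region-by-region, zero diagonal),
#'   `outcome`, `performance` (`mean`, `sd` across iterations),
#'   `iteration_performance`, `selection_count`, `region_labels`, `config`.
#' @export
run_discovery <- function(study, config) {
  stopifnot(inherits(study, "fc_study"), inherits(config, "cv_config"))
  prep <- prepare_outcome(study, config)
  n <- nrow(prep$edges)
  if (n < 10) stop("outcome present for fewer than 10 sessions")
  n_regions <- length(study$region_labels)
  n_edge <- ncol(prep$edges)
  res_outcome <- prep$family == "gaussian"

  weights <- numeric(n_edge)
  sel_count <- integer(n_edge)
  iter_perf <- numeric(config$n_iterations)

  for (it in seq_len(config$n_iterations)) {
    folds <- withr::with_seed(derive_seed(config$seed, it),
                              sample(rep_len(seq_len(config$n_folds), n)))
    sel_iter <- logical(n_edge)
    fold_perf <- numeric(config$n_folds)
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      res <- residualize_confounds(prep$edges, prep$y, prep$covars, tr,
                                   residualize_outcome = res_outcome)
      assoc <- edgewise_association(res$edges[tr, , drop = FALSE],
                                    res$outcome[tr])
      comp <- largest_connected_component(assoc$p, config$p_threshold,
                                          n_regions)
      if (!length(comp)) {
        fold_perf[f] <- chance_level(prep$family)
        next
      }
      fit <- fit_component_model(res$edges[tr, comp, drop = FALSE],
                                 res$outcome[tr], family = prep$family,
                                 alpha_grid = config$alpha_grid,
                                 inner_folds = config$inner_folds,
                                 seed = derive_seed(config$seed,
                                                    it * 1000L + f))
      pred <- predict_component(fit, res$edges[!tr, comp, drop = FALSE])
      truth <- prep$y[!tr]
      if (res_outcome) {
        # put predictions back on the outcome scale before comparison
        x_cov <- covar_design(prep$covars, res$kept_covars, which(!tr))
        pred <- pred + drop(x_cov %*% res$coef_outcome)
      }
      fold_perf[f] <- prediction_performance(pred, truth, prep$family)
      sel_iter[comp] <- TRUE
    }
    iter_perf[it] <- mean(fold_perf)
    weights[sel_iter] <- weights[sel_iter] + iter_perf[it]
    sel_count[sel_iter] <- sel_count[sel_iter] + 1L
  }
  weights <- weights / config$n_iterations

  structure(
    list(weights = weights,
         matrix = unvectorize(weights, study$region_labels, diag = 0)$matrix,
         outcome = config$outcome,
         performance = c(mean = mean(iter_perf), sd = stats::sd(iter_perf)),
         iteration_performance = iter_perf,
         selection_count = sel_count,
         region_labels = study$region_labels,
         config = config),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("<weighted_network> outcome:", x$outcome, "|",
      sum(x$weights != 0), "of", length(x$weights), "edges selected |",
      sprintf("performance %.3f +/- %.3f\n",
              x$performance["mean"], x$performance["sd"]))
  invisible(x)
}

#' Threshold a performance-weighted network
#'
#' Keeps the top `ceiling(retain_fraction * n_nonzero)` edges by weight
#' among the positively weighted edges (edges whose average association with
#' the outcome across iterations was positive); ties are broken by canonical
#' edge index. If the cap exceeds the number of positive edges, all positive
#' edges are returned.
#'
#' @param network A `"weighted_network"`.
#' @param retain_fraction Fraction in (0, 1].
#' @return Integer vector of canonical edge ids.
#' @export
threshold_network <- function(network, retain_fraction = 0.5) {
  stopifnot(retain_fraction > 0, retain_fraction <= 1)
  w <- network$weights
  nz <- which(w != 0)
  if (!length(nz)) {
    warning("weighted network has no nonzero edges")
    return(integer(0))
  }
  pos <- which(w > 0)
  n_keep <- min(ceiling(retain_fraction * length(nz)), length(pos))
  pos[order(-w[pos], pos)][seq_len(n_keep)]
}

#' Train the final penalized model on the full discovery study
#'
#' Residualization, feature standardization, and penalty choice are all
#' refit on the complete discovery study over the supplied edge set; every
#' parameter needed to apply the model to an independent study is stored.
#'
#' @param study Discovery `"fc_study"`.
#' @param edge_set Integer vector of canonical edge ids (e.g. from
#'   [threshold_network()]).
#' @param config A [cv_config()].
#' @return Object of class `"fitted_model"` with `edge_ids`, `edges` (i, j
#'   pairs), `beta`, `intercept`, `alpha`, `family`, `center`, `scale`,
#'   residualization coefficients, `covariates`, `outcome`, `scale_outcome`,
#'   `region_labels`.
#' @export
train_final_model <- function(study, edge_set, config) {
  stopifnot(inherits(study, "fc_study"), inherits(config, "cv_config"))
  if (!length(edge_set)) stop("edge set is empty")
  prep <- prepare_outcome(study, config)
  res_outcome <- prep$family == "gaussian"
  res <- residualize_confounds(prep$edges[, edge_set, drop = FALSE], prep$y,
                               prep$covars, seq_len(nrow(prep$edges)),
                               residualize_outcome = res_outcome)
  fit <- fit_component_model(res$edges, res$outcome, family = prep$family,
                             alpha_grid = config$alpha_grid,
                             inner_folds = config$inner_folds,
                             seed = derive_seed(config$seed, 999983L))
  n_regions <- length(study$region_labels)
  structure(
    list(edge_ids = as.integer(edge_set),
         edges = edge_pairs(n_regions)[edge_set, , drop = FALSE],
         beta = fit$beta, intercept = fit$intercept, alpha = fit$alpha,
         family = prep$family, center = fit$center, scale = fit$scale,
         coef_edges = res$coef_edges, coef_outcome = res$coef_outcome,
         kept_covars = res$kept_covars,
         covariates = config$covariates, outcome = config$outcome,
         scale_outcome = config$scale_outcome,
         region_labels = study$region_labels),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("<fitted_model>", x$family, "model of", x$outcome, "on",
      length(x$edge_ids), "edges, alpha =", signif(x$alpha, 3), "\n")
  invisible(x)
}

# Intercept + retained covariate columns for the given rows, matching the
# column layout of the residualization coefficients.
covar_design <- function(covars, kept, rows) {
  x <- matrix(1, length(rows), 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covars) && length(kept)) {
    x <- cbind(x, as.matrix(covars)[rows, kept, drop = FALSE])
  }
  x
}

# Covariate matrix of an external study in the layout a model expects.
model_covariates <- function(model, sessions) {
  covars <- NULL
  if ("fd" %in% model$covariates) covars <- cbind(covars, fd = sessions$mean_fd)
  if ("hc" %in% model$covariates && model$family == "gaussian") {
    covars <- cbind(covars, hc = as.numeric(sessions$hc_use))
  }
  covars
}

#' Apply a trained model to an independent study (transfer evaluation)
#'
#' The external study's edges are cleaned with the *stored* residualization
#' coefficients (fitted on the discovery study; no refitting), standardized
#' with the stored training statistics, and pushed through the stored
#' coefficients. Hormone outcomes are min-max scaled within the external
#' dataset before comparison, and hormone predictions are mapped back to the
#' outcome scale by adding the stored confound contribution. Performance is
#' classification accuracy (HC) or Spearman correlation (hormones), plus
#' mean squared error on the modeled scale (for HC, the error rate of the
#' 0/1 class prediction).
#'
#' @param model A `"fitted_model"`.
#' @param external An `"fc_study"` over the same region set.
#' @return List of class `"transfer_result"`: `predicted`, `actual`,
#'   `performance`, `metric`, `mse`, `n`, `n_dropped`.
#' @export
transfer_predict <- function(model, external) {
  stopifnot(inherits(model, "fitted_model"), inherits(external, "fc_study"))
  if (!identical(external$region_labels, model$region_labels)) {
    stop("external study's region set does not match the model")
  }
  sess <- external$sessions
  y_raw <- switch(model$outcome, hc = sess$hc_use, e2 = sess$e2, p4 = sess$p4)
  keep <- !is.na(y_raw)
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(n_dropped, " external session(s) without ", model$outcome,
            " dropped")
  }
  sess <- sess[keep, , drop = FALSE]
  y <- if (model$family == "binomial") {
    as.numeric(y_raw[keep])
  } else if (model$scale_outcome) {
    minmax_by(y_raw[keep], sess$dataset_id)
  } else {
    y_raw[keep]
  }
  E <- edge_matrix(external)[keep, model$edge_ids, drop = FALSE]
  covars <- model_covariates(model, sess)
  x_cov <- covar_design(covars, model$kept_covars, seq_len(nrow(sess)))
  E_res <- E - x_cov %*% model$coef_edges
  xs <- sweep(sweep(E_res, 2, model$center), 2, model$scale, "/")
  pred <- penalized_predict(model, xs)
  if (model$family == "gaussian") {
    pred <- pred + drop(x_cov %*% model$coef_outcome)
    perf <- prediction_performance(pred, y, "gaussian")
    mse <- mean((pred - y)^2)
    metric <- "spearman_rho"
  } else {
    cls <- as.integer(pred > 0.5)
    perf <- mean(cls == y)
    mse <- mean((cls - y)^2)
    metric <- "accuracy"
  }
  structure(
    list(predicted = pred, actual = y, performance = perf, metric = metric,
         mse = mse, n = length(y), n_dropped = n_dropped),
    class = "transfer_result"
  )
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %s = %.3f, MSE = %.4f on %d sessions\n",
              x$metric, x$performance, x$mse, x$n))
  invisible(x)
}

#' Drop sessions inside a cycle-day window (sensitivity analysis)
#'
#' Removes sessions whose cycle day falls in the closed `window` (e.g. the
#' ovulatory days 12-16) from a study before network discovery; sessions
#' with missing cycle day are retained with a warning.
#'
#' @param study An `"fc_study"`.
#' @param window Length-2 numeric, inclusive day range; an empty window
#'   (`NULL`) returns the study unchanged.
#' @return The filtered `"fc_study"`.
#' @export
drop_cycle_window <- function(study, window = c(12, 16)) {
  stopifnot(inherits(study, "fc_study"))
  if (is.null(window) || !length(window)) return(study)
  stopifnot(length(window) == 2, window[1] <= window[2])
  cd <- study$sessions$cycle_day
  if (anyNA(cd)) {
    warning(sum(is.na(cd)), " session(s) with missing cycle_day retained")
  }
  drop <- !is.na(cd) & cd >= window[1] & cd <= window[2]
  message(sum(drop), " session(s) in cycle-day window [", window[1], ", ",
          window[2], "] removed")
  subset_study(study, !drop)
}

#' Serialize a fitted model to JSON / read it back
#'
#' @param model A `"fitted_model"`.
#' @param path JSON file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   reconstructed `"fitted_model"`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  out <- unclass(model)
  out$edges <- NULL  # reconstructed from edge_ids
  out$coef_edges <- list(values = as.vector(model$coef_edges),
                         nrow = nrow(model$coef_edges),
                         rownames = rownames(model$coef_edges))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ce <- matrix(raw$coef_edges$values, nrow = raw$coef_edges$nrow)
  rownames(ce) <- raw$coef_edges$rownames
  n_regions <- length(raw$region_labels)
  structure(
    list(edge_ids = as.integer(raw$edge_ids),
         edges = edge_pairs(n_regions)[as.integer(raw$edge_ids), ,
                                       drop = FALSE],
         beta = as.numeric(raw$beta), intercept = raw$intercept,
         alpha = raw$alpha, family = raw$family,
         center = as.numeric(raw$center), scale = as.numeric(raw$scale),
         coef_edges = ce,
         coef_outcome = if (!is.null(raw$coef_outcome))
           as.numeric(raw$coef_outcome),
         kept_covars = as.character(raw$kept_covars %||% character(0)),
         covariates = as.character(raw$covariates),
         outcome = raw$outcome, scale_outcome = isTRUE(raw$scale_outcome),
         region_labels = as.character(raw$region_labels)),
    class = "fitted_model"
  )
}

#' Write discovery outputs as TSV/JSON
#'
#' Writes `network_<outcome>.tsv` (square weighted matrix),
#' `edges_<outcome>.tsv` (edge list `i`, `j`, `weight` for nonzero edges),
#' and `metrics_<outcome>.json` (CV performance mean/SD and any extra
#' metrics supplied) under `dir`.
#'
#' @param network A `"weighted_network"`.
#' @param dir Output directory.
#' @param extra_metrics Optional named list merged into the metrics JSON
#'   (e.g. in-sample and out-of-sample performance).
#' @return `dir`, invisibly.
#' @export
write_discovery <- function(network, dir, extra_metrics = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- network$outcome
  m <- network$matrix
  utils::write.table(
    data.frame(region = rownames(m), m, check.names = FALSE),
    file.path(dir, paste0("network_", out, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  nz <- which(network$weights != 0)
  pairs <- edge_pairs(length(network$region_labels))
  utils::write.table(
    data.frame(i = pairs[nz, 1], j = pairs[nz, 2],
               weight = network$weights[nz]),
    file.path(dir, paste0("edges_", out, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  metrics <- c(list(outcome = out,
                    cv_mean = unname(network$performance["mean"]),
                    cv_sd = unname(network$performance["sd"]),
                    n_iterations = network$config$n_iterations,
                    n_folds = network$config$n_folds),
               extra_metrics)
  jsonlite::write_json(metrics, file.path(dir, paste0("metrics_", out, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
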