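#' Ridge (L2-penalized linear) regression, closed form
#'
#' Minimizes `sum((y - b0 - X b)^2) + alpha * sum(b^2)` with an unpenalized
#' intercept, solved exactly via the singular value decomposition of the
#' column-centered design: `b(alpha) = V diag(d / (d^2 + alpha)) U' yc`.
#' Passing several `alpha` values reuses one SVD, which makes grid search
#' over the penalty cheap. As `alpha -> 0` on a full-rank design the
#' solution converges to ordinary least squares.
#'
#' @param x Numeric design matrix (n x p); columns are used as given (no
#'   internal standardization).
#' @param y Numeric response vector.
#' @param alpha Positive penalty, or a vector of penalties.
#' @return For a single `alpha`, a list with `beta`, `intercept`, `alpha`,
#'   `family = "gaussian"`; for several, a list of such fits (one per
#'   `alpha`, in order).
#' @export
ridge_fit <- function(x, y, alpha) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(alpha > 0))
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2, xm)
  sv <- svd(xc)
  uty <- crossprod(sv$u, y - ym)
  fits <- lapply(alpha, function(a) {
    beta <- drop(sv$v %*% (sv$d / (sv$d^2 + a) * uty))
    list(beta = beta, intercept = ym - sum(xm * beta), alpha = a,
         family = "gaussian")
  })
  if (length(alpha) == 1L) fits[[1L]] else fits
}

#' L2-penalized logistic regression via iteratively reweighted least squares
#'
#' Maximizes the binomial log-likelihood minus `alpha / 2 * sum(b^2)` (the
#' intercept is unpenalized) by damped Newton iterations. The penalty keeps
#' the problem well-posed even for separable data.
#'
#' @param x Numeric design matrix (n x p).
#' @param y 0/1 response vector.
#' @param alpha Positive penalty.
#' @param max_iter,tol Newton iteration controls.
#' @param start Optional warm-start coefficient vector `c(intercept, beta)`.
#' @return List with `beta`, `intercept`, `alpha`, `family = "binomial"`,
#'   `converged`.
#' @export
logistic_ridge_fit <- function(x, y, alpha, max_iter = 100L, tol = 1e-9,
                               start = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)), alpha > 0)
  xd <- cbind(1, x)
  p <- ncol(x)
  pen <- diag(c(0, rep(alpha, p)), p + 1L)
  coef <- start %||% c(stats::qlogis(mean(pmin(pmax(y, 0.05), 0.95))),
                       rep(0, p))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(xd %*% coef)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(xd, y - mu) - pen %*% coef
    hess <- crossprod(xd, xd * w) + pen
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) break
    # halve the step until the penalized log-likelihood does not decrease
    obj <- function(cf) {
      e <- drop(xd %*% cf)
      sum(y * e - log1p(exp(e))) - alpha / 2 * sum(cf[-1]^2)
    }
    f0 <- obj(coef)
    lambda <- 1
    repeat {
      cand <- coef + lambda * drop(step)
      if (obj(cand) >= f0 - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    coef_new <- coef + lambda * drop(step)
    delta <- max(abs(coef_new - coef))
    coef <- coef_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = coef[-1L], intercept = coef[1L], alpha = alpha,
       family = "binomial", converged = converged)
}

# Linear predictor / fitted values for the fit objects above.
penalized_predict <- function(fit, x, type = c("response", "class")) {
  type <- match.arg(type)
  eta <- drop(as.matrix(x) %*% fit$beta) + fit$intercept
  if (fit$family == "binomial") {
    pr <- stats::plogis(eta)
    if (type == "class") as.integer(pr > 0.5) else pr
  } else {
    eta
  }
}
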