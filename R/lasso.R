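#' Build a design matrix for the sparse regression stage
#'
#' Validates that predictors and predictand are centred (the model carries no
#' intercept: columns are pre-normalized) and returns them with labels.
#'
#' @param X numeric matrix, n x k, columns the normalized predictors.
#' @param y numeric vector, length n, the normalized predictand.
#' @param labels predictor labels; defaults to \code{colnames(X)}.
#' @param center_tol tolerance on column/means (default 1e-8).
#' @return list of class \code{"hm_design"} with \code{X}, \code{y},
#'   \code{labels}, \code{n}, \code{k}.
#' @export
design_matrix <- function(X, y, labels = colnames(X), center_tol = 1e-8) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), is.numeric(y), nrow(X) == length(y), nrow(X) > 1)
  if (is.null(labels)) labels <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(labels) == ncol(X))
  if (max(abs(colMeans(X))) > center_tol || abs(mean(y)) > center_tol)
    stop("columns and y must be centred (z-score them first)", call. = FALSE)
  if (any(apply(X, 2, function(c) all(c == 0))))
    stop("degenerate design: zero column", call. = FALSE)
  colnames(X) <- labels
  structure(list(X = X, y = y, labels = labels, n = nrow(X), k = ncol(X)),
            class = "hm_design")
}

soft_threshold <- function(z, gamma) sign(z) * pmax(abs(z) - gamma, 0)

#' LASSO objective function
#'
#' \eqn{J(\beta) = \frac{1}{N}\sum_n (y_n - \sum_k \beta_k x_{nk})^2
#'   + \lambda \sum_k |\beta_k|}. Note the 1/N (not 1/2N) scaling of the
#' squared-error term: the coordinate-wise soft threshold is at
#' \eqn{\lambda/2}, and the all-zero solution is optimal for
#' \eqn{\lambda \ge 2\max_k |\frac{1}{N}\sum_n x_{nk} y_n|}.
#'
#' @param beta coefficient vector, length k.
#' @param design an \code{hm_design} from [design_matrix()].
#' @param lambda non-negative penalty weight.
#' @return scalar objective value.
#' @export
lasso_objective <- function(beta, design, lambda) {
  stopifnot(inherits(design, "hm_design"), lambda >= 0)
  if (length(beta) != design$k)
    stop("beta has length ", length(beta), ", expected ", design$k,
         call. = FALSE)
  mean((design$y - design$X %*% beta)^2) + lambda * sum(abs(beta))
}

#' Fit the LASSO at one penalty value by cyclic coordinate descent
#'
#' Minimizes [lasso_objective()] with covariance updates: each coordinate is
#' set to its exact one-dimensional minimizer (a soft threshold at
#' \eqn{\lambda/2}), cycling until the largest coefficient change in a sweep
#' falls below \code{tol}. Each sweep can only decrease the objective.
#'
#' @param design an \code{hm_design}.
#' @param lambda non-negative penalty.
#' @param tol convergence threshold on the max absolute coefficient change
#'   per sweep (default 1e-7).
#' @param max_iter maximum number of sweeps (default 1e5).
#' @param beta_init warm-start coefficients (default zeros).
#' @param trace if TRUE, attach the per-sweep objective values as the
#'   \code{"objective_trace"} attribute.
#' @return named coefficient vector satisfying the subgradient stationarity
#'   conditions within \code{tol}.
#' @export
lasso_fit <- function(design, lambda, tol = 1e-7, max_iter = 1e5,
                      beta_init = NULL, trace = FALSE) {
  stopifnot(inherits(design, "hm_design"), lambda >= 0, tol > 0)
  X <- design$X; y <- design$y; n <- design$n; k <- design$k
  G <- crossprod(X) / n            # (1/N) X'X
  c0 <- drop(crossprod(X, y)) / n  # (1/N) X'y
  beta0 <- if (is.null(beta_init)) numeric(k) else {
    stopifnot(length(beta_init) == k); as.numeric(beta_init)
  }
  res <- .cd_lasso(G, c0, mean(y^2), lambda, tol, as.integer(max_iter),
                   beta0, isTRUE(trace))
  if (!res$converged) {
    gap <- stationarity_gap(res$beta, G, c0, lambda)
    stop(sprintf(
      "coordinate descent did not converge in %d sweeps (stationarity gap %.3g)",
      as.integer(max_iter), gap), call. = FALSE)
  }
  beta <- res$beta
  names(beta) <- design$labels
  if (trace) attr(beta, "objective_trace") <- res$objective_trace
  beta
}

# max violation of the subgradient conditions of the 1/N-scaled objective
stationarity_gap <- function(beta, G, c0, lambda) {
  grad <- 2 * (G %*% beta - c0)  # d/dbeta of (1/N) RSS
  viol <- ifelse(beta == 0,
                 pmax(abs(grad) - lambda, 0),
                 abs(grad + lambda * sign(beta)))
  max(viol)
}

#' Solve the LASSO along a decreasing penalty grid
#'
#' The grid is log-spaced from \eqn{\lambda_{max} =
#' 2 \max_k |\frac{1}{N} \sum_n x_{nk} y_n|} (the smallest penalty at which
#' the all-zero solution is optimal) down to
#' \eqn{\lambda_{max} \cdot} \code{lambda_min_ratio}. Solutions are
#' warm-started from the previous grid point.
#'
#' @param design an \code{hm_design}.
#' @param grid_size number of grid points (default 100).
#' @param lambda_min_ratio ratio of smallest to largest penalty
#'   (default 1e-4).
#' @param tol,max_iter passed to [lasso_fit()].
#' @return object of class \code{"hm_lasso_path"}: list with \code{lambda}
#'   (decreasing), \code{beta} (grid_size x k matrix), \code{supports}
#'   (list of character vectors of nonzero labels), \code{labels}.
#' @export
lasso_path <- function(design, grid_size = 100, lambda_min_ratio = 1e-4,
                       tol = 1e-7, max_iter = 1e5) {
  stopifnot(inherits(design, "hm_design"), grid_size >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  c0 <- drop(crossprod(design$X, design$y)) / design$n
  lambda_max <- 2 * max(abs(c0))
  if (lambda_max == 0)
    stop("predictand is orthogonal to every predictor; path is degenerate",
         call. = FALSE)
  lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = grid_size))
  B <- matrix(0, grid_size, design$k, dimnames = list(NULL, design$labels))
  beta <- numeric(design$k)
  for (i in seq_len(grid_size)) {
    beta <- lasso_fit(design, lambda[i], tol = tol, max_iter = max_iter,
                      beta_init = beta)
    B[i, ] <- beta
  }
  supports <- apply(B, 1, function(b) design$labels[b != 0], simplify = FALSE)
  structure(list(lambda = lambda, beta = B, supports = supports,
                 labels = design$labels),
            class = "hm_lasso_path")
}

#' @export
print.hm_lasso_path <- function(x, ...) {
  cat("LASSO path:", length(x$lambda), "penalty values,",
      length(x$labels), "predictors\n")
  cat(sprintf("  lambda: %.4g ... %.4g\n",
              x$lambda[1], x$lambda[length(x$lambda)]))
  sizes <- lengths(x$supports)
  cat("  support sizes along path:", paste(rle(sizes)$values, collapse = " -> "),
      "\n")
  invisible(x)
}

#' Extract candidate predictor subsets from a LASSO path
#'
#' A support (set of nonzero predictors) that persists unchanged over at
#' least \code{persistence_m} consecutive grid points is treated as a
#' candidate model for the subsequent AIC stage. Candidates are returned in
#' order of first appearance (largest penalty first), without duplicates,
#' and the empty support is excluded.
#'
#' @param path an \code{hm_lasso_path}.
#' @param persistence_m minimum run length in grid points (default 2).
#' @return object of class \code{"hm_candidates"}: list of elements with
#'   \code{support} (character vector) and \code{lambda_range} of the first
#'   run over which it persisted. May be empty.
#' @export
candidate_supports <- function(path, persistence_m = 2) {
  stopifnot(inherits(path, "hm_lasso_path"), persistence_m >= 1)
  keys <- vapply(path$supports,
                 function(s) paste(sort(s), collapse = "+"), character(1))
  runs <- rle(keys)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seen <- character(0)
  out <- list()
  for (r in seq_along(runs$values)) {
    key <- runs$values[r]
    if (key == "" || runs$lengths[r] < persistence_m || key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- list(
      support = path$supports[[starts[r]]],
      lambda_range = c(path$lambda[ends[r]], path$lambda[starts[r]]))
  }
  structure(out, class = "hm_candidates")
}

#' @export
print.hm_candidates <- function(x, ...) {
  cat(length(x), "candidate support(s):\n")
  for (ci in x)
    cat(sprintf("  {%s}  lambda in [%.4g, %.4g]\n",
                paste(ci$support, collapse = ", "),
                ci$lambda_range[1], ci$lambda_range[2]))
  invisible(x)
}
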