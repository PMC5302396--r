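#' Root-mean-square prediction error (standard error of the estimate)
#'
#' \eqn{\sigma_{est} = \sqrt{\sum (Y - Y')^2 / N}}.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return non-negative scalar; its square is exactly the mean squared error.
#' @export
sigma_est <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length", call. = FALSE)
  if (length(observed) < 1) stop("need at least one pair", call. = FALSE)
  sqrt(mean((observed - predicted)^2))
}

#' Mean-squared-error skill score (MSES)
#'
#' \eqn{MSES = 1 - MSE(Y', Y) / MSE(Y, \bar Y)}, with the mean of the
#' verification observations as the climatological reference forecast.
#' Equals 1 for a perfect forecast, 0 for the climatology, and is negative
#' for forecasts worse than climatology. In-sample, on the fitted values of
#' an OLS fit with intercept, it equals R^2 exactly.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return scalar skill score.
#' @export
msess <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length", call. = FALSE)
  ref <- mean((observed - mean(observed))^2)
  if (ref == 0)
    stop("constant observations: climatology reference has zero MSE",
         call. = FALSE)
  1 - mean((observed - predicted)^2) / ref
}

#' Sample Pearson correlation
#'
#' Thin validated wrapper around [stats::cor()].
#'
#' @param a,b numeric vectors of equal length >= 3 with positive variance.
#' @return correlation in \eqn{[-1, 1]}.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance input", call. = FALSE)
  stats::cor(a, b)
}

#' Normal Q-Q points for a residual vector
#'
#' Pairs the i-th order statistic of the residuals with the standard-normal
#' quantile at plotting position \eqn{(i - 0.5)/n}. If the residuals are
#' N(0, sigma^2) the points fall on a line through the origin with slope
#' sigma.
#'
#' @param residuals numeric vector (observed minus predicted), finite.
#' @return data frame of class \code{"hm_qq"} with columns
#'   \code{theoretical} and \code{sample}, both non-decreasing.
#' @export
qq_points <- function(residuals) {
  if (length(residuals) < 1) stop("empty residual vector", call. = FALSE)
  if (any(!is.finite(residuals)))
    stop("non-finite residuals", call. = FALSE)
  n <- length(residuals)
  out <- data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
                    sample = sort(residuals))
  class(out) <- c("hm_qq", "data.frame")
  out
}

#' Leave-one-year-out cross-validation of the index--milk regression
#'
#' For each calendar year in turn, the year's rows (within the given season)
#' are withheld; predictors and predictand are z-scored on the training rows
#' only; the LASSO path, candidate extraction and AIC selection are run on
#' the training design; and the withheld rows are predicted with the
#' training-fold normalization parameters, then mapped back to the original
#' predictand scale. Pooled metrics are computed over all held-out pairs.
#'
#' With \code{fix_support}, the per-fold model search is skipped and the
#' given predictor subset is OLS-refit on each training fold instead
#' (the literal reading of selecting once and only refitting per fold).
#'
#' @param monthly data frame of monthly observations (from
#'   [monthly_aggregate()] or [generate_study()]): columns \code{zone},
#'   \code{year}, \code{month}, \code{season}, the six index columns and the
#'   predictand.
#' @param season \code{"spring"} or \code{"summer"}.
#' @param predictand response column name (e.g. \code{"yield"}).
#' @param predictors predictor column names (default the six index labels).
#' @param fix_support optional character vector: skip selection and use this
#'   support in every fold.
#' @param grid_size,lambda_min_ratio,persistence_m,window tuning of the
#'   per-fold path and selection; defaults as in [lasso_path()],
#'   [candidate_supports()] and [select_best()].
#' @return object of class \code{"hm_cv"}: list with \code{folds} (per-year
#'   list: year, support, coefficients, intercept, held-out indices),
#'   \code{observed}, \code{predicted} (pooled, original predictand units),
#'   \code{pearson_r}, \code{msess}, \code{sigma_est}, \code{qq}
#'   (Q-Q points of observed - predicted), \code{skipped} (years whose
#'   training fold failed, with the reason).
#' @export
loyo_cv <- function(monthly, season, predictand = "yield",
                    predictors = INDEX_LABELS, fix_support = NULL,
                    grid_size = 100, lambda_min_ratio = 1e-4,
                    persistence_m = 2, window = 1.0) {
  stopifnot(is.data.frame(monthly),
            season %in% c("spring", "summer"),
            all(c(predictors, predictand, "year", "season") %in%
                  names(monthly)))
  dat <- monthly[monthly$season == season, , drop = FALSE]
  years <- sort(unique(dat$year))
  if (length(years) < 3)
    stop("need at least 3 distinct years for leave-one-year-out CV",
         call. = FALSE)
  folds <- list()
  skipped <- list()
  obs <- pred <- numeric(0)
  for (yr in years) {
    test <- dat[dat$year == yr, , drop = FALSE]
    train <- dat[dat$year != yr, , drop = FALSE]
    res <- tryCatch({
      zs <- zscore(train, c(predictors, predictand))
      des <- design_matrix(as.matrix(zs$data[predictors]),
                           zs$data[[predictand]], labels = predictors)
      support <- if (is.null(fix_support)) {
        path <- lasso_path(des, grid_size = grid_size,
                           lambda_min_ratio = lambda_min_ratio)
        cands <- candidate_supports(path, persistence_m = persistence_m)
        sel <- refit_and_select(des, cands, window = window)
        sel$candidates[[sel$final]]$support
      } else fix_support
      fit <- ols_fit(des, support)
      test_z <- apply_zscore(test, zs$params)
      yhat_z <- fit$intercept +
        as.matrix(test_z[, support, drop = FALSE]) %*% fit$coefficients
      yp <- zs$params[zs$params$column == predictand, ]
      list(support = support,
           coefficients = fit$coefficients,
           intercept = fit$intercept,
           predicted = drop(yhat_z) * yp$sd + yp$mean)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("fold for year ", yr, " skipped: ", conditionMessage(res),
              call. = FALSE)
      skipped[[as.character(yr)]] <- conditionMessage(res)
      next
    }
    folds[[as.character(yr)]] <- c(list(year = yr), res)
    obs <- c(obs, test[[predictand]])
    pred <- c(pred, res$predicted)
  }
  if (!length(folds)) stop("every fold failed", call. = FALSE)
  structure(list(folds = folds,
                 observed = obs, predicted = pred,
                 pearson_r = pearson_r(obs, pred),
                 msess = msess(obs, pred),
                 sigma_est = sigma_est(obs, pred),
                 qq = qq_points(obs - pred),
                 season = season, predictand = predictand,
                 skipped = skipped),
            class = "hm_cv")
}

#' @export
print.hm_cv <- function(x, ...) {
  cat("Leave-one-year-out CV (", x$season, ", ", x$predictand, "): ",
      length(x$folds), " folds, ", length(x$observed),
      " held-out observations\n", sep = "")
  cat(sprintf("  pooled r = %.3f, MSES = %.3f, sigma_est = %.3f\n",
              x$pearson_r, x$msess, x$sigma_est))
  supports <- vapply(x$folds,
                     function(f) paste(f$support, collapse = ","),
                     character(1))
  cat("  fold supports:", paste(unique(supports), collapse = " | "), "\n")
  invisible(x)
}
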