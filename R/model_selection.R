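#' Ordinary least-squares refit on a predictor subset
#'
#' Refits the candidate support by OLS with an intercept (which is ~0 on
#' normalized data and retained for audit), returning the quantities the
#' AIC stage and the reporting tables need.
#'
#' @param design an \code{hm_design} from [design_matrix()].
#' @param support character vector of predictor labels (may be empty for the
#'   intercept-only model).
#' @return object of class \code{"hm_fit"}: list with \code{support},
#'   \code{coefficients} (named, excluding intercept), \code{intercept},
#'   \code{rss}, \code{r_squared}, \code{p_value} (overall F test; NA for an
#'   empty support), \code{n}, \code{k_params} (= |support| + 2: slopes,
#'   intercept, and the Gaussian error variance).
#' @export
ols_fit <- function(design, support) {
  stopifnot(inherits(design, "hm_design"))
  support <- as.character(support)
  if (!all(support %in% design$labels))
    stop("unknown predictor(s): ",
         paste(setdiff(support, design$labels), collapse = ", "),
         call. = FALSE)
  n <- design$n
  p <- length(support)
  if (n <= p + 1)
    stop("need n > |support| + 1 observations (n = ", n, ", |support| = ",
         p, ")", call. = FALSE)
  Xs <- cbind(`(Intercept)` = 1, design$X[, support, drop = FALSE])
  fit <- stats::lm.fit(Xs, design$y)
  if (fit$rank < ncol(Xs))
    stop("rank-deficient design for support {",
         paste(support, collapse = ", "), "}", call. = FALSE)
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((design$y - mean(design$y))^2)
  r2 <- 1 - rss / tss
  p_value <- if (p == 0) NA_real_ else {
    f <- (r2 / p) / ((1 - r2) / (n - p - 1))
    stats::pf(f, p, n - p - 1, lower.tail = FALSE)
  }
  structure(list(support = support,
                 coefficients = fit$coefficients[-1],
                 intercept = unname(fit$coefficients[1]),
                 fitted = drop(Xs %*% fit$coefficients),
                 rss = rss, r_squared = r2, p_value = p_value,
                 n = n, k_params = p + 2),
            class = "hm_fit")
}

#' Gaussian AIC of a least-squares fit
#'
#' \eqn{AIC = 2k - 2\ln L} with the Gaussian maximized likelihood at
#' \eqn{\hat\sigma^2 = RSS/n}, i.e.
#' \eqn{AIC = 2 k + n \ln(2\pi\, RSS/n) + n}, where k counts the slopes,
#' the intercept and the error variance (\code{k_params = |support| + 2}).
#' A zero RSS means an unbounded likelihood and is rejected.
#'
#' @param fit an \code{hm_fit} from [ols_fit()].
#' @return scalar AIC value.
#' @export
aic_gaussian <- function(fit) {
  stopifnot(inherits(fit, "hm_fit"))
  if (fit$rss <= 0)
    stop("RSS is zero: Gaussian likelihood unbounded, AIC undefined",
         call. = FALSE)
  2 * fit$k_params + fit$n * log(2 * pi * fit$rss / fit$n) + fit$n
}

#' Select the best model by AIC with an Occam tie-break
#'
#' Computes \eqn{\Delta AIC_i = AIC_i - \min_j AIC_j}; every candidate with
#' \eqn{\Delta AIC \le} \code{window} is co-selected, and the final model is
#' the co-selected candidate with the fewest predictors (ties broken by the
#' lower AIC).
#'
#' @param candidates list; each element needs \code{support} (character
#'   vector) and \code{aic} (scalar), and may carry a full \code{fit}
#'   (\code{hm_fit}) plus other fields, which pass through.
#' @param window co-selection width on the Delta-AIC scale (default 1.0).
#' @return object of class \code{"hm_selection"}: list with \code{table}
#'   (data frame: model, support, n_predictors, aic, delta_aic, selected,
#'   and r_squared / p_value when fits are present), \code{selected}
#'   (indices of co-selected models), \code{final} (index of the final
#'   model), \code{window}, and \code{candidates} (the input, with fits).
#' @export
select_best <- function(candidates, window = 1.0) {
  stopifnot(is.list(candidates), window >= 0)
  if (length(candidates) == 0)
    stop("no candidate models to select from", call. = FALSE)
  aics <- vapply(candidates, function(ci) as.numeric(ci$aic), numeric(1))
  sizes <- vapply(candidates, function(ci) length(ci$support), integer(1))
  delta <- aics - min(aics)
  selected <- which(delta <= window)
  final <- selected[order(sizes[selected], aics[selected])][1]
  tab <- data.frame(
    model = seq_along(candidates),
    support = vapply(candidates,
                     function(ci) paste(ci$support, collapse = ", "),
                     character(1)),
    n_predictors = sizes,
    aic = aics,
    delta_aic = delta,
    selected = seq_along(candidates) %in% selected,
    stringsAsFactors = FALSE)
  has_fit <- vapply(candidates, function(ci) inherits(ci$fit, "hm_fit"),
                    logical(1))
  if (all(has_fit)) {
    tab$r_squared <- vapply(candidates, function(ci) ci$fit$r_squared,
                            numeric(1))
    tab$p_value <- vapply(candidates, function(ci) ci$fit$p_value, numeric(1))
  }
  structure(list(table = tab, selected = selected, final = final,
                 window = window, candidates = candidates),
            class = "hm_selection")
}

#' @export
print.hm_selection <- function(x, digits = 3, ...) {
  tab <- x$table
  tab$aic <- round(tab$aic, digits)
  tab$delta_aic <- round(tab$delta_aic, digits)
  if ("r_squared" %in% names(tab)) tab$r_squared <- round(tab$r_squared, digits)
  print(tab, row.names = FALSE)
  cat("final model (Occam among Delta-AIC <= ", x$window, "): model ",
      x$final, " {", x$table$support[x$final], "}\n", sep = "")
  invisible(x)
}

#' Refit all candidate supports and select by AIC
#'
#' Convenience wrapper: OLS-refits every candidate support on the design,
#' scores each with [aic_gaussian()], and runs [select_best()].
#'
#' @param design an \code{hm_design}.
#' @param cands an \code{hm_candidates} from [candidate_supports()], or a
#'   list of character vectors.
#' @param window co-selection window (default 1.0).
#' @return an \code{hm_selection}.
#' @export
refit_and_select <- function(design, cands, window = 1.0) {
  supports <- if (inherits(cands, "hm_candidates"))
    lapply(cands, `[[`, "support") else cands
  if (length(supports) == 0)
    stop("no candidate supports (LASSO path produced none)", call. = FALSE)
  candidates <- lapply(supports, function(s) {
    fit <- ols_fit(design, s)
    list(support = s, fit = fit, aic = aic_gaussian(fit))
  })
  select_best(candidates, window = window)
}
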