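#' Season label for a month
#'
#' Spring is April--June, summer is July--September; other months are outside
#' the study window.
#'
#' @param month integer month(s) 1--12.
#' @return character vector, \code{"spring"}, \code{"summer"} or \code{NA}.
#' @export
season_of <- function(month) {
  out <- rep(NA_character_, length(month))
  out[month %in% 4:6] <- "spring"
  out[month %in% 7:9] <- "summer"
  out
}

#' Filter test-day milk records
#'
#' Retains records with 4--305 days in milk, parity (calving count) between
#' three and six, and neither a mastitis nor a dry-period flag. Records with
#' missing values in any of these fields are dropped with a message.
#'
#' @param records data frame with columns \code{days_in_milk}, \code{parity},
#'   \code{mastitis}, \code{dry} (logical or 0/1).
#' @return The filtered data frame (possibly empty). Idempotent.
#' @export
filter_milk_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("days_in_milk", "parity", "mastitis", "dry")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  complete <- stats::complete.cases(records[need])
  if (any(!complete))
    message("dropping ", sum(!complete), " record(s) with missing fields")
  rec <- records[complete, , drop = FALSE]
  keep <- rec$days_in_milk >= 4 & rec$days_in_milk <= 305 &
    rec$parity >= 3 & rec$parity <= 6 &
    !as.logical(rec$mastitis) & !as.logical(rec$dry)
  rec[keep, , drop = FALSE]
}

#' Aggregate daily indices and milk records to monthly zone means
#'
#' Computes the arithmetic mean of each index per (zone, year, month) from
#' the daily table, the mean of each milk variable per (zone, year, month)
#' from the milk records, inner-joins the two on the key, and attaches the
#' season label. Keys present in only one input are excluded with a warning.
#'
#' @param daily_indices data frame with \code{zone}, \code{date} (Date) and
#'   index columns (any of Tg, THI, ETI, ESI, HLI, HLI_new, RRP).
#' @param milk data frame with \code{zone}, \code{year}, \code{month} and
#'   milk columns (any of yield, fat, protein); typically already filtered
#'   by [filter_milk_records()].
#' @return data frame with one row per (zone, year, month): key columns,
#'   \code{season}, monthly index means and monthly milk means.
#' @export
monthly_aggregate <- function(daily_indices, milk) {
  stopifnot(is.data.frame(daily_indices), is.data.frame(milk))
  di <- daily_indices
  di$year <- as.integer(format(as.Date(di$date), "%Y"))
  di$month <- as.integer(format(as.Date(di$date), "%m"))
  idx_cols <- intersect(c("Tg", INDEX_LABELS), names(di))
  if (!length(idx_cols)) stop("no index columns in daily table", call. = FALSE)
  milk_cols <- intersect(c("yield", "fat", "protein"), names(milk))
  if (!length(milk_cols)) stop("no milk columns in milk table", call. = FALSE)

  agg_i <- stats::aggregate(di[idx_cols],
                            by = list(zone = di$zone, year = di$year,
                                      month = di$month),
                            FUN = mean)
  agg_m <- stats::aggregate(milk[milk_cols],
                            by = list(zone = milk$zone, year = milk$year,
                                      month = milk$month),
                            FUN = mean)
  key_i <- paste(agg_i$zone, agg_i$year, agg_i$month)
  key_m <- paste(agg_m$zone, agg_m$year, agg_m$month)
  only <- c(setdiff(key_i, key_m), setdiff(key_m, key_i))
  if (length(only))
    warning(length(only), " (zone, year, month) key(s) present in only one ",
            "input; excluded", call. = FALSE)
  out <- merge(agg_i, agg_m, by = c("zone", "year", "month"))
  out$season <- season_of(out$month)
  out <- out[order(out$zone, out$year, out$month), , drop = FALSE]
  rownames(out) <- NULL
  out[c("zone", "year", "month", "season", idx_cols, milk_cols)]
}

#' Z-score normalization with stored parameters
#'
#' Centres and scales the selected columns to mean 0 and standard deviation 1
#' (sample denominator, N-1). The per-column mean and sd are returned so the
#' transform can be applied to new data or inverted.
#'
#' @param data data frame.
#' @param columns character vector of column names to normalize.
#' @return list with \code{data} (normalized copy) and \code{params}
#'   (data frame: column, mean, sd).
#' @export
zscore <- function(data, columns) {
  stopifnot(is.data.frame(data), all(columns %in% names(data)))
  mu <- vapply(data[columns], mean, numeric(1))
  sd <- vapply(data[columns], stats::sd, numeric(1))
  zero <- columns[sd == 0 | !is.finite(sd)]
  if (length(zero))
    stop("zero-variance column(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  out <- data
  for (j in seq_along(columns))
    out[[columns[j]]] <- (data[[columns[j]]] - mu[j]) / sd[j]
  list(data = out,
       params = data.frame(column = columns, mean = unname(mu),
                           sd = unname(sd), stringsAsFactors = FALSE))
}

#' Apply stored normalization parameters to new data
#'
#' @param data data frame containing the parameterized columns.
#' @param params data frame from [zscore()].
#' @return data frame with those columns standardized by the stored
#'   mean and sd.
#' @export
apply_zscore <- function(data, params) {
  stopifnot(all(params$column %in% names(data)))
  out <- data
  for (j in seq_len(nrow(params))) {
    cl <- params$column[j]
    out[[cl]] <- (data[[cl]] - params$mean[j]) / params$sd[j]
  }
  out
}

#' Invert a z-score normalization
#'
#' @inheritParams apply_zscore
#' @return data frame with the columns mapped back to the original scale.
#' @export
invert_zscore <- function(data, params) {
  stopifnot(all(params$column %in% names(data)))
  out <- data
  for (j in seq_len(nrow(params))) {
    cl <- params$column[j]
    out[[cl]] <- data[[cl]] * params$sd[j] + params$mean[j]
  }
  out
}

#' Stratified non-parametric bootstrap of a scalar statistic
#'
#' Resamples rows with replacement (same n per stratum) and recomputes the
#' statistic B times; the confidence interval is the percentile interval,
#' whose endpoints are order statistics of the replicates.
#'
#' @param data data frame of observations (e.g. monthly means).
#' @param statistic function mapping a resampled data frame to one number.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param level confidence level (default 0.95).
#' @param strata optional factor/vector of length nrow(data); resampling is
#'   done independently within each stratum (e.g. zone-season).
#' @return object of class \code{"hm_bootstrap"}: list with \code{replicates}
#'   (length B), \code{ci} (two order-statistic endpoints), \code{level},
#'   \code{B}, \code{statistic_label}.
#' @export
bootstrap_stat <- function(data, statistic, B = 1000, seed = NULL,
                           level = 0.95, strata = NULL) {
  stopifnot(is.data.frame(data), is.function(statistic), B >= 1)
  n <- nrow(data)
  if (n == 0) stop("cannot bootstrap an empty table", call. = FALSE)
  if (!is.null(strata)) {
    stopifnot(length(strata) == n)
    groups <- split(seq_len(n), strata, drop = TRUE)
    if (any(lengths(groups) == 0)) stop("empty stratum", call. = FALSE)
  } else {
    groups <- list(seq_len(n))
  }
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), length(g), replace = TRUE)]),
      use.names = FALSE)
    statistic(data[idx, , drop = FALSE])
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), type = 1, names = FALSE)
  structure(list(replicates = reps, ci = ci, level = level, B = B,
                 statistic_label = deparse(substitute(statistic))[1]),
            class = "hm_bootstrap")
}

#' @export
print.hm_bootstrap <- function(x, ...) {
  cat("Non-parametric bootstrap:", x$B, "replicates\n")
  cat(sprintf("  %.0f%% percentile CI: [%.4g, %.4g]\n",
              100 * x$level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Read a milk-record table
#'
#' Header-bearing delimited text with columns \code{zone}, \code{year},
#' \code{month}, \code{days_in_milk}, \code{parity}, \code{mastitis},
#' \code{dry}, \code{yield}, \code{fat}, \code{protein}.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data frame.
#' @export
read_milk <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write monthly observations
#'
#' @param x data frame from [monthly_aggregate()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_monthly <- function(x, path, sep = "\t") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
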