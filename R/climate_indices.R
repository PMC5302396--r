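#' @keywords internal
#' @useDynLib heatmilk, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

INDEX_LABELS <- c("THI", "ETI", "ESI", "HLI", "HLI_new", "RRP")

stop_if_nonfinite <- function(..., what = "input") {
  vals <- c(...)
  if (any(!is.finite(vals)))
    stop("non-finite ", what, " value", call. = FALSE)
  invisible(NULL)
}

#' Saturation vapour pressure over water
#'
#' Magnus-type formula \eqn{e_w^* = 6.1078 \exp(17.1 T / (235 + T))} giving the
#' saturation vapour pressure of air at temperature \code{T}.
#'
#' @param T air temperature in degrees Celsius; must exceed -235 (the Magnus
#'   denominator's pole).
#' @return Saturation vapour pressure in hPa; positive and strictly increasing
#'   in \code{T}.
#' @examples
#' saturation_vapor_pressure(0)   # 6.1078
#' saturation_vapor_pressure(20)  # ~23.35
#' @export
saturation_vapor_pressure <- function(T) {
  stop_if_nonfinite(T, what = "temperature")
  if (any(T <= -235))
    stop("temperature must exceed -235 degC", call. = FALSE)
  6.1078 * exp(17.1 * T / (235 + T))
}

#' Vapour pressure from pressure and specific humidity
#'
#' \eqn{e = 1.6077\, p\, q}: actual vapour pressure from sea-level pressure
#' \code{p} (hPa) and specific humidity \code{q} (kg/kg).
#'
#' @param p sea-level pressure, hPa; must be positive.
#' @param q specific humidity, kg/kg; must be non-negative.
#' @return Vapour pressure in hPa, linear in each argument.
#' @export
vapor_pressure <- function(p, q) {
  stop_if_nonfinite(p, q)
  if (any(p <= 0)) stop("pressure must be positive", call. = FALSE)
  if (any(q < 0)) stop("specific humidity must be non-negative", call. = FALSE)
  1.6077 * p * q
}

#' Relative humidity from vapour pressures
#'
#' Ratio \eqn{e / e_w^*} expressed on the 0--100 percent scale. Supersaturated
#' inputs (\code{e > ew_star}), which can arise from mutually inconsistent
#' reanalysis-like fields, are clipped to 100 with a warning rather than
#' rejected.
#'
#' @param e vapour pressure, hPa (non-negative).
#' @param ew_star saturation vapour pressure, hPa (positive).
#' @return Relative humidity in percent, in \eqn{[0, 100]}.
#' @export
relative_humidity <- function(e, ew_star) {
  stop_if_nonfinite(e, ew_star)
  if (any(ew_star <= 0))
    stop("saturation vapour pressure must be positive", call. = FALSE)
  if (any(e < 0)) stop("vapour pressure must be non-negative", call. = FALSE)
  rh <- 100 * e / ew_star
  if (any(rh > 100 * (1 + 1e-12))) {  # beyond rounding error of saturation
    warning(sum(rh > 100), " supersaturated record(s): RH clipped to 100%",
            call. = FALSE)
  }
  pmin(rh, 100)
}

#' Dew-point temperature from temperature and relative humidity
#'
#' Eighth-root approximation
#' \eqn{T_d = (RH/100)^{1/8} (112 + 0.9T) + 0.1T - 112},
#' which is exact at saturation (\eqn{T_d = T} at \eqn{RH = 100}) and
#' monotone increasing in RH.
#'
#' @param T air temperature, degrees Celsius.
#' @param RH relative humidity in percent, in \eqn{(0, 100]}.
#' @return Dew-point temperature in degrees Celsius, \eqn{T_d \le T}.
#' @export
dew_point <- function(T, RH) {
  stop_if_nonfinite(T, RH)
  if (any(RH <= 0))
    stop("relative humidity must be positive for dew point", call. = FALSE)
  if (any(RH > 100))
    stop("relative humidity above 100% is not a valid dew-point input",
         call. = FALSE)
  (RH / 100)^(1 / 8) * (112 + 0.9 * T) + 0.1 * T - 112
}

#' Temperature-humidity index (THI)
#'
#' \eqn{THI = 41.5 + T + 0.36\,T_d}. Affine in both arguments.
#'
#' @param T air temperature, degrees Celsius.
#' @param Td dew-point temperature, degrees Celsius.
#' @return THI index value (dimensionless).
#' @export
thi <- function(T, Td) {
  stop_if_nonfinite(T, Td)
  41.5 + T + 0.36 * Td
}

#' Equivalent temperature index (ETI)
#'
#' Full quadratic in temperature, relative humidity and wind speed, with
#' temperature-humidity and temperature-wind interaction terms.
#'
#' @param T air temperature, degrees Celsius.
#' @param RH relative humidity, percent (0--100 scale).
#' @param V wind speed, m/s.
#' @return ETI index value.
#' @export
eti <- function(T, RH, V) {
  stop_if_nonfinite(T, RH, V)
  27.88 - 0.456 * T + 0.010754 * T^2 -
    0.4905 * RH + 0.00088 * RH^2 +
    1.1507 * V - 0.12645 * V^2 +
    0.019876 * T * RH - 0.046313 * T * V
}

#' Environmental stress index (ESI)
#'
#' \eqn{ESI = 0.63 T_a - 0.03 RH + 0.002 SR + 0.0054\, T_a RH
#'   - 0.073 (0.1 + SR)^{-1}}, adding solar radiation to the
#' temperature-humidity stress signal.
#'
#' @param Ta ambient (2 m) air temperature, degrees Celsius.
#' @param RH relative humidity, percent.
#' @param SR solar radiation, W/m^2 (non-negative).
#' @return ESI index value.
#' @export
esi <- function(Ta, RH, SR) {
  stop_if_nonfinite(Ta, RH, SR)
  if (any(SR < 0)) stop("solar radiation must be non-negative", call. = FALSE)
  0.63 * Ta - 0.03 * RH + 0.002 * SR + 0.0054 * Ta * RH - 0.073 / (0.1 + SR)
}

#' Black-globe temperature estimate
#'
#' \eqn{T_g = 1.33 T - 2.65 \sqrt{T} + 3.21 \log_{10}(SR + 1) + 3.5},
#' a radiant-heat-adjusted temperature used by the heat load indices. The
#' square-root term restricts the domain to non-negative temperatures; the
#' indices are intended for warm-season conditions.
#'
#' @param T air temperature, degrees Celsius; must be non-negative.
#' @param SR solar radiation, W/m^2 (non-negative).
#' @param log_base base of the logarithm; default 10 per the original heat
#'   load index definitions, natural log available for sensitivity checks.
#' @return Black-globe temperature in degrees Celsius.
#' @export
black_globe_temp <- function(T, SR, log_base = 10) {
  stop_if_nonfinite(T, SR)
  if (any(T < 0))
    stop("black-globe temperature undefined for T < 0 degC", call. = FALSE)
  if (any(SR < 0)) stop("solar radiation must be non-negative", call. = FALSE)
  1.33 * T - 2.65 * sqrt(T) + 3.21 * log(SR + 1, base = log_base) + 3.5
}

#' Heat load index (HLI)
#'
#' \eqn{HLI = 33.2 + 0.2 RH + 1.2 T_g - (0.82 V)^{0.1}
#'   - \log_{10}(0.4 V^2 + 10^{-4})}. The additive guard keeps the
#' logarithm finite at calm wind; \eqn{(0.82V)^{0.1}} is taken as 0 (its
#' limit) at \eqn{V = 0}.
#'
#' @param RH relative humidity, percent.
#' @param Tg black-globe temperature, degrees Celsius.
#' @param V wind speed, m/s (non-negative).
#' @param log_base base of the logarithm (default 10).
#' @return HLI index value, finite for all \eqn{V \ge 0}.
#' @export
hli <- function(RH, Tg, V, log_base = 10) {
  stop_if_nonfinite(RH, Tg, V)
  if (any(V < 0)) stop("wind speed must be non-negative", call. = FALSE)
  wind_pow <- ifelse(V == 0, 0, (0.82 * V)^0.1)
  33.2 + 0.2 * RH + 1.2 * Tg - wind_pow - log(0.4 * V^2 + 1e-4, base = log_base)
}

#' Modified heat load index (HLI_new)
#'
#' Piecewise by black-globe temperature:
#' \eqn{10.66 + 0.28 RH + 1.3 T_g - V} for \eqn{T_g < 25} and
#' \eqn{8.62 + 0.38 RH + 1.55 T_g - 0.5 V + e^{2.4 - V}} for
#' \eqn{T_g \ge 25}. The boundary point \eqn{T_g = 25} is assigned to the
#' upper branch; the function is discontinuous there by construction.
#'
#' @inheritParams hli
#' @return HLI_new index value.
#' @export
hli_new <- function(RH, Tg, V) {
  stop_if_nonfinite(RH, Tg, V)
  if (any(V < 0)) stop("wind speed must be non-negative", call. = FALSE)
  lower <- 10.66 + 0.28 * RH + 1.3 * Tg - V
  upper <- 8.62 + 0.38 * RH + 1.55 * Tg - 0.5 * V + exp(2.4 - V)
  ifelse(Tg < 25, lower, upper)
}

#' Respiratory rate predictor (RRP)
#'
#' \eqn{RRP = 5.4 T + 0.58 RH - 0.63 V + 0.024 SR - 110.9}, a linear
#' predictor of cattle respiratory rate.
#'
#' @param T air temperature, degrees Celsius.
#' @param RH relative humidity, percent.
#' @param V wind speed, m/s.
#' @param SR solar radiation, W/m^2.
#' @return RRP index value.
#' @export
rrp <- function(T, RH, V, SR) {
  stop_if_nonfinite(T, RH, V, SR)
  5.4 * T + 0.58 * RH - 0.63 * V + 0.024 * SR - 110.9
}

#' Compute all six heat-stress indices for a table of daily meteorology
#'
#' Evaluates THI, ETI, ESI, HLI, HLI_new and RRP row-wise. Relative humidity
#' is taken from an \code{RH} column when present, otherwise derived through
#' the humidity chain from sea-level pressure \code{p} and specific humidity
#' \code{q}; the dew point is taken from a \code{Td} column when present,
#' otherwise derived from \code{(T, RH)}. The black-globe temperature
#' \code{Tg} is retained for audit.
#'
#' @param meteo data frame of daily records with columns \code{T} (degC),
#'   \code{V} (m/s), \code{SR} (W/m^2) and either \code{RH} (percent) or the
#'   pair \code{p} (hPa), \code{q} (kg/kg); optional \code{Td} (degC).
#'   Identifier columns such as \code{zone} and \code{date} pass through.
#' @param log_base logarithm base for the heat load indices (default 10).
#' @return The input data frame augmented with columns \code{RH}, \code{Td},
#'   \code{Tg}, \code{THI}, \code{ETI}, \code{ESI}, \code{HLI},
#'   \code{HLI_new}, \code{RRP}.
#' @export
compute_all_indices <- function(meteo, log_base = 10) {
  stopifnot(is.data.frame(meteo))
  need <- c("T", "V", "SR")
  miss <- setdiff(need, names(meteo))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_rh <- "RH" %in% names(meteo) && !anyNA(meteo$RH)
  has_pq <- all(c("p", "q") %in% names(meteo)) &&
    !anyNA(meteo$p) && !anyNA(meteo$q)
  if (!has_rh && !has_pq)
    stop("need either an RH column or both p and q columns", call. = FALSE)
  for (col in intersect(c("T", "Td", "RH", "q", "p", "V", "SR"), names(meteo))) {
    v <- meteo[[col]]
    if (anyNA(v) && col %in% need)
      stop("non-finite values in column ", col, call. = FALSE)
    if (any(!is.finite(v[!is.na(v)])))
      stop("non-finite values in column ", col, call. = FALSE)
  }
  if (any(meteo$V < 0)) stop("wind speed must be non-negative", call. = FALSE)
  if (any(meteo$SR < 0))
    stop("solar radiation must be non-negative", call. = FALSE)

  T <- meteo$T
  RH <- if (has_rh) {
    if (any(meteo$RH < 0 | meteo$RH > 100))
      stop("RH must lie in [0, 100]", call. = FALSE)
    meteo$RH
  } else {
    relative_humidity(vapor_pressure(meteo$p, meteo$q),
                      saturation_vapor_pressure(T))
  }
  Td <- if ("Td" %in% names(meteo) && !anyNA(meteo$Td)) meteo$Td
        else dew_point(T, RH)
  Tg <- black_globe_temp(T, meteo$SR, log_base = log_base)

  out <- meteo
  out$RH <- RH
  out$Td <- Td
  out$Tg <- Tg
  out$THI <- thi(T, Td)
  out$ETI <- eti(T, RH, meteo$V)
  out$ESI <- esi(T, RH, meteo$SR)
  out$HLI <- hli(RH, Tg, meteo$V, log_base = log_base)
  out$HLI_new <- hli_new(RH, Tg, meteo$V)
  out$RRP <- rrp(T, RH, meteo$V, meteo$SR)
  out
}

#' Read a daily meteorology table
#'
#' Reads header-bearing delimited text with columns \code{zone}, \code{date}
#' (ISO-8601), \code{T}, and any of \code{Td}, \code{RH}, \code{q}, \code{p},
#' \code{V}, \code{SR}. Missing optional columns are allowed.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data frame with \code{date} parsed as \code{Date}.
#' @export
read_meteo <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("zone", "date", "T") %in% names(df)))
    stop("meteorology table needs at least zone, date and T columns",
         call. = FALSE)
  df$date <- as.Date(df$date)
  df
}

#' Write a table of daily indices
#'
#' Writes the augmented meteorology table (with Tg and the six index
#' columns) as header-bearing delimited text.
#'
#' @param x data frame, typically from [compute_all_indices()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_indices <- function(x, path, sep = "\t") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
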