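#' Named coefficient presets for the synthetic milk response
#'
#' Coefficient vectors over the six normalized indices used as generating
#' truths: the two near-tied spring milk-yield models (four predictors each,
#' with RRP entering with opposite sign in the two parameterizations — both
#' are kept as presets), the two summer milk-yield models, weak fat/protein
#' vectors of the magnitude the milk-fat and protein fits reach, and a null
#' (all-zero) preset.
#'
#' @return named list of length-6 named numeric vectors
#'   (names \code{THI, ETI, ESI, HLI, HLI_new, RRP}).
#' @export
milk_presets <- function() {
  mk <- function(...) {
    b <- stats::setNames(numeric(6), INDEX_LABELS)
    v <- c(...)
    b[names(v)] <- v
    b
  }
  list(
    spring_yield_mod3 = mk(THI = -3.58, ETI = -0.77, ESI = 5.14, RRP = -2.3),
    spring_yield_mod2 = mk(THI = -3.485, ETI = -0.68, HLI = -0.295,
                           RRP = 3.13),
    summer_yield_mod2 = mk(THI = -1.6, ETI = -0.28, ESI = 1.47),
    summer_yield_mod3 = mk(THI = -1.7, ETI = -0.126, ESI = 2.58, HLI = -0.91),
    fat_weak = mk(THI = -0.9, ESI = -0.45),
    protein_weak = mk(THI = 0.8, HLI_new = 0.55),
    null = mk()
  )
}

#' Default simulation configuration
#'
#' Three climate zones with distinct warm-season climates (a cool semi-arid
#' highland, a mild humid coastal zone, and a warm dry interior), years
#' 2002--2010, months April--September. Daily temperature and humidity follow
#' a seasonal sinusoid plus AR(1) noise (autocorrelation 0.7 for
#' temperature); wind is lognormal, radiation seasonal with additive noise,
#' pressure near 1013 hPa. Milk responses are linear in the six normalized
#' monthly indices with preset coefficients and Gaussian noise calibrated to
#' a target population R^2: 0.5 for spring yield, 0.7 for summer yield, 0.12
#' for fat and protein.
#'
#' @param years integer years (default 2002:2010).
#' @param months integer months (default 4:9, spring + summer).
#' @param seed default seed recorded in the config (can be overridden in
#'   [generate_study()]).
#' @return list of class \code{"hm_sim_config"}.
#' @export
default_sim_config <- function(years = 2002:2010, months = 4:9, seed = 1L) {
  presets <- milk_presets()
  cfg <- list(
    zones = data.frame(
      zone = c("NW", "N", "C"),
      T_mean = c(16, 21, 26),      # warm-season mean 2 m temperature, degC
      T_amp = c(7, 5, 8),          # seasonal half-amplitude, degC
      RH_mean = c(45, 75, 30),     # mean relative humidity, %
      RH_amp = c(-8, -5, -10),     # seasonal RH swing (drier mid-summer)
      V_mean = c(3.0, 2.0, 3.5),   # mean wind speed, m/s
      SR_mean = c(260, 210, 300),  # mean daily solar radiation, W/m^2
      SR_amp = c(60, 50, 70),      # seasonal SR half-amplitude
      stringsAsFactors = FALSE),
    years = years,
    months = months,
    ar = list(T_phi = 0.7, T_sd = 1.5,   # AR(1) coef and innovation sd
              RH_phi = 0.6, RH_sd = 6,
              SR_sd = 35, V_sdlog = 0.35, p_sd = 4),
    # monthly-scale (synoptic) anomalies shared by all days of a zone-month;
    # these survive monthly averaging and carry the between-month variance
    monthly_anom = list(T_sd = 1.2, RH_sd = 8, SR_sd = 40, V_sdlog = 0.25),
    milk = list(
      spring = list(yield = list(beta = presets$spring_yield_mod3,
                                 target_r2 = 0.5),
                    fat = list(beta = presets$fat_weak, target_r2 = 0.12),
                    protein = list(beta = presets$protein_weak,
                                   target_r2 = 0.12)),
      summer = list(yield = list(beta = presets$summer_yield_mod2,
                                 target_r2 = 0.7),
                    fat = list(beta = presets$fat_weak, target_r2 = 0.12),
                    protein = list(beta = presets$protein_weak,
                                   target_r2 = 0.12))),
    seed = as.integer(seed)
  )
  class(cfg) <- "hm_sim_config"
  cfg
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "hm_sim_config"))
  if (nrow(config$zones) < 2) stop("need at least 2 zones", call. = FALSE)
  if (length(config$years) < 3) stop("need at least 3 years", call. = FALSE)
  if (config$ar$T_phi < 0 || config$ar$T_phi >= 1)
    stop("AR(1) coefficient must lie in [0, 1)", call. = FALSE)
  for (season in names(config$milk))
    for (m in config$milk[[season]]) {
      if (!is.null(m$target_r2) &&
          (m$target_r2 <= 0 || m$target_r2 >= 1) && any(m$beta != 0))
        stop("target R^2 must lie in (0, 1)", call. = FALSE)
    }
  invisible(config)
}

ar1_series <- function(n, phi, sd_innov) {
  stats::filter(stats::rnorm(n, sd = sd_innov), phi,
                method = "recursive")
}

#' Simulate daily meteorology for all zones and years
#'
#' Per zone and day: temperature is a seasonal sinusoid (peaking in
#' mid-July) plus AR(1) noise; relative humidity likewise, clamped to
#' [5, 100]; wind is lognormal; radiation seasonal with Gaussian noise,
#' clamped non-negative; pressure is Gaussian around 1013 hPa. Specific
#' humidity is back-solved from (RH, T, p) through the humidity chain, so
#' recomputing RH from (p, q, T) reproduces the stored value.
#'
#' @param config an \code{hm_sim_config}.
#' @param seed integer seed (default the config's).
#' @return data frame of daily records: \code{zone}, \code{date}, \code{T},
#'   \code{RH}, \code{q}, \code{p}, \code{V}, \code{SR}.
#' @export
simulate_meteorology <- function(config = default_sim_config(),
                                 seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  dates <- as.Date(unlist(lapply(config$years, function(yr) {
    d <- seq(as.Date(sprintf("%d-01-01", yr)),
             as.Date(sprintf("%d-12-31", yr)), by = "day")
    d[as.integer(format(d, "%m")) %in% config$months]
  })), origin = "1970-01-01")
  doy <- as.integer(format(dates, "%j"))
  seasonal <- sin(2 * pi * (doy - 105) / 365)  # peaks near mid-July
  nd <- length(dates)
  ym <- format(dates, "%Y-%m")
  month_id <- match(ym, unique(ym))
  nm <- max(month_id)
  ar <- config$ar
  ma <- config$monthly_anom
  out <- do.call(rbind, lapply(seq_len(nrow(config$zones)), function(zi) {
    z <- config$zones[zi, ]
    aT <- stats::rnorm(nm, sd = ma$T_sd)[month_id]
    aRH <- stats::rnorm(nm, sd = ma$RH_sd)[month_id]
    aSR <- stats::rnorm(nm, sd = ma$SR_sd)[month_id]
    aV <- stats::rnorm(nm, sd = ma$V_sdlog)[month_id]
    T <- z$T_mean + z$T_amp * seasonal + aT +
      as.numeric(ar1_series(nd, ar$T_phi, ar$T_sd))
    T <- pmax(T, 0.5)  # black-globe domain; warm-season sims stay above this
    RH <- z$RH_mean + z$RH_amp * seasonal + aRH +
      as.numeric(ar1_series(nd, ar$RH_phi, ar$RH_sd))
    RH <- pmin(pmax(RH, 5), 100)
    V <- stats::rlnorm(nd, meanlog = log(z$V_mean) + aV, sdlog = ar$V_sdlog)
    SR <- pmax(z$SR_mean + z$SR_amp * seasonal + aSR +
                 stats::rnorm(nd, sd = ar$SR_sd), 0)
    p <- 1013 + stats::rnorm(nd, sd = ar$p_sd)
    e <- (RH / 100) * saturation_vapor_pressure(T)
    q <- e / (1.6077 * p)
    data.frame(zone = z$zone, date = dates, T = T, RH = RH, q = q, p = p,
               V = V, SR = SR, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate milk components as linear responses to normalized indices
#'
#' \eqn{y = Z\beta + \epsilon} with \eqn{\epsilon \sim N(0, \sigma^2)} and
#' \eqn{\sigma^2 = Var(Z\beta)(1 - R^2)/R^2}, so the population R^2 of the
#' generating model equals \code{target_r2}. An all-zero \eqn{\beta} gives
#' pure standard-normal noise.
#'
#' @param Z matrix (or data frame) of normalized index values, columns named
#'   by the six index labels.
#' @param beta named length-6 coefficient vector (zeros allowed).
#' @param target_r2 target population R^2 in (0, 1); ignored when
#'   \code{beta} is all zero.
#' @param seed optional integer seed.
#' @return list with \code{y}, \code{signal}, \code{noise_sd},
#'   \code{support} (labels with nonzero beta).
#' @export
simulate_milk <- function(Z, beta, target_r2, seed = NULL) {
  Z <- as.matrix(Z)
  stopifnot(all(INDEX_LABELS %in% colnames(Z)),
            all(names(beta) %in% INDEX_LABELS))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Z)
  if (all(beta == 0)) {
    y <- stats::rnorm(n)
    return(list(y = y, signal = rep(0, n), noise_sd = 1,
                support = character(0)))
  }
  stopifnot(target_r2 > 0, target_r2 < 1)
  signal <- drop(Z[, names(beta), drop = FALSE] %*% beta)
  vs <- stats::var(signal)
  if (vs == 0)
    stop("signal variance is zero for a nonzero beta", call. = FALSE)
  noise_sd <- sqrt(vs * (1 - target_r2) / target_r2)
  list(y = signal + stats::rnorm(n, sd = noise_sd),
       signal = signal, noise_sd = noise_sd,
       support = names(beta)[beta != 0])
}

#' Generate a complete synthetic study
#'
#' Composes [simulate_meteorology()], [compute_all_indices()], monthly
#' aggregation, per-season z-scoring of the indices (zones pooled) and
#' [simulate_milk()] for every season and predictand in the config. The
#' generating coefficients and noise sds are returned alongside the data.
#'
#' @param config an \code{hm_sim_config}.
#' @param seed integer seed governing every random draw (default the
#'   config's).
#' @return object of class \code{"hm_study"}: list with \code{daily}
#'   (meteorology + indices), \code{monthly} (one row per zone-year-month:
#'   season, z-scored indices, simulated \code{yield}, \code{fat},
#'   \code{protein}), \code{norm_params} (per-season index normalization),
#'   \code{truth} (per season-predictand: beta, support, noise_sd,
#'   target_r2), \code{config}, \code{seed}.
#' @export
generate_study <- function(config = default_sim_config(),
                           seed = config$seed) {
  validate_sim_config(config)
  met <- simulate_meteorology(config, seed = seed)
  daily <- compute_all_indices(met)
  mon <- stats::aggregate(
    daily[c("Tg", INDEX_LABELS)],
    by = list(zone = daily$zone,
              year = as.integer(format(daily$date, "%Y")),
              month = as.integer(format(daily$date, "%m"))),
    FUN = mean)
  mon$season <- season_of(mon$month)
  mon <- mon[order(mon$zone, mon$year, mon$month), , drop = FALSE]
  rownames(mon) <- NULL

  norm_params <- list()
  truth <- list()
  for (cl in c("yield", "fat", "protein")) mon[[cl]] <- NA_real_
  # deterministic sub-seeds per season/predictand, derived from the main seed
  sub <- 0L
  for (season in names(config$milk)) {
    rows <- which(mon$season == season)
    zs <- zscore(mon[rows, , drop = FALSE], INDEX_LABELS)
    mon[rows, INDEX_LABELS] <- zs$data[INDEX_LABELS]
    norm_params[[season]] <- zs$params
    for (pv in names(config$milk[[season]])) {
      sub <- sub + 1L
      spec_m <- config$milk[[season]][[pv]]
      sim <- simulate_milk(as.matrix(zs$data[INDEX_LABELS]), spec_m$beta,
                           spec_m$target_r2,
                           seed = (seed * 131L + sub) %% .Machine$integer.max)
      mon[rows, pv] <- sim$y
      truth[[paste(season, pv, sep = ".")]] <-
        list(season = season, predictand = pv, beta = spec_m$beta,
             support = sim$support, noise_sd = sim$noise_sd,
             target_r2 = if (all(spec_m$beta == 0)) NA_real_
                         else spec_m$target_r2)
    }
  }
  structure(list(daily = daily, monthly = mon, norm_params = norm_params,
                 truth = truth, config = config, seed = seed),
            class = "hm_study")
}

#' @export
print.hm_study <- function(x, ...) {
  cat("Synthetic heat-stress study: ", nrow(x$config$zones), " zones, ",
      length(x$config$years), " years, months ",
      paste(range(x$config$months), collapse = "-"), "\n", sep = "")
  cat("  daily records: ", nrow(x$daily), "; monthly rows: ",
      nrow(x$monthly), " (", sum(x$monthly$season == "spring"), " spring, ",
      sum(x$monthly$season == "summer"), " summer)\n", sep = "")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
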