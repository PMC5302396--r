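test_that("humidity chain evaluates to its closed-form values", {
  expect_equal(saturation_vapor_pressure(0), 6.1078)
  expect_equal(saturation_vapor_pressure(20), 23.35, tolerance = 1e-3)
  expect_gt(saturation_vapor_pressure(30), saturation_vapor_pressure(20))

  expect_equal(vapor_pressure(1013.25, 0), 0)
  expect_equal(vapor_pressure(1013.25, 0.010), 16.290, tolerance = 1e-4)
  expect_equal(vapor_pressure(1000, 0.00622), 10.000, tolerance = 1e-4)

  expect_equal(relative_humidity(23.354, 23.354), 100)
  expect_equal(relative_humidity(0, 23.354), 0)
  expect_equal(relative_humidity(11.677, 23.354), 50, tolerance = 1e-6)

  expect_equal(dew_point(20, 100), 20)
  expect_equal(dew_point(20, 50), 9.21, tolerance = 1e-3)
  expect_lt(dew_point(25, 40), dew_point(25, 80))
})

test_that("humidity chain rejects out-of-domain inputs", {
  expect_error(saturation_vapor_pressure(-240), "-235")
  expect_error(vapor_pressure(1000, -0.001), "non-negative")
  expect_error(vapor_pressure(0, 0.01), "positive")
  expect_error(relative_humidity(10, 0), "positive")
  expect_error(dew_point(20, 0), "positive")
  expect_warning(relative_humidity(25, 20), "clipped")
  expect_equal(suppressWarnings(relative_humidity(25, 20)), 100)
})

test_that("each index reproduces its hand-computed spot values", {
  expect_equal(thi(0, 0), 41.5)
  expect_equal(thi(30, 20), 78.7)
  expect_equal(thi(25, dew_point(25, 100)), 75.5)  # 41.5 + 1.36 T at saturation

  expect_equal(eti(0, 0, 0), 27.88)
  expect_equal(eti(20, 0, 0), 23.0616)
  expect_equal(eti(30, 60, 2), 32.410, tolerance = 1e-4)

  expect_equal(esi(0, 0, 0), -0.73)
  expect_equal(esi(25, 50, 0), 20.27)
  expect_equal(esi(30, 40, 500), 25.18, tolerance = 1e-4)

  expect_equal(black_globe_temp(0, 0), 3.5)
  expect_equal(black_globe_temp(25, 0), 23.5)
  expect_equal(black_globe_temp(25, 500), 32.17, tolerance = 1e-3)

  expect_equal(hli(0, 0, 0), 37.2)  # 33.2 - log10(1e-4)
  expect_equal(hli(50, 23.5, 0), 75.4)
  expect_equal(hli(50, 30, 2), 77.945, tolerance = 1e-4)

  expect_equal(hli_new(0, 0, 0), 10.66)
  expect_equal(hli_new(50, 20, 1), 49.66)
  expect_equal(hli_new(50, 30, 2.4), 73.92)  # upper branch, e^0 = 1

  expect_equal(rrp(0, 0, 0, 0), -110.9)
  expect_equal(rrp(30, 50, 2, 500), 90.84)
  expect_equal(rrp(20, 60, 0, 0), 31.9)
})

test_that("saturation identity holds across the temperature range", {
  T <- seq(-20, 45, by = 0.5)
  expect_equal(dew_point(T, 100), T, tolerance = 1e-9)
})

test_that("THI and RRP are affine: midpoint of inputs maps to midpoint of outputs", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_meteo_input(); b <- random_meteo_input()
    expect_equal(thi((a$T + b$T) / 2, (a$Td + b$Td) / 2),
                 (thi(a$T, a$Td) + thi(b$T, b$Td)) / 2, tolerance = 1e-13)
    expect_equal(rrp((a$T + b$T) / 2, (a$RH + b$RH) / 2, (a$V + b$V) / 2,
                     (a$SR + b$SR) / 2),
                 (rrp(a$T, a$RH, a$V, a$SR) + rrp(b$T, b$RH, b$V, b$SR)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("indices agree with an independent transcription on random inputs", {
  set.seed(21)
  for (i in 1:200) {
    m <- random_meteo_input()
    Tg <- black_globe_temp(m$T, m$SR)
    got <- c(THI = thi(m$T, m$Td), ETI = eti(m$T, m$RH, m$V),
             ESI = esi(m$T, m$RH, m$SR), HLI = hli(m$RH, Tg, m$V),
             HLI_new = hli_new(m$RH, Tg, m$V),
             RRP = rrp(m$T, m$RH, m$V, m$SR))
    want <- vapply(INDEX6, oracle_index, numeric(1),
                   T = m$T, Td = m$Td, RH = m$RH, V = m$V, SR = m$SR)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("modified HLI branches on black-globe temperature only", {
  # continuous within each branch
  tg_lo <- seq(0, 24.99, length.out = 50)
  v_lo <- hli_new(40, tg_lo, 2)
  expect_true(all(abs(diff(v_lo)) < 1.3 * diff(tg_lo)[1] + 1e-9))
  tg_hi <- seq(25, 40, length.out = 50)
  v_hi <- hli_new(40, tg_hi, 2)
  expect_true(all(diff(v_hi) > 0))
  # boundary assigned to the upper branch
  expect_equal(hli_new(40, 25, 2),
               8.62 + 0.38 * 40 + 1.55 * 25 - 0.5 * 2 + exp(2.4 - 2))
})

test_that("black-globe temperature rejects sub-zero air temperature", {
  expect_error(black_globe_temp(-1, 100), "undefined")
})

test_that("compute_all_indices matches scalar ops and derives RH and Td", {
  met <- data.frame(zone = "A", date = as.Date("2005-05-01") + 0:4,
                    T = c(18, 22, 26, 30, 34), RH = c(30, 45, 60, 75, 90),
                    V = c(0, 1, 2, 4, 8), SR = c(0, 100, 300, 600, 900))
  out <- compute_all_indices(met)
  expect_equal(out$THI, thi(met$T, dew_point(met$T, met$RH)))
  expect_equal(out$ETI, eti(met$T, met$RH, met$V))
  expect_equal(out$RRP, rrp(met$T, met$RH, met$V, met$SR))
  expect_equal(out$HLI, hli(met$RH, black_globe_temp(met$T, met$SR), met$V))

  # RH derived through the humidity chain when only (p, q) given
  ew <- saturation_vapor_pressure(met$T)
  e <- 0.55 * ew
  met2 <- met
  met2$RH <- NULL
  met2$p <- rep(1010, 5)
  met2$q <- e / (1.6077 * met2$p)
  out2 <- compute_all_indices(met2)
  expect_equal(out2$RH, rep(55, 5), tolerance = 1e-9)
  expect_equal(out2$THI, thi(met2$T, dew_point(met2$T, out2$RH)))

  # batch evaluation is elementwise: row order does not matter
  perm <- c(3, 1, 5, 2, 4)
  out_perm <- compute_all_indices(met[perm, ])
  expect_equal(out_perm$HLI_new, out$HLI_new[perm])

  met_bad <- met2
  met_bad$q[2] <- -1e-4
  expect_error(compute_all_indices(met_bad), "non-negative")
  met_none <- met
  met_none$RH <- NULL
  expect_error(compute_all_indices(met_none), "RH")
})

test_that("meteorology tables round-trip through the reader and writer", {
  met <- data.frame(zone = "Z1", date = as.Date("2004-07-10") + 0:2,
                    T = c(25, 27, 29), RH = c(50, 40, 30),
                    V = c(2, 3, 1), SR = c(400, 500, 600))
  out <- compute_all_indices(met)
  f <- tempfile(fileext = ".tsv")
  write_indices(out, f)
  back <- read_meteo(f)
  expect_equal(back$THI, out$THI, tolerance = 1e-12)
  expect_equal(back$date, out$date)
  unlink(f)
})
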