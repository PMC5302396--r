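# single centred predictor with (1/n) sum x^2 = 1 and (1/n) sum xy = 0.8,
# predictand with unit second moment
single_predictor_design <- function() {
  x <- c(-1.5, -0.5, 0.5, 1.5) / sqrt(1.25)
  resid <- c(1, -1, -1, 1)                      # orthogonal to x, mean 0
  y <- 0.8 * x + resid * sqrt((1 - 0.64) / mean(resid^2))
  design_matrix(matrix(x, ncol = 1), y, labels = "x1")
}

test_that("objective matches its hand-expanded value", {
  des <- single_predictor_design()
  expect_equal(mean(des$y^2), 1, tolerance = 1e-12)
  expect_equal(lasso_objective(numeric(1), des, 0.7), 1, tolerance = 1e-12)
  # J(0.6; lambda = 0.4) = 1 - 2*0.8*0.6 + 0.36 + 0.24
  expect_equal(lasso_objective(0.6, des, 0.4), 1 - 0.96 + 0.36 + 0.24,
               tolerance = 1e-12)
  expect_error(lasso_objective(c(1, 2), des, 0.1), "length")
})

test_that("single-predictor fit equals the soft-threshold closed form", {
  des <- single_predictor_design()
  expect_equal(unname(lasso_fit(des, lambda = 0.4)), 0.6, tolerance = 1e-9)
  expect_equal(unname(lasso_fit(des, lambda = 1.6)), 0, tolerance = 1e-12)
  expect_equal(unname(lasso_fit(des, lambda = 0)), 0.8, tolerance = 1e-9)
})

test_that("penalty-free fit equals least squares", {
  set.seed(51)
  inst <- random_lasso_instance(n = 50, k = 6)
  des <- design_matrix(inst$X, inst$y, labels = paste0("x", 1:6),
                       center_tol = 1e-6)
  beta <- lasso_fit(des, lambda = 0, tol = 1e-10)
  ols <- qr.solve(inst$X, inst$y)
  expect_equal(unname(beta), unname(ols), tolerance = 1e-6)
})

test_that("all coefficients vanish once lambda reaches twice the max correlation", {
  set.seed(52)
  X <- make_unit_cols(40, 2, orthonormal = TRUE)
  y <- drop(X %*% c(0.8, 0.3))           # (1/n) X'y = (0.8, 0.3)
  des <- design_matrix(X, y, labels = c("a", "b"), center_tol = 1e-10)
  expect_equal(unname(lasso_fit(des, lambda = 1.7)), c(0, 0))
  expect_true(any(lasso_fit(des, lambda = 1.5) != 0))
})

test_that("orthonormal designs follow the soft-threshold solution at every lambda", {
  set.seed(53)
  X <- make_unit_cols(60, 5, orthonormal = TRUE)
  beta_true <- c(2, -1, 0.5, 0, -0.25)
  y <- drop(X %*% beta_true) + rnorm(60, sd = 0.3)
  y <- y - mean(y)
  des <- design_matrix(X, y, labels = paste0("x", 1:5), center_tol = 1e-9)
  c0 <- drop(crossprod(X, y)) / nrow(X)
  for (lam in c(0, 0.05, 0.2, 0.5, 1, 2, 5)) {
    got <- lasso_fit(des, lam, tol = 1e-10)
    expect_equal(unname(got), unname(soft_oracle(c0, lam / 2)),
                 tolerance = 1e-7)
  }
})

test_that("objective is non-increasing across coordinate-descent sweeps", {
  set.seed(54)
  for (i in 1:10) {
    inst <- random_lasso_instance(rho = 0.8)
    des <- design_matrix(inst$X, inst$y, labels = paste0("x", 1:6),
                         center_tol = 1e-6)
    beta <- lasso_fit(des, lambda = 0.3, trace = TRUE)
    tr <- attr(beta, "objective_trace")
    expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("coordinate descent matches a proximal-gradient oracle", {
  set.seed(55)
  for (i in 1:25) {
    inst <- random_lasso_instance(n = 40, k = 6, rho = runif(1, 0.3, 0.8))
    des <- design_matrix(inst$X, inst$y, labels = paste0("x", 1:6),
                         center_tol = 1e-6)
    lam <- runif(1, 0.02, 1.5)
    got <- lasso_fit(des, lam, tol = 1e-9)
    want <- fista_lasso(inst$X, inst$y, lam)
    expect_equal(lasso_objective(got, des, lam),
                 lasso_objective(want, des, lam), tolerance = 1e-8)
    expect_equal(unname(got), want, tolerance = 1e-5)
  }
})

test_that("path starts empty at lambda_max, is warm-started and deterministic", {
  set.seed(56)
  inst <- random_lasso_instance(n = 60, k = 6)
  des <- design_matrix(inst$X, inst$y, labels = paste0("x", 1:6),
                       center_tol = 1e-6)
  p1 <- lasso_path(des, grid_size = 60)
  expect_length(p1$supports[[1]], 0)
  expect_equal(p1$lambda[1],
               2 * max(abs(crossprod(inst$X, inst$y) / nrow(inst$X))))
  expect_true(all(diff(p1$lambda) < 0))
  p2 <- lasso_path(des, grid_size = 60)
  expect_identical(p1$beta, p2$beta)
  # grid is log-spaced down to lambda_max * ratio
  expect_equal(p1$lambda[60], p1$lambda[1] * 1e-4, tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  X <- cbind(c(-1, 0, 1, 0), 0)
  expect_error(design_matrix(X, c(-1, 0, 1, 0)), "zero column")
  expect_error(design_matrix(matrix(1:4, 2), c(5, 6)), "centred")
})

test_that("candidate extraction keeps persistent, distinct, nonempty supports", {
  sup <- list(character(0), character(0), "A", "A", c("A", "B"),
              c("A", "B"), c("A", "B", "C"))
  path <- fake_path(sup)
  got <- candidate_supports(path, persistence_m = 2)
  expect_length(got, 2)
  expect_equal(got[[1]]$support, "A")
  expect_equal(got[[2]]$support, c("A", "B"))
  # lambda range covers the run (largest-lambda run first)
  expect_gt(got[[1]]$lambda_range[2], got[[2]]$lambda_range[2])

  got1 <- candidate_supports(path, persistence_m = 1)
  expect_equal(lapply(got1, `[[`, "support"),
               list("A", c("A", "B"), c("A", "B", "C")))

  empty <- candidate_supports(fake_path(rep(list(character(0)), 5)))
  expect_length(empty, 0)

  # a support that reappears is only reported once
  sup2 <- list("A", "A", c("A", "B"), c("A", "B"), "A", "A")
  got2 <- candidate_supports(fake_path(sup2), persistence_m = 2)
  expect_length(got2, 2)
})
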