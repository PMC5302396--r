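# Independent oracles used across the suite. These deliberately share no code
# with the package: the index transcription is coefficient-table driven, and
# the LASSO oracle is a proximal-gradient (FISTA) scheme rather than
# coordinate descent.

INDEX6 <- c("THI", "ETI", "ESI", "HLI", "HLI_new", "RRP")

# direct transcription of the six index definitions, evaluated term by term
oracle_index <- function(name, T, Td, RH, V, SR) {
  Tg <- 1.33 * T - 2.65 * T^0.5 + 3.21 * log10(SR + 1) + 3.5
  switch(name,
    THI = 41.5 + T + 0.36 * Td,
    ETI = {
      terms <- c(27.88, -0.456 * T, 0.010754 * T^2, -0.4905 * RH,
                 0.00088 * RH^2, 1.1507 * V, -0.12645 * V^2,
                 0.019876 * T * RH, -0.046313 * T * V)
      sum(terms)
    },
    ESI = 0.63 * T - 0.03 * RH + 0.002 * SR + 0.0054 * T * RH -
      0.073 * (0.1 + SR)^(-1),
    HLI = 33.2 + 0.2 * RH + 1.2 * Tg -
      (if (V > 0) (0.82 * V)^0.1 else 0) - log10(0.4 * V^2 + 0.0001),
    HLI_new = if (Tg < 25) 10.66 + 0.28 * RH + 1.3 * Tg - V
              else 8.62 + 0.38 * RH + 1.55 * Tg - 0.5 * V + exp(2.4 - V),
    RRP = 5.4 * T + 0.58 * RH - 0.63 * V + 0.024 * SR - 110.9,
    stop("unknown index"))
}

# random valid scalar meteorological input (warm-season ranges)
random_meteo_input <- function() {
  T <- runif(1, 1, 42)
  list(T = T, RH = runif(1, 5, 100), V = runif(1, 0, 12),
       SR = runif(1, 0, 1000),
       Td = (runif(1, 5, 100) / 100)^(1 / 8) * (112 + 0.9 * T) +
         0.1 * T - 112)
}

soft_oracle <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# FISTA proximal-gradient minimizer of (1/N)||y - Xb||^2 + lambda ||b||_1
fista_lasso <- function(X, y, lambda, max_iter = 50000, tol = 1e-13) {
  n <- nrow(X)
  G <- crossprod(X) / n
  c0 <- drop(crossprod(X, y)) / n
  L <- 2 * max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  beta <- numeric(ncol(X))
  z <- beta
  s <- 1
  for (i in seq_len(max_iter)) {
    grad <- 2 * (drop(G %*% z) - c0)
    bnew <- soft_oracle(z - step * grad, step * lambda)
    snew <- (1 + sqrt(1 + 4 * s^2)) / 2
    z <- bnew + ((s - 1) / snew) * (bnew - beta)
    done <- max(abs(bnew - beta)) < tol
    beta <- bnew
    s <- snew
    if (done && i > 20) break
  }
  beta
}

# n x k matrix with exactly centred columns, (1/n) sum x^2 = 1 per column,
# and mutually orthogonal columns when orthonormal = TRUE
make_unit_cols <- function(n, k, orthonormal = FALSE) {
  X <- matrix(rnorm(n * k), n, k)
  X <- sweep(X, 2, colMeans(X))
  if (orthonormal) X <- qr.Q(qr(X)) * sqrt(n)  # columns: sum x^2 = n
  X <- sweep(X, 2, sqrt(colMeans(X^2)), "/")
  sweep(X, 2, colMeans(X))  # re-centre against rounding
}

# correlated random LASSO instance
random_lasso_instance <- function(n = 40, k = 6, rho = 0.6) {
  Z <- matrix(rnorm(n * k), n, k)
  common <- rnorm(n)
  X <- sqrt(rho) * common + sqrt(1 - rho) * Z
  X <- sweep(X, 2, colMeans(X))
  beta <- sample(c(-2, -1, 0, 0, 1, 2))
  y <- drop(X %*% beta) + rnorm(n)
  y <- y - mean(y)
  list(X = X, y = y)
}

# build a minimal path object with prescribed supports (for the
# candidate-extraction rule)
fake_path <- function(supports, labels = c("A", "B", "C")) {
  g <- length(supports)
  structure(list(lambda = exp(seq(log(2), log(0.01), length.out = g)),
                 beta = matrix(0, g, length(labels),
                               dimnames = list(NULL, labels)),
                 supports = supports, labels = labels),
            class = "hm_lasso_path")
}
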