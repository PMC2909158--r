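# Shared oracles and small fixtures, built in code at test time.

# Tiny balanced sire dataset for sampler validation.
tiny_sim <- function(nu_true = Inf, n_sires = 15, progeny = 20,
                     n_herds = 20, seed = 42) {
  simulate_dataset(sim_config(n_sires = n_sires, progeny_per_sire = progeny,
                              n_herds = n_herds, nu_true = nu_true,
                              seed = seed))
}

# Independent dense assembly and solve of Henderson's mixed model
# equations with heterogeneous residual precisions lambda_i * R0^-1.
# Built from scratch (dense, loop-based) so it shares nothing with the
# sampler's sparse Kronecker path.
dense_mme_solution <- function(frame, G0, H0, R0, lambda) {
  m <- frame$m
  X <- as.matrix(frame$X)
  Z <- as.matrix(frame$Z)
  W <- as.matrix(frame$W)
  Tm <- cbind(X, Z, W)
  cT <- ncol(Tm)
  N <- cT * m
  R0i <- solve(R0)
  C <- matrix(0, N, N)
  rhs <- numeric(N)
  for (i in seq_len(frame$n)) {
    ti <- Tm[i, ]
    nz <- which(ti != 0)
    for (j in nz) for (k in nz) {
      rj <- (j - 1) * m + seq_len(m)
      rk <- (k - 1) * m + seq_len(m)
      C[rj, rk] <- C[rj, rk] + ti[j] * ti[k] * lambda[i] * R0i
    }
    for (j in nz) {
      rj <- (j - 1) * m + seq_len(m)
      rhs[rj] <- rhs[rj] + ti[j] * lambda[i] * (R0i %*% frame$y[i, ])
    }
  }
  p <- ncol(X)
  qz <- ncol(Z)
  gsc <- p * m + seq_len(qz * m)
  C[gsc, gsc] <- C[gsc, gsc] + kronecker(frame$A_inv, solve(G0))
  hsc <- (p + qz) * m + seq_len(ncol(W) * m)
  C[hsc, hsc] <- C[hsc, hsc] + kronecker(diag(ncol(W)), solve(H0))
  Ci <- solve(C)
  list(solution = matrix(Ci %*% rhs, cT, m, byrow = TRUE), C_inv = Ci)
}

# Hand tabular-method relationship coefficients for named pedigrees are
# computed inline in the pedigree tests.

# Brute-force Kendall tau-b by exhaustive pair counting.
kendall_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j])
    dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Numerical-integration oracle for the mixing-scale full conditional:
# normalized density of lambda given residual e, scale R0, df nu on a grid.
lambda_conditional_grid <- function(e, R0, nu, grid) {
  m <- length(e)
  R0i <- solve(R0)
  q <- drop(t(e) %*% R0i %*% e)
  # prior Gamma(nu/2, nu/2) times N(e; 0, R0/lambda) likelihood
  logk <- stats::dgamma(grid, nu / 2, rate = nu / 2, log = TRUE) +
    (m / 2) * log(grid) - grid * q / 2
  w <- exp(logk - max(logk))
  w / sum(w)
}

# Quadrature oracle for the lambda-marginalized observation density:
# integral of N(y; mu, R0/lambda) dGamma(lambda; nu/2, nu/2).
t_density_quadrature <- function(e, R0, nu) {
  m <- length(e)
  R0i <- solve(R0)
  q <- drop(t(e) %*% R0i %*% e)
  ld <- determinant(R0, logarithm = TRUE)$modulus
  f <- function(lam) {
    exp(stats::dgamma(lam, nu / 2, rate = nu / 2, log = TRUE) -
          0.5 * (m * log(2 * pi) + ld - m * log(lam) + lam * q))
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
}
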