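test_that("location update matches the dense MME solution with fixed variances", {
  dat <- tiny_sim(nu_true = Inf, seed = 42)
  fr <- build_model_frame(dat$phenotypes, genetic = "sire")
  vc <- list(G0 = matrix(c(2, 1.5, 1.5, 4), 2), H0 = diag(c(1.5, 6)),
             R0 = matrix(c(15, 4, 4, 20), 2))
  ch <- fit_mixed(fr, fit_config(burn_in = 50, n_keep = 4000, seed = 8,
                                 residual_family = "normal",
                                 update_covariances = FALSE,
                                 start_vc = vc))
  oracle <- dense_mme_solution(fr, vc$G0, vc$H0, vc$R0,
                               rep(1, fr$n))
  # with fixed variances the joint draws are iid from the exact Gaussian
  # full conditional, so the running mean converges at rate 1/sqrt(G)
  post_sd <- sqrt(diag(oracle$C_inv))
  diff <- as.vector(t(ch$effect_mean)) - as.vector(t(oracle$solution))
  expect_lt(max(abs(diff) / post_sd), 5 / sqrt(4000) * 3)

  # empirical variance of a sampled fixed effect matches the C diagonal
  b11 <- ch$samples[, "b[gender:g1:trait1]"]
  expect_equal(var(b11), oracle$C_inv[1, 1], tolerance = 0.1)
})

test_that("all phenotypes zero gives zero posterior means by symmetry", {
  dat <- tiny_sim(nu_true = Inf, seed = 43)
  ph <- dat$phenotypes
  ph$trait1 <- 0
  ph$trait2 <- 0
  ph <- phenotype_table(ph, traits = c("trait1", "trait2"), fixed = "gender",
                        random = "herd", sire = "sire")
  fr <- build_model_frame(ph)
  vc <- list(G0 = diag(2), H0 = diag(2), R0 = diag(2))
  ch <- fit_mixed(fr, fit_config(burn_in = 20, n_keep = 500, seed = 9,
                                 residual_family = "normal",
                                 update_covariances = FALSE, start_vc = vc))
  expect_lt(max(abs(ch$effect_mean)), 0.2)
})

test_that("mixing-scale full conditional has the Gamma form", {
  R0 <- matrix(c(15, 4, 4, 20), 2)
  nu <- 4
  # zero residual: conditional mean (nu + m)/nu = 1.5
  set.seed(11)
  lam0 <- sample_mixture_scales(matrix(0, 1e5, 2), R0, nu)
  expect_equal(mean(lam0), 1.5, tolerance = 0.01)
  # fixed nonzero residual: MC mean matches (nu + m)/(nu + e'R0^-1 e)
  e <- c(5, -3)
  q <- drop(t(e) %*% solve(R0) %*% e)
  set.seed(12)
  lam <- sample_mixture_scales(matrix(e, 1e5, 2, byrow = TRUE), R0, nu)
  expect_equal(mean(lam), (nu + 2) / (nu + q), tolerance = 0.01)

  # density check against the numerical-integration oracle on a grid
  grid <- seq(0.001, 8, length.out = 4000)
  oracle <- lambda_conditional_grid(e, R0, nu, grid)
  ours <- dgamma(grid, (nu + 2) / 2, rate = (nu + q) / 2)
  expect_equal(ours / sum(ours), oracle, tolerance = 1e-6)
})

test_that("covariance updates match inverse-Wishart closed-form means", {
  dat <- tiny_sim(nu_true = Inf, seed = 44)
  fr <- build_model_frame(dat$phenotypes, genetic = "sire")
  set.seed(13)
  B <- matrix(rnorm((2 + ncol(fr$Z) + fr$r) * 2), ncol = 2)
  E <- matrix(rnorm(fr$n * 2), ncol = 2)
  lambda <- rgamma(fr$n, 2, 2)
  draws <- replicate(3000, sample_covariances(fr, B, E, lambda),
                     simplify = FALSE)
  m <- 2
  Se <- crossprod(sqrt(lambda) * E)
  R0m <- Reduce(`+`, lapply(draws, `[[`, "R0")) / 3000
  expect_equal(R0m, Se / (fr$n - m - 1), tolerance = 0.02)
  Bg <- B[2 + seq_len(ncol(fr$Z)), ]
  Sg <- crossprod(Bg, fr$A_inv %*% Bg)
  G0m <- Reduce(`+`, lapply(draws, `[[`, "G0")) / 3000
  expect_equal(G0m, Sg / (fr$q_ind - m - 1), tolerance = 0.1)
  Bh <- B[2 + ncol(fr$Z) + seq_len(fr$r), ]
  H0m <- Reduce(`+`, lapply(draws, `[[`, "H0")) / 3000
  expect_equal(H0m, crossprod(Bh) / (fr$r - m - 1), tolerance = 0.15)
  # every draw is symmetric positive definite
  pd <- vapply(draws[1:500], function(d) {
    all(vapply(d, function(M) {
      isSymmetric(M, tol = 1e-8) &&
        min(eigen(M, TRUE, TRUE)$values) > 0
    }, logical(1)))
  }, logical(1))
  expect_true(all(pd))
})

test_that("degrees-of-freedom MH targets the Gamma-likelihood posterior", {
  set.seed(14)
  lambda <- rgamma(2500, 2, 2)  # true nu = 4
  nu <- 8
  draws <- numeric(6000)
  for (j in seq_along(draws)) {
    st <- sample_df(nu, lambda, proposal_sd = 0.6)
    nu <- st$nu
    draws[j] <- nu
  }
  draws <- draws[-(1:1000)]
  # grid oracle: normalized posterior over nu of the Gamma likelihood
  grid <- seq(2, 30, by = 0.005)
  sl <- sum(log(lambda))
  s <- sum(lambda)
  logk <- length(lambda) * (grid / 2 * log(grid / 2) - lgamma(grid / 2)) +
    (grid / 2 - 1) * sl - grid / 2 * s
  w <- exp(logk - max(logk))
  post_mean <- sum(grid * w) / sum(w)
  post_mode <- grid[which.max(w)]
  expect_equal(mean(draws), post_mean, tolerance = 0.05)
  expect_lt(abs(post_mode - 4), 0.5)

  # truncation rule: proposals below 2 are evaluated at 2, so the chain
  # never leaves [2, nu_max] and can sit exactly on the boundary
  set.seed(15)
  lam_low <- rgamma(500, 0.5, 0.5)  # pushes nu toward the boundary
  nu <- 2.2
  tr <- replicate(2000, {
    st <- sample_df(nu, lam_low, proposal_sd = 3)
    nu <<- st$nu
    nu
  })
  expect_gte(min(tr), 2)
  expect_true(any(tr == 2))
})

test_that("chains are reproducible and the normal family skips the df update", {
  dat <- tiny_sim(nu_true = 4, seed = 45)
  fr <- build_model_frame(dat$phenotypes)
  cfg <- fit_config(burn_in = 100, n_keep = 200, seed = 77)
  ch1 <- fit_mixed(fr, cfg)
  ch2 <- fit_mixed(fr, cfg)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$lambda_mean, ch2$lambda_mean)

  chn <- fit_mixed(fr, fit_config(burn_in = 100, n_keep = 200, seed = 77,
                                  residual_family = "normal"))
  expect_true(all(is.infinite(chn$samples[, "nu"])))
})

test_that("MH step-size tuning reaches an intermediate acceptance rate", {
  dat <- tiny_sim(nu_true = 4, n_sires = 20, progeny = 50, n_herds = 40,
                  seed = 46)
  fr <- build_model_frame(dat$phenotypes)
  ch <- fit_mixed(fr, fit_config(burn_in = 3000, n_keep = 3000, seed = 21))
  expect_gte(ch$accept_rate, 0.30)
  expect_lte(ch$accept_rate, 0.60)
})
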