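test_that("mixing scales have the Gamma(nu/2, nu/2) moments", {
  expect_equal(draw_mixture_scales(Inf, 5), rep(1, 5))
  lam <- draw_mixture_scales(4, 1e6, seed = 123)
  # mean 1, variance 2/nu; 3 MC standard errors
  expect_equal(mean(lam), 1, tolerance = 3 * sqrt(0.5 / 1e6) / 1)
  expect_equal(var(lam), 0.5, tolerance = 0.01)
  expect_error(draw_mixture_scales(-1, 10), "positive")
})

test_that("the balanced design has the stated dimensions and fixed effects", {
  dat <- simulate_dataset(sim_config(nu_true = 4, seed = 5))
  ph <- dat$phenotypes
  expect_equal(nrow(ph), 2500)
  expect_equal(length(unique(ph$sire)), 50)
  expect_equal(length(unique(ph$herd)), 100)
  expect_equal(length(unique(ph$gender)), 2)

  # shrink all random variation: gender-1 trait-1 phenotypes collapse to 11
  eps <- 1e-10
  tiny <- sim_config(G0_true = diag(eps, 2), H0_true = diag(eps, 2),
                     R0_true = diag(eps, 2), nu_true = Inf, seed = 6)
  d0 <- simulate_dataset(tiny)
  g1 <- d0$phenotypes$gender == "g1"
  expect_equal(d0$phenotypes$trait1[g1],
               rep(11, sum(g1)), tolerance = 1e-4)
  expect_equal(d0$phenotypes$trait2[g1],
               rep(38, sum(g1)), tolerance = 1e-4)
})

test_that("true sire effects reproduce the genetic covariance across replicates", {
  effs <- do.call(rbind, lapply(1:100, function(r) {
    simulate_dataset(sim_config(progeny_per_sire = 1, seed = 1000 + r))$
      sire_effects
  }))
  emp <- cov(effs)  # 5000 draws from N(0, G0)
  expect_equal(emp, matrix(c(2, 1.5, 1.5, 4), 2), tolerance = 0.12,
               ignore_attr = TRUE)
})

test_that("simulated residuals have the Student's-t marginal moments", {
  base <- function(nu, seed) {
    cfg <- sim_config(n_sires = 2, progeny_per_sire = 250000, n_herds = 2,
                      G0_true = diag(1e-10, 2), H0_true = diag(1e-10, 2),
                      nu_true = nu, seed = seed)
    d <- simulate_dataset(cfg)
    b <- cbind(c(11, 90), c(38, 32))
    g <- as.integer(sub("g", "", d$phenotypes$gender))
    cbind(d$phenotypes$trait1, d$phenotypes$trait2) - b[g, ]
  }
  R0 <- matrix(c(15, 4, 4, 20), 2)
  # nu = 12: marginal covariance 1.2 R0, positive excess kurtosis 6/(nu-4)
  e12 <- base(12, 21)
  expect_equal(cov(e12), 1.2 * R0, tolerance = 0.02)
  exk <- function(x) mean((x - mean(x))^4) / var(x)^2 - 3
  expect_equal(exk(e12[, 1]), 6 / 8, tolerance = 0.2)
  # normal model: excess kurtosis ~ 0, covariance R0
  einf <- base(Inf, 22)
  expect_equal(cov(einf), R0, tolerance = 0.02)
  expect_lt(abs(exk(einf[, 1])), 0.05)
  # nu = 4: marginal covariance 2 R0 (slow-converging fourth moments)
  e4 <- base(4, 23)
  expect_equal(cov(e4), 2 * R0, tolerance = 0.1)
})

test_that("simulation is reproducible from its seed", {
  d1 <- simulate_dataset(sim_config(nu_true = 4, seed = 99))
  d2 <- simulate_dataset(sim_config(nu_true = 4, seed = 99))
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$lambda, d2$lambda)
})

test_that("field-like data matches its design targets", {
  cfg <- fieldlike_config(n_records = 3000, seed = 31)
  d <- simulate_fieldlike(cfg)
  ph <- d$phenotypes
  expect_equal(mean(table(ph$hys)), 7, tolerance = 0.15)
  expect_equal(mean(ph$GL), 290, tolerance = 0.01)
  expect_equal(sd(ph$GL), 8.1, tolerance = 0.1)
  expect_equal(length(unique(ph$agesex)), 16)
  # generated pedigree yields a valid positive-definite A
  rel <- build_relationship_matrix(expand_sire_mgs_pedigree(d$pedigree))
  ev <- eigen(rel$A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)

  # degenerate config: phenotype SD collapses to the marginal residual SD
  d0 <- simulate_fieldlike(fieldlike_config(n_records = 20000,
                                            h2_sire = 0, hys_frac = 0,
                                            nu_true = Inf, seed = 32))
  expect_equal(sd(d0$phenotypes$GL), 8.1, tolerance = 0.02)
})
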