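test_that("Geyer ESS recovers independence and AR(1) autocorrelation times", {
  set.seed(23)
  iid <- rnorm(50000)
  expect_equal(ess_initial_positive(iid), 50000, tolerance = 0.1)

  rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), 50000))
  # integrated autocorrelation time (1 + rho)/(1 - rho) = 19
  expect_equal(ess_initial_positive(ar), 50000 * (1 - rho) / (1 + rho),
               tolerance = 0.2)
  expect_error(ess_initial_positive(rep(3, 100)), "zero-variance")
  expect_error(ess_initial_positive(1:5), "at least 10")
})

test_that("chain summaries report mean, percentile PPI and ESS", {
  const <- matrix(3, 100, 1, dimnames = list(NULL, "c"))
  s <- summarize_chain(const)
  expect_equal(s$pm, 3)
  expect_equal(s$ppi_low, 3)
  expect_equal(s$ppi_high, 3)

  set.seed(24)
  u <- matrix(runif(1e6), ncol = 1, dimnames = list(NULL, "u"))
  su <- summarize_chain(u)
  expect_equal(su$ppi_low, 0.025, tolerance = 0.05)
  expect_equal(su$ppi_high, 0.975, tolerance = 0.002)
  expect_equal(su$pm, sum(sort(u)) / 1e6, tolerance = 1e-12)

  expect_error(summarize_chain(matrix(0, 0, 1)), "empty")
  expect_error(summarize_chain(u, params = "nope"), "nope")
})

test_that("outlier flags are monotone in the threshold", {
  expect_equal(nrow(flag_outliers(rep(1, 100))), 0)
  lam <- c(0.05, 0.15, 0.25, 0.5, 1, 1.2)
  fl <- flag_outliers(lam, thresholds = c(0.3, 0.2))
  expect_equal(sort(fl$record), 1:3)
  tight <- fl$record[fl$threshold == 0.2]
  loose <- fl$record
  expect_true(all(tight %in% loose))
  expect_equal(sort(tight), 1:2)
})

test_that("planted outliers receive depressed mixing scales and BSt shrinks more", {
  dat <- simulate_dataset(sim_config(nu_true = Inf, seed = 55))
  ph <- dat$phenotypes
  set.seed(56)
  shifted <- sample(nrow(ph), 50)  # 2% of records, +8 residual SD on trait 1
  ph$trait1[shifted] <- ph$trait1[shifted] + 8 * sqrt(15)
  shifted_sires <- unique(ph$sire[shifted])
  ph <- phenotype_table(ph, traits = c("trait1", "trait2"),
                        fixed = "gender", random = "herd", sire = "sire")
  fr <- build_model_frame(ph)
  cht <- fit_mixed(fr, fit_config(burn_in = 800, n_keep = 1200, seed = 57))
  chn <- fit_mixed(fr, fit_config(burn_in = 800, n_keep = 1200, seed = 58,
                                  residual_family = "normal"))
  w <- wilcox.test(cht$lambda_mean[shifted], cht$lambda_mean[-shifted],
                   alternative = "less")
  expect_lt(w$p.value, 0.01)
  # flagged sets pick up the planted records, with residuals attached
  res <- fr$y - as.matrix(cbind(fr$X, fr$Z, fr$W) %*% cht$effect_mean)
  fl <- flag_outliers(cht, residuals = res)
  expect_gt(mean(fl$record %in% shifted), 0.5)
  expect_true(all(c("residual_trait1", "residual_trait2") %in% names(fl)))
  # outlier-hit sires receive more extreme (upward-dragged) predictions
  # under the normal fit; the heavy-tailed fit mutes them and predicts
  # the true effects more accurately
  at <- genetic_effect_means(cht)
  an <- genetic_effect_means(chn)
  aff <- rownames(at) %in% shifted_sires
  d <- an[, 1] - at[, 1]
  expect_lt(t.test(d[aff], d[!aff], alternative = "greater")$p.value, 0.01)
  truth <- dat$sire_effects[rownames(at), 1]
  expect_lt(mean((at[, 1] - truth)^2), mean((an[, 1] - truth)^2))
})

test_that("prediction metrics match their defining formulas", {
  set.seed(25)
  a <- matrix(rnorm(40), 20, 2)
  perfect <- evaluate_predictions(a, a, alt_predicted = a, k = 5)
  expect_equal(perfect$accuracy, c(1, 1))
  expect_equal(perfect$pev, c(0, 0))
  expect_equal(perfect$kendall_tau, c(1, 1))
  expect_equal(perfect$topk_overlap, c(1, 1))

  # Kendall tau-b equals exhaustive pair counting (with ties)
  x <- c(3, 1, 4, 1, 5)
  y <- c(2, 7, 1, 8, 2)
  ev <- evaluate_predictions(matrix(rnorm(5)), matrix(x),
                             alt_predicted = matrix(y), k = 2)
  expect_equal(ev$kendall_tau, kendall_brute(x, y))

  expect_error(evaluate_predictions(a, a[1:10, ]), "dimensions")
})
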