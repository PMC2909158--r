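test_that("marginal residual covariance applies the nu/(nu-2) factor", {
  R0 <- matrix(c(15, 4, 4, 20), 2)
  expect_equal(marginal_residual_covariance(R0, 4)[1, 1], 30)
  expect_equal(marginal_residual_covariance(R0, 12)[2, 2], 24)
  expect_equal(marginal_residual_covariance(R0, 12)[1, 1], 18)
  expect_equal(marginal_residual_covariance(R0, 4)[2, 2], 40)
  expect_equal(marginal_residual_covariance(R0, 4)[1, 2], 8)
  expect_identical(marginal_residual_covariance(R0, Inf), R0)
  expect_error(marginal_residual_covariance(R0, 2), "undefined")

  # monotone decreasing in nu, converging to the scale matrix
  nus <- c(3, 5, 10, 100, 1e6)
  v <- sapply(nus, function(nu) marginal_residual_covariance(R0, nu)[1, 1])
  expect_true(all(diff(v) < 0))
  expect_equal(v[length(v)], 15, tolerance = 1e-5)
})

test_that("Willham inversion reproduces the field posterior-mean anchors", {
  # gestation-length block of the sire-MGS covariance (posterior means)
  G_gl <- matrix(c(8.42, -0.54, -0.54, 1.02), 2)
  am <- sire_mgs_to_animal(G_gl, m = 1)
  expect_equal(am$G_DM[1, 1], 33.68)   # 4 * 8.42
  expect_equal(am$G_DM[1, 2], -19.00)  # 4 * (-0.54) - 2 * 8.42
  expect_equal(am$G_DM[2, 2], 14.66)   # 4 * 1.02 + 8.42 - 4 * (-0.54)
  r_dm <- am$G_DM[1, 2] / sqrt(am$G_DM[1, 1] * am$G_DM[2, 2])
  # consistent with the reported direct-maternal correlation about -0.86
  expect_equal(r_dm, -0.855, tolerance = 0.002)

  expect_equal(sire_mgs_to_animal(matrix(0, 4, 4))$G_DM,
               matrix(0, 4, 4), ignore_attr = TRUE)
})

test_that("the sire-MGS <-> animal maps are mutually inverse and linear", {
  set.seed(3)
  rand_pd <- function() {
    M <- matrix(rnorm(16), 4)
    crossprod(M) + diag(4)
  }
  for (k in 1:5) {
    G <- rand_pd()
    round_trip <- sire_mgs_to_animal(
      robustsire:::animal_to_sire_mgs(G))$G_DM
    expect_equal(round_trip, G, ignore_attr = TRUE, tolerance = 1e-10)
  }
  G1 <- rand_pd()
  G2 <- rand_pd()
  lhs <- sire_mgs_to_animal(2 * G1 + 3 * G2)$G_DM
  rhs <- 2 * sire_mgs_to_animal(G1)$G_DM + 3 * sire_mgs_to_animal(G2)$G_DM
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("genetic parameters behave at the boundaries", {
  H0 <- diag(c(4, 2.4))
  RE <- diag(c(50, 12))
  zero <- genetic_parameters(matrix(0, 4, 4), H0, RE)
  expect_equal(zero$h2_direct, c(0, 0))
  expect_equal(zero$h2_maternal, c(0, 0))

  G_gl <- matrix(c(8.42, -0.54, -0.54, 1.02), 2)
  gp <- genetic_parameters(sire_mgs_to_animal(G_gl, m = 1),
                           H0 = matrix(4), R_E = matrix(50))
  expect_equal(gp$r_dm, -0.855, tolerance = 0.002)
  expect_true(all(abs(gp$r_g) <= 1, na.rm = TRUE))
  expect_error(genetic_parameters(matrix(0, 4, 4), -H0, -RE),
               "phenotypic variance")
})

test_that("per-draw heritabilities recover the field-like truth", {
  cfg <- fieldlike_config(n_records = 800, n_sires = 60, n_base = 30,
                          nu_true = Inf, seed = 61)
  d <- simulate_fieldlike(cfg)
  rel <- build_relationship_matrix(expand_sire_mgs_pedigree(d$pedigree))
  fr <- build_model_frame(d$phenotypes, genetic = "sire_mgs",
                          relationship = rel)
  # weak proper prior on the 4x4 genetic covariance keeps the flat-prior
  # chain away from its rank-deficient boundary on this small design
  vp <- diag(cov(fr$y))
  ch <- fit_mixed(fr, fit_config(burn_in = 800, n_keep = 1500, seed = 62,
                                 residual_family = "normal",
                                 vc_prior = list(G0 = list(
                                   df = 6, scale = diag(0.05 * rep(vp, 2))))))
  gs <- genetic_parameter_summary(ch)
  # truth by construction: s2_s = 0.10 vp, s2_m = 0.05 vp, s_sm = 0,
  # hys = 0.08 vp, residual = 0.77 vp
  # =>  h2_D = 4 s2_s / vp = 0.40,  h2_M = (4 s2_m + s2_s) / vp = 0.30
  h2d <- gs[gs$parameter == "h2_direct:GL", ]
  expect_gt(h2d$ppi_high, 0.40 * 0.8)
  expect_lt(h2d$ppi_low, 0.40 * 1.3)
  h2m <- gs[gs$parameter == "h2_maternal:GL", ]
  expect_lt(h2m$ppi_low, 0.30 * 1.4)
  # marginal residual variance on the phenotypic scale
  re <- gs[gs$parameter == "sigma2_E_marginal:GL", ]
  expect_equal(re$pm, 0.77 * 8.1^2, tolerance = 0.2)
})
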