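#' Draw residual mixing scales
#'
#' The heavy-tailed residual is a scale mixture of normals: record `i` has
#' residual \eqn{e_i / \sqrt{\lambda_i}} with
#' \eqn{\lambda_i \sim \mathrm{Gamma}(\nu/2, \nu/2)} (shape, rate), whose
#' marginal is multivariate Student's-t with `nu` degrees of freedom. An
#' infinite `nu` corresponds to the normal model, \eqn{\lambda_i \equiv 1}.
#'
#' @param nu Degrees of freedom (`> 0`, or `Inf` for the normal model).
#' @param n Number of scales to draw.
#' @param seed Optional integer seed (set before drawing when supplied).
#' @return Numeric vector of `n` positive scales.
#' @export
draw_mixture_scales <- function(nu, n, seed = NULL) {
  if (!is.numeric(nu) || length(nu) != 1L || is.na(nu) || nu <= 0) {
    stop("nu must be a positive scalar (or Inf)")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.infinite(nu)) return(rep(1, n))
  stats::rgamma(n, shape = nu / 2, rate = nu / 2)
}

check_spd <- function(M, name) {
  if (!isSymmetric(unname(M), tol = 1e-8)) {
    stop(name, " must be symmetric")
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop(name, " is not positive definite")
  invisible(TRUE)
}

#' Simulation configuration for the balanced sire design
#'
#' Defaults reproduce the study conditions of the bivariate simulation:
#' 50 unrelated sires with 50 progeny each, 100 herds, a two-level gender
#' fixed effect with trait-1 means (11, 90) and trait-2 means (38, 32),
#' sire covariance `G0 = [[2, 1.5], [1.5, 4]]`, herd variances (1.5, 6.0)
#' with zero herd covariance, residual scale `R0 = [[15, 4], [4, 20]]`, and
#' residual degrees of freedom `nu` (4, 12, or `Inf` for normal residuals).
#'
#' @param n_sires,progeny_per_sire,n_herds Design counts.
#' @param b_trait1,b_trait2 Gender-level means per trait.
#' @param G0_true,H0_true,R0_true True covariance/scale matrices.
#' @param nu_true True residual degrees of freedom (`> 2` or `Inf`).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 50, progeny_per_sire = 50, n_herds = 100,
                       b_trait1 = c(11, 90), b_trait2 = c(38, 32),
                       G0_true = matrix(c(2, 1.5, 1.5, 4), 2),
                       H0_true = diag(c(1.5, 6)),
                       R0_true = matrix(c(15, 4, 4, 20), 2),
                       nu_true = 4, seed = 1L) {
  stopifnot(n_sires >= 1, progeny_per_sire >= 1, n_herds >= 1)
  if (length(b_trait1) != length(b_trait2)) {
    stop("gender effect vectors must have equal length")
  }
  check_spd(G0_true, "G0_true")
  check_spd(H0_true, "H0_true")
  check_spd(R0_true, "R0_true")
  if (!(is.infinite(nu_true) || nu_true > 2)) {
    stop("nu_true must exceed 2 (finite marginal variance) or be Inf")
  }
  structure(list(n_sires = n_sires, progeny_per_sire = progeny_per_sire,
                 n_herds = n_herds, b_trait1 = b_trait1, b_trait2 = b_trait2,
                 G0_true = G0_true, H0_true = H0_true, R0_true = R0_true,
                 nu_true = nu_true, seed = as.integer(seed)),
            class = "sim_config")
}

# Draw rows iid N(0, Sigma) via Cholesky; fixed draw order (row-major).
rmvnorm_rows <- function(n, Sigma) {
  L <- chol(Sigma)
  z <- matrix(stats::rnorm(n * ncol(Sigma)), n, ncol(Sigma), byrow = TRUE)
  z %*% L
}

#' Simulate the balanced bivariate sire dataset
#'
#' Generates phenotypes `y_i = X_i b + Z_i a + W_i h + e_i / sqrt(lambda_i)`
#' under the balanced design of [sim_config()]: sire effects
#' `a ~ N(0, I (x) G0)` (sires unrelated), herd effects `h ~ N(0, I (x) H0)`,
#' residual cores `e_i ~ N(0, R0)`, and mixing scales
#' `lambda_i ~ Gamma(nu/2, nu/2)` (all 1 when `nu` is infinite). Progeny are
#' assigned to herds and genders uniformly at random. Draw order is fixed
#' (sire effects, herd effects, gender, herd, lambda, residuals) so a seed
#' fully determines the dataset.
#'
#' @param config A [sim_config()].
#' @return A list with `phenotypes` (a [phenotype_table()]), `sire_effects`
#'   (n_sires x m matrix), `herd_effects`, `lambda`, and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- 2L
  ns <- config$n_sires
  nh <- config$n_herds
  n <- ns * config$progeny_per_sire
  a <- rmvnorm_rows(ns, config$G0_true)
  h <- rmvnorm_rows(nh, config$H0_true)
  gender <- sample.int(length(config$b_trait1), n, replace = TRUE)
  herd <- sample.int(nh, n, replace = TRUE)
  lambda <- draw_mixture_scales(config$nu_true, n)
  e <- rmvnorm_rows(n, config$R0_true) / sqrt(lambda)
  sire <- rep(seq_len(ns), each = config$progeny_per_sire)
  b <- cbind(config$b_trait1, config$b_trait2)
  y <- b[gender, , drop = FALSE] + a[sire, , drop = FALSE] +
    h[herd, , drop = FALSE] + e
  dat <- data.frame(animal = paste0("an", seq_len(n)),
                    trait1 = y[, 1], trait2 = y[, 2],
                    gender = paste0("g", gender),
                    herd = paste0("h", herd),
                    sire = paste0("s", sire),
                    stringsAsFactors = FALSE)
  ph <- phenotype_table(dat, traits = c("trait1", "trait2"),
                        fixed = "gender", random = "herd", sire = "sire")
  rownames(a) <- paste0("s", seq_len(ns))
  rownames(h) <- paste0("h", seq_len(nh))
  list(phenotypes = ph, sire_effects = a, herd_effects = h,
       lambda = lambda, config = config)
}

#' Field-like sire-MGS simulation configuration
#'
#' Emulates the scale and structure of national beef-cattle gestation-length
#' (GL, days) and birth-weight (BW, kg) recording: 16 dam-age-by-sex fixed
#' subclasses, many small uneven herd-year-season (HYS) subclasses (mean
#' size about 7), and a sire-MGS genetic structure in which young sires have
#' a known sire and maternal grandsire among older bulls. Default trait
#' scales follow GL mean 290 SD 8.1 and BW mean 39.6 SD 4.1.
#'
#' @param n_records Number of phenotype records.
#' @param n_sires Number of bulls appearing as sire or MGS of a record.
#' @param n_base Founder bulls (no recorded parents) in the pedigree.
#' @param mean_hys Average HYS subclass size (subclass count is derived).
#' @param trait_means,trait_sd Marginal trait means / SDs to emulate.
#' @param h2_sire Fraction of phenotypic variance assigned to the sire
#'   variance (sire-model scale, i.e. a quarter of direct h2).
#' @param hys_frac Fraction of phenotypic variance assigned to HYS.
#' @param nu_true Residual degrees of freedom.
#' @param seed Integer seed.
#' @return A list of class `fieldlike_config`.
#' @export
fieldlike_config <- function(n_records = 2000, n_sires = 160, n_base = 60,
                             mean_hys = 7,
                             trait_means = c(GL = 290, BW = 39.6),
                             trait_sd = c(GL = 8.1, BW = 4.1),
                             h2_sire = 0.10, hys_frac = 0.08,
                             nu_true = 4, seed = 1L) {
  stopifnot(n_records >= 1, n_sires >= 2, n_base >= 2, n_base <= n_sires,
            mean_hys >= 1, h2_sire >= 0, hys_frac >= 0,
            h2_sire + hys_frac < 1)
  n_hys <- max(1L, round(n_records / mean_hys))
  if (n_hys > n_records) stop("infeasible HYS allocation: more subclasses than records")
  structure(list(n_records = n_records, n_sires = n_sires, n_base = n_base,
                 n_hys = n_hys, trait_means = trait_means,
                 trait_sd = trait_sd, h2_sire = h2_sire,
                 hys_frac = hys_frac, nu_true = nu_true,
                 seed = as.integer(seed)),
            class = "fieldlike_config")
}

#' Simulate a field-like sire-MGS dataset with pedigree
#'
#' Builds a bull pedigree (founders plus younger bulls with sire and MGS
#' sampled from older bulls), assigns records to sires and MGS, to 16
#' age-sex fixed subclasses and to uneven HYS subclasses, and generates
#' bivariate phenotypes with Student's-t residuals on the GL/BW scale of
#' [fieldlike_config()].
#'
#' @param config A [fieldlike_config()].
#' @return List with `phenotypes` (a [phenotype_table()] with a sire-MGS
#'   design), `pedigree` (sire-MGS record table suitable for
#'   [expand_sire_mgs_pedigree()]), `sire_effects`, `lambda`, `config`.
#' @export
simulate_fieldlike <- function(config) {
  stopifnot(inherits(config, "fieldlike_config"))
  set.seed(config$seed)
  ns <- config$n_sires
  nb <- config$n_base
  m <- 2L
  bulls <- paste0("bull", seq_len(ns))
  sire_of <- rep(NA_character_, ns)
  mgs_of <- rep(NA_character_, ns)
  for (k in (nb + 1L):ns) {
    pool <- seq_len(k - 1L)
    sire_of[k] <- bulls[sample(pool, 1)]
    mgs_of[k] <- bulls[sample(pool, 1)]
  }
  ped <- data.frame(individual = bulls, sire = sire_of, mgs = mgs_of,
                    stringsAsFactors = FALSE)
  rel <- build_relationship_matrix(expand_sire_mgs_pedigree(ped))
  A <- rel$A[bulls, bulls]

  # Variance decomposition on the marginal phenotypic scale.
  vp <- config$trait_sd^2
  s2_s <- config$h2_sire * vp       # sire variance
  s2_m <- 0.5 * config$h2_sire * vp # MGS variance (smaller, as in practice)
  s_sm <- rep(0, m)                 # sire-MGS covariance defaults to 0
  s2_hys <- config$hys_frac * vp
  marg_res <- vp - s2_s - s2_m - s2_hys
  if (any(marg_res <= 0)) stop("variance decomposition leaves no residual")
  nu <- config$nu_true
  scale_fac <- if (is.infinite(nu)) 1 else (nu - 2) / nu
  R0 <- diag(marg_res * scale_fac)
  rho_r <- 0.3                      # GL-BW residual correlation, moderate +
  R0[1, 2] <- R0[2, 1] <- rho_r * sqrt(prod(diag(R0)))
  G0 <- matrix(0, 2 * m, 2 * m)     # layout sire:t1, sire:t2, mgs:t1, mgs:t2
  G0[1:2, 1:2] <- diag(s2_s)
  G0[3:4, 3:4] <- diag(s2_m)
  H0 <- diag(s2_hys)

  # Correlated sire/MGS effects across the pedigree: chol(A) (x) chol(G0).
  # Zero variance components (degenerate configs) give zero effects.
  La <- chol(A)
  u <- matrix(stats::rnorm(ns * 2 * m), ns, 2 * m, byrow = TRUE)
  eff <- if (all(G0 == 0)) {
    matrix(0, ns, 2 * m)
  } else {
    t(La) %*% u %*% chol(G0)        # ns x 4, row = bull
  }
  hys_eff <- if (all(H0 == 0)) {
    matrix(0, config$n_hys, m)
  } else {
    rmvnorm_rows(config$n_hys, H0)
  }

  n <- config$n_records
  rec_sire <- sample(bulls, n, replace = TRUE)
  rec_mgs <- sample(bulls, n, replace = TRUE)
  agesex <- paste0("as", sample.int(16L, n, replace = TRUE))
  # Uneven HYS sizes: multinomial with Dirichlet-ish weights.
  w <- stats::rgamma(config$n_hys, shape = 2, rate = 1)
  hys <- sample.int(config$n_hys, n, replace = TRUE, prob = w)
  lambda <- draw_mixture_scales(nu, n)
  e <- rmvnorm_rows(n, R0) / sqrt(lambda)
  # Mean-centred age-sex subclass effects, kept small (1% of phenotypic
  # variance) so the marginal SD target is preserved by construction.
  fx <- rmvnorm_rows(16L, diag(0.01 * vp))
  fx <- fx - matrix(colMeans(fx), 16L, m, byrow = TRUE)
  is_ <- match(rec_sire, bulls)
  im_ <- match(rec_mgs, bulls)
  y <- matrix(rep(config$trait_means, each = n), n, m) +
    fx[as.integer(sub("as", "", agesex)), , drop = FALSE] +
    eff[is_, 1:2, drop = FALSE] + eff[im_, 3:4, drop = FALSE] +
    hys_eff[hys, , drop = FALSE] + e

  dat <- data.frame(animal = paste0("rec", seq_len(n)),
                    GL = y[, 1], BW = y[, 2],
                    agesex = agesex, hys = paste0("hys", hys),
                    sire = rec_sire, mgs = rec_mgs,
                    stringsAsFactors = FALSE)
  ph <- phenotype_table(dat, traits = c("GL", "BW"), fixed = "agesex",
                        random = "hys", sire = "sire", mgs = "mgs")
  rownames(eff) <- bulls
  list(phenotypes = ph, pedigree = ped, sire_effects = eff,
       lambda = lambda, config = config)
}
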