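#' MCMC configuration for the robust mixed-model sampler
#'
#' @param burn_in Burn-in cycles (discarded).
#' @param n_keep Number of retained post-burn-in samples.
#' @param thin Thinning stride (1 retains every cycle, as in long
#'   production runs of this model class).
#' @param seed Integer seed; one stream drives the whole chain in a fixed
#'   update order, so a seed fully determines the output.
#' @param residual_family `"student_t"` (scale-mixture residuals with
#'   unknown degrees of freedom) or `"normal"` (mixing scales fixed at 1,
#'   no degrees-of-freedom update).
#' @param nu_prior Prior on the degrees of freedom: `"uniform"` (bounded
#'   uniform on `(2, nu_max)`) or `"damped"` (density proportional to
#'   `(1 + nu)^-2`).
#' @param nu_max Upper bound of the uniform prior.
#' @param nu_start Initial degrees of freedom.
#' @param proposal_sd Initial random-walk Metropolis-Hastings step size for
#'   the degrees of freedom.
#' @param tuning_interval Burn-in cycles between step-size adaptations.
#' @param tune_factor Multiplicative adaptation factor; the step size is
#'   multiplied (acceptance above 50%) or divided (below 40%) by this
#'   factor at each adaptation and frozen after burn-in.
#' @param nu_truncation `"truncate"` sets proposals below 2 to 2 before
#'   evaluation (keeps the marginal residual covariance defined);
#'   `"reject"` rejects them outright, which preserves detailed balance
#'   exactly.
#' @param update_covariances Draw `G0`/`H0`/`R0` from their inverse-Wishart
#'   full conditionals (set `FALSE` to fix them at `start_vc`, e.g. for
#'   sampler validation against the mixed-model-equations solution).
#' @param start_vc Optional list with starting (or fixed) `G0`, `H0`, `R0`,
#'   `nu`.
#' @param vc_prior Optional proper inverse-Wishart priors, a list with any
#'   of `G0`, `H0`, `R0`, each a `list(df =, scale =)` added to the full
#'   conditional. The default (`NULL`) keeps the flat priors; a weak proper
#'   prior stabilizes small designs where a flat-prior covariance can drift
#'   to a rank-deficient boundary.
#' @param store_logdens Keep the full n-by-G per-record log-density matrix
#'   (memory heavy; intended for small validation runs).
#' @param verbose Print progress every `verbose` cycles (0 = silent).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(burn_in = 50000, n_keep = 50000, thin = 1,
                       seed = 1L,
                       residual_family = c("student_t", "normal"),
                       nu_prior = c("uniform", "damped"), nu_max = 5000,
                       nu_start = 8, proposal_sd = 0.5,
                       tuning_interval = 100, tune_factor = 1.3,
                       nu_truncation = c("truncate", "reject"),
                       update_covariances = TRUE, start_vc = NULL,
                       vc_prior = NULL, store_logdens = FALSE, verbose = 0) {
  residual_family <- match.arg(residual_family)
  nu_prior <- match.arg(nu_prior)
  nu_truncation <- match.arg(nu_truncation)
  stopifnot(burn_in >= 0, n_keep >= 1, thin >= 1, nu_max > 2,
            nu_start >= 2, proposal_sd > 0, tuning_interval >= 1,
            tune_factor > 1)
  structure(list(burn_in = as.integer(burn_in),
                 n_keep = as.integer(n_keep), thin = as.integer(thin),
                 seed = as.integer(seed),
                 residual_family = residual_family, nu_prior = nu_prior,
                 nu_max = nu_max, nu_start = nu_start,
                 proposal_sd = proposal_sd,
                 tuning_interval = as.integer(tuning_interval),
                 tune_factor = tune_factor, nu_truncation = nu_truncation,
                 update_covariances = isTRUE(update_covariances),
                 start_vc = start_vc, vc_prior = vc_prior,
                 store_logdens = isTRUE(store_logdens),
                 verbose = verbose),
            class = "fit_config")
}

# Inverse-Wishart draw, IW(scale = S, df), via the Bartlett route:
# W ~ Wishart(df, S^-1), return W^-1. Under the package's flat-prior
# convention the full-conditional df is simply the number of contributing
# vectors (no prior increment); this function is the single place that
# convention lives.
riwish <- function(df, S) {
  d <- nrow(S)
  if (df < d) stop("inverse-Wishart df (", df, ") below dimension ", d)
  U <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(U)) {
    stop("inverse-Wishart scale matrix is not positive definite ",
         "(a variance component may have collapsed; flat covariance ",
         "priors need enough levels per random factor)")
  }
  W <- stats::rWishart(1, df, chol2inv(U))[, , 1]
  chol2inv(chol(W))
}

# Log kernel of the df full conditional given the mixing scales:
# product of Gamma(nu/2, nu/2) densities times the prior.
nu_log_kernel <- function(nu, n, sum_log_lambda, sum_lambda, prior, nu_max) {
  if (nu < 2) return(-Inf)
  lp <- switch(prior,
               uniform = if (nu > nu_max) -Inf else 0,
               damped = -2 * log1p(nu))
  if (!is.finite(lp)) return(lp)
  h <- nu / 2
  n * (h * log(h) - lgamma(h)) + (h - 1) * sum_log_lambda - h * sum_lambda + lp
}

#' One random-walk Metropolis-Hastings update of the degrees of freedom
#'
#' Proposes `nu* ~ Normal(nu, proposal_sd^2)`; proposals below 2 are set to
#' 2 before evaluation (or rejected, per `nu_truncation`), keeping the
#' marginal residual covariance `nu/(nu-2) R0` defined. The target is the
#' product of `Gamma(nu/2, nu/2)` mixing-scale densities times the prior.
#'
#' @param nu Current value.
#' @param lambda Current mixing scales.
#' @param proposal_sd Random-walk step size.
#' @param nu_prior `"uniform"` or `"damped"`.
#' @param nu_max Upper bound of the uniform prior.
#' @param nu_truncation `"truncate"` or `"reject"`.
#' @return List with `nu` and logical `accepted`.
#' @export
sample_df <- function(nu, lambda, proposal_sd, nu_prior = "uniform",
                      nu_max = 5000, nu_truncation = "truncate") {
  n <- length(lambda)
  sl <- sum(log(lambda))
  s <- sum(lambda)
  prop <- nu + proposal_sd * stats::rnorm(1)
  if (prop < 2) {
    if (nu_truncation == "reject") {
      return(list(nu = nu, accepted = FALSE))
    }
    prop <- 2
  }
  la <- nu_log_kernel(prop, n, sl, s, nu_prior, nu_max) -
    nu_log_kernel(nu, n, sl, s, nu_prior, nu_max)
  if (is.finite(la) && log(stats::runif(1)) < la) {
    list(nu = prop, accepted = TRUE)
  } else {
    list(nu = nu, accepted = FALSE)
  }
}

#' Gibbs update of the per-record mixing scales
#'
#' Draws `lambda_i ~ Gamma((nu + m)/2, (nu + e_i' R0^-1 e_i)/2)` (shape,
#' rate), the full conditional under the scale-mixture representation of
#' the multivariate Student's-t residual.
#'
#' @param E n-by-m matrix of current residuals `y_i - X_i b - Z_i a - W_i h`.
#' @param R0 Residual scale matrix.
#' @param nu Current degrees of freedom.
#' @return Vector of `n` positive scales.
#' @export
sample_mixture_scales <- function(E, R0, nu) {
  if (any(!is.finite(E))) {
    stop("non-finite residual at record ",
         which(!is.finite(rowSums(E)))[1])
  }
  m <- ncol(E)
  R0i <- chol2inv(chol(R0))
  q <- rowSums((E %*% R0i) * E)
  stats::rgamma(nrow(E), shape = (nu + m) / 2, rate = (nu + q) / 2)
}

# Internal: precompute the fixed structural pieces of the mixed-model
# coefficient matrix for a frame.
mme_structure <- function(frame) {
  Tmat <- cbind(frame$X, frame$Z, frame$W)
  cT <- ncol(Tmat)
  m <- frame$m
  p <- frame$p
  qz <- ncol(frame$Z)
  r <- frame$r
  N <- cT * m
  grows <- (p * m + 1L):((p + qz) * m)       # genetic scalar rows
  hcols <- p + qz + seq_len(r)               # herd T-columns
  # Flat indices of the r diagonal m x m herd prior blocks within the
  # dense N x N coefficient matrix.
  off <- (hcols - 1L) * m
  hrow <- as.vector(outer(seq_len(m), off, `+`))          # all herd rows
  blk <- function(k) {
    rows <- off[k] + seq_len(m)
    as.vector(outer(rows, (rows - 1L) * N, `+`))
  }
  hflat <- unlist(lapply(seq_len(r), blk))
  list(Tmat = Tmat, cT = cT, N = N, grows = grows, hflat = hflat)
}

#' One joint draw of all location effects
#'
#' Samples `(b, a, h)` from the multivariate normal full conditional whose
#' mean solves Henderson's mixed-model equations with heterogeneous
#' residual precisions `lambda_i R0^-1` and whose covariance is the inverse
#' coefficient matrix. The coefficient matrix is assembled as
#' `(T' Lambda T) (x) R0^-1` plus the random-effect prior precisions
#' `A^-1 (x) G0^-1` and `I (x) H0^-1`.
#'
#' @param frame A [build_model_frame()] result.
#' @param G0,H0,R0 Current covariance matrices.
#' @param lambda Current mixing scales (length n).
#' @param struct Optional precomputed structure (internal reuse).
#' @return List with `B` (coefficient-by-trait matrix of the sampled
#'   effects, rows ordered fixed/genetic/herd), `mean` (same shape, the
#'   MME solution), and `ok`.
#' @export
sample_location_effects <- function(frame, G0, H0, R0, lambda,
                                    struct = NULL) {
  if (is.null(struct)) struct <- mme_structure(frame)
  m <- frame$m
  R0i <- chol2inv(chol(R0))
  G0i <- chol2inv(chol(G0))
  H0i <- chol2inv(chol(H0))
  M <- as.matrix(Matrix::crossprod(struct$Tmat, lambda * struct$Tmat))
  C <- kronecker(M, R0i)
  gp <- kronecker(frame$A_inv, G0i)
  C[struct$grows, struct$grows] <- C[struct$grows, struct$grows] + gp
  C[struct$hflat] <- C[struct$hflat] + rep(as.vector(H0i), frame$r)
  rhs <- as.vector(t(as.matrix(
    Matrix::crossprod(struct$Tmat, lambda * frame$y)) %*% R0i))
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U)) {
    stop("singular mixed-model coefficient matrix; ",
         "check for confounded factor levels")
  }
  mu <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
  theta <- mu + backsolve(U, stats::rnorm(length(mu)))
  list(B = matrix(theta, struct$cT, m, byrow = TRUE),
       mean = matrix(mu, struct$cT, m, byrow = TRUE))
}

#' Gibbs update of the covariance matrices
#'
#' Draws `R0`, `G0` and `H0` from their inverse-Wishart full conditionals
#' under flat priors: scale matrices are the (lambda-weighted) residual
#' cross-product, the genetic-effect cross-product contracted against
#' `A^-1`, and the herd-effect cross-product; degrees of freedom equal the
#' number of contributing vectors.
#'
#' @param frame Model frame.
#' @param B Current location effects (as returned by
#'   [sample_location_effects()]).
#' @param E Current residual matrix.
#' @param lambda Current mixing scales.
#' @param vc_prior Optional proper inverse-Wishart priors (see
#'   [fit_config()]); `NULL` keeps the flat-prior convention.
#' @return List with updated `G0`, `H0`, `R0`.
#' @export
sample_covariances <- function(frame, B, E, lambda, vc_prior = NULL) {
  m <- frame$m
  p <- frame$p
  qz <- ncol(frame$Z)
  pr <- function(which, S, df) {
    pp <- vc_prior[[which]]
    if (is.null(pp)) list(S = S, df = df)
    else list(S = S + pp$scale, df = df + pp$df)
  }
  Se <- pr("R0", crossprod(sqrt(lambda) * E), frame$n)
  R0 <- riwish(Se$df, Se$S)
  Bg <- B[p + seq_len(qz), , drop = FALSE]
  Ag <- do.call(cbind, lapply(seq_len(frame$n_gtype), function(s) {
    Bg[seq(s, qz, by = frame$n_gtype), , drop = FALSE]
  }))
  Sg <- pr("G0", crossprod(Ag, frame$A_inv %*% Ag), frame$q_ind)
  G0 <- riwish(Sg$df, Sg$S)
  Bh <- B[p + qz + seq_len(frame$r), , drop = FALSE]
  Sh <- pr("H0", crossprod(Bh), frame$r)
  H0 <- riwish(Sh$df, Sh$S)
  list(G0 = G0, H0 = H0, R0 = R0)
}

# Per-record log density of y_i given one parameter draw: multivariate
# Student's-t (lambda marginalized) or multivariate normal.
row_log_density <- function(E, R0, nu) {
  m <- ncol(E)
  Ui <- chol(R0)
  ldet <- 2 * sum(log(diag(Ui)))
  R0i <- chol2inv(Ui)
  q <- rowSums((E %*% R0i) * E)
  if (is.infinite(nu)) {
    -0.5 * (m * log(2 * pi) + ldet + q)
  } else {
    lgamma((nu + m) / 2) - lgamma(nu / 2) - 0.5 * m * log(nu * pi) -
      0.5 * ldet - 0.5 * (nu + m) * log1p(q / nu)
  }
}

# Elementwise log(exp(a) + exp(b)) with -Inf handling.
lse2 <- function(a, b) {
  M <- pmax(a, b)
  out <- M + log(exp(a - M) + exp(b - M))
  out[is.infinite(M) & M < 0] <- -Inf
  out
}

#' Run the Gibbs / Metropolis-Hastings chain
#'
#' Executes `burn_in + n_keep * thin` cycles in the fixed update order
#' location -> mixing scales -> covariance matrices -> degrees of freedom,
#' retaining every `thin`-th post-burn-in draw. Under the normal residual
#' family the mixing-scale and degrees-of-freedom updates are skipped
#' (`lambda == 1`). Per-record conditional-predictive-ordinate terms are
#' accumulated online for [predictive_log_likelihood()].
#'
#' @param frame A [build_model_frame()] result.
#' @param config A [fit_config()].
#' @return An object of class `sire_chain`: list with `samples` (matrix of
#'   retained scalar draws: covariance elements, degrees of freedom, fixed
#'   effects), `effect_mean` / `effect_m2` (running moments of all location
#'   effects), `lambda_mean`, CPO accumulators, acceptance and tuning
#'   state, and metadata (layout, traits, config).
#' @export
fit_mixed <- function(frame, config) {
  stopifnot(inherits(frame, "model_frame"), inherits(config, "fit_config"))
  set.seed(config$seed)
  m <- frame$m
  n <- frame$n
  struct <- mme_structure(frame)
  student <- config$residual_family == "student_t"

  sv <- config$start_vc
  Sy <- stats::cov(frame$y)
  G0 <- if (!is.null(sv$G0)) sv$G0 else {
    diag(0.05 * rep(diag(Sy), frame$n_gtype), m * frame$n_gtype)
  }
  H0 <- if (!is.null(sv$H0)) sv$H0 else diag(0.05 * diag(Sy), m)
  R0 <- if (!is.null(sv$R0)) sv$R0 else 0.5 * Sy
  nu <- if (!is.null(sv$nu)) sv$nu else config$nu_start
  lambda <- rep(1, n)
  proposal_sd <- config$proposal_sd

  n_cycles <- config$burn_in + config$n_keep * config$thin
  param_names <- c(cov_names("G0", m * frame$n_gtype),
                   cov_names("H0", m), cov_names("R0", m), "nu",
                   paste0("b[", rep(colnames(frame$X), each = m),
                          ":trait", rep(seq_len(m), frame$p), "]"))
  samples <- matrix(NA_real_, config$n_keep, length(param_names),
                    dimnames = list(NULL, param_names))
  eff_mean <- matrix(0, struct$cT, m)
  eff_m2 <- matrix(0, struct$cT, m)
  lambda_mean <- rep(0, n)
  cpo_neg <- rep(-Inf, n)   # log sum exp of -logdens (harmonic mean)
  cpo_pos <- rep(-Inf, n)   # log sum exp of +logdens (arithmetic mean)
  logdens_mat <- if (config$store_logdens) {
    matrix(NA_real_, n, config$n_keep)
  } else NULL
  accepts_window <- 0L
  window_n <- 0L
  accepts_post <- 0L
  post_n <- 0L
  kept <- 0L

  for (cyc in seq_len(n_cycles)) {
    loc <- sample_location_effects(frame, G0, H0, R0, lambda, struct)
    B <- loc$B
    E <- frame$y - as.matrix(struct$Tmat %*% B)
    if (any(!is.finite(E))) {
      stop("sampler diverged at cycle ", cyc, " (non-finite state)")
    }
    if (student) {
      lambda <- sample_mixture_scales(E, R0, nu)
    }
    if (config$update_covariances) {
      vc <- sample_covariances(frame, B, E, lambda, config$vc_prior)
      G0 <- vc$G0
      H0 <- vc$H0
      R0 <- vc$R0
    }
    if (student) {
      st <- sample_df(nu, lambda, proposal_sd, config$nu_prior,
                      config$nu_max, config$nu_truncation)
      nu <- st$nu
      if (cyc <= config$burn_in) {
        accepts_window <- accepts_window + st$accepted
        window_n <- window_n + 1L
        if (window_n == config$tuning_interval) {
          rate <- accepts_window / window_n
          if (rate > 0.50) {
            proposal_sd <- min(proposal_sd * config$tune_factor,
                               config$nu_max / 2)
          } else if (rate < 0.40) {
            proposal_sd <- proposal_sd / config$tune_factor
          }
          accepts_window <- 0L
          window_n <- 0L
        }
      } else {
        accepts_post <- accepts_post + st$accepted
        post_n <- post_n + 1L
      }
    }
    if (cyc > config$burn_in &&
        (cyc - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- c(upper_tri_vec(G0), upper_tri_vec(H0),
                           upper_tri_vec(R0), if (student) nu else Inf,
                           as.vector(t(B[seq_len(frame$p), , drop = FALSE])))
      eff_mean <- eff_mean + B
      eff_m2 <- eff_m2 + B * B
      lambda_mean <- lambda_mean + lambda
      ld <- row_log_density(E, R0, if (student) nu else Inf)
      cpo_neg <- lse2(cpo_neg, -ld)
      cpo_pos <- lse2(cpo_pos, ld)
      if (config$store_logdens) logdens_mat[, kept] <- ld
    }
    if (config$verbose > 0 && cyc %% config$verbose == 0) {
      message("cycle ", cyc, "/", n_cycles, "  nu=", signif(nu, 4),
              "  step=", signif(proposal_sd, 3))
    }
  }

  G <- config$n_keep
  structure(list(
    samples = samples,
    effect_mean = eff_mean / G,
    effect_var = pmax(eff_m2 / G - (eff_mean / G)^2, 0),
    lambda_mean = lambda_mean / G,
    cpo_neg = cpo_neg, cpo_pos = cpo_pos, n_kept = G,
    logdens = logdens_mat,
    accept_rate = if (post_n > 0) accepts_post / post_n else NA_real_,
    proposal_sd = proposal_sd,
    residual_family = config$residual_family,
    effect_rows = list(fixed = seq_len(frame$p),
                       genetic = frame$p + seq_len(ncol(frame$Z)),
                       random = frame$p + ncol(frame$Z) + seq_len(frame$r)),
    gen_ids = frame$gen_ids, n_gtype = frame$n_gtype,
    effect_layout = frame$effect_layout,
    traits = frame$traits, m = m, config = config
  ), class = "sire_chain")
}

# Names for the stored upper-triangle (including diagonal) of a covariance
# matrix, column-major over the upper triangle.
cov_names <- function(prefix, d) {
  idx <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  paste0(prefix, "[", idx[, "row"], ",", idx[, "col"], "]")
}

upper_tri_vec <- function(M) {
  M[upper.tri(M, diag = TRUE)]
}

# Rebuild a symmetric matrix from its stored upper triangle.
sym_from_upper <- function(v, d) {
  M <- matrix(0, d, d)
  M[upper.tri(M, diag = TRUE)] <- v
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

#' Extract posterior-mean genetic (sire) effects from a chain
#'
#' @param chain A `sire_chain`.
#' @param type For sire-MGS designs, `"sire"` or `"mgs"` slot.
#' @return Matrix (individuals x traits) of posterior means.
#' @export
genetic_effect_means <- function(chain, type = "sire") {
  g <- chain$effect_mean[chain$effect_rows$genetic, , drop = FALSE]
  if (chain$n_gtype == 1L) {
    out <- g
  } else {
    s <- match(type, c("sire", "mgs"))
    out <- g[seq(s, nrow(g), by = 2L), , drop = FALSE]
  }
  rownames(out) <- chain$gen_ids
  colnames(out) <- chain$traits
  out
}

#' @export
print.sire_chain <- function(x, ...) {
  cat("sire_chain:", x$n_kept, "kept samples,",
      ncol(x$samples), "stored scalars; residual family",
      x$residual_family, "\n")
  if (x$residual_family == "student_t") {
    cat("  posterior mean df:", signif(mean(x$samples[, "nu"]), 4),
        " MH acceptance:", signif(x$accept_rate, 3), "\n")
  }
  invisible(x)
}
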