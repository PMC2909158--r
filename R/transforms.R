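#' Marginal residual covariance of a Student's-t residual
#'
#' The scale matrix `R0` of a multivariate Student's-t residual is not a
#' covariance; the marginal (unconditional) residual covariance is
#' `nu/(nu - 2) * R0` for finite `nu > 2`, and `R0` itself under the normal
#' model (`nu = Inf`). Scale parameters must be transformed this way before
#' they are compared across residual families or used in heritabilities.
#'
#' @param R0 Residual scale matrix (m x m).
#' @param nu Degrees of freedom (`> 2` or `Inf`).
#' @return m x m marginal residual covariance matrix.
#' @examples
#' marginal_residual_covariance(matrix(c(15, 4, 4, 20), 2), 4)[1, 1]  # 30
#' @export
marginal_residual_covariance <- function(R0, nu) {
  if (!is.numeric(nu) || length(nu) != 1L || is.na(nu)) {
    stop("nu must be a numeric scalar")
  }
  if (is.infinite(nu)) return(R0)
  if (nu <= 2) {
    stop("marginal residual variance is undefined for nu <= 2 (nu = ",
         nu, ")")
  }
  nu / (nu - 2) * R0
}

# Per-trait Willham inversion block: (sire, mgs) -> (direct, maternal).
willham_block <- matrix(c(2, -1, 0, 2), 2, 2)

#' Convert sire-MGS covariances to direct/maternal animal-model covariances
#'
#' Applies `G_DM = P G0 P'` with per-trait block `[[2, 0], [-1, 2]]`
#' (Willham inversion: `s2_D = 4 s2_s`, `s_DM = 4 s_sm - 2 s2_s`,
#' `s2_M = 4 s2_m + s2_s - 4 s_sm`), extended over traits by block
#' structure. Input layout is type-major, trait-minor (sire:trait1,
#' sire:trait2, mgs:trait1, mgs:trait2, matching the chain's stored `G0`);
#' output layout is direct:trait1, ..., maternal:trait1, ....
#'
#' @param G0 Symmetric `2m x 2m` sire-MGS covariance matrix.
#' @param m Trait count (default inferred as `nrow(G0)/2`).
#' @return List of class `animal_covariances`: `G_DM` (2m x 2m), `P`,
#'   `m`, and `layout`.
#' @export
sire_mgs_to_animal <- function(G0, m = nrow(G0) / 2) {
  if (nrow(G0) != ncol(G0) || nrow(G0) != 2 * m) {
    stop("G0 must be a square 2m x 2m sire-MGS covariance matrix")
  }
  if (!isSymmetric(unname(G0), tol = 1e-8)) stop("G0 must be symmetric")
  P <- kronecker(willham_block, diag(m))
  G_DM <- P %*% G0 %*% t(P)
  G_DM <- (G_DM + t(G_DM)) / 2
  layout <- paste0(rep(c("direct", "maternal"), each = m),
                   ":trait", rep(seq_len(m), 2))
  dimnames(G_DM) <- list(layout, layout)
  structure(list(G_DM = G_DM, P = P, m = m, layout = layout),
            class = "animal_covariances")
}

# Forward Willham map: animal-model (D, M) covariances back to sire-MGS
# scale (the inverse of sire_mgs_to_animal); used for round-trip checks
# and for reconstructing per-trait sire-model components.
animal_to_sire_mgs <- function(G_DM, m = nrow(G_DM) / 2) {
  P <- kronecker(willham_block, diag(m))
  Pi <- solve(P)
  Pi %*% G_DM %*% t(Pi)
}

#' Heritabilities and genetic correlations from one parameter draw
#'
#' Computes direct and maternal heritabilities and genetic correlations
#' from the direct/maternal genetic covariances, the uncorrelated random
#' (herd-year-season) covariance, and the marginal residual covariance of a
#' single posterior draw. The per-trait phenotypic variance follows the
#' selected convention:
#' `"full"` (default) `s2_P = s2_s + s2_m + s_sm + s2_HYS + s2_E(marginal)`
#' on the sire-MGS scale, `"no_hys"` drops the HYS term, `"no_cov"` drops
#' the sire-MGS covariance.
#'
#' @param animal An [sire_mgs_to_animal()] result (or its `G_DM` matrix).
#' @param H0 m x m uncorrelated-random covariance of the same draw.
#' @param R_E m x m marginal residual covariance of the same draw (see
#'   [marginal_residual_covariance()]).
#' @param convention Phenotypic-variance convention tag.
#' @return List of class `genetic_parameters`: `h2_direct`, `h2_maternal`
#'   (per trait), `r_dm` (per-trait direct-maternal genetic correlation),
#'   `r_g` (full 2m x 2m genetic correlation matrix), `sigma2_p`,
#'   `convention`.
#' @export
genetic_parameters <- function(animal, H0, R_E,
                               convention = c("full", "no_hys", "no_cov")) {
  convention <- match.arg(convention)
  G_DM <- if (inherits(animal, "animal_covariances")) animal$G_DM else animal
  m <- nrow(G_DM) / 2
  G0 <- animal_to_sire_mgs(G_DM, m)
  s2_s <- diag(G0)[seq_len(m)]
  s2_m <- diag(G0)[m + seq_len(m)]
  s_sm <- G0[cbind(seq_len(m), m + seq_len(m))]
  s2_p <- switch(convention,
                 full = s2_s + s2_m + s_sm + diag(H0) + diag(R_E),
                 no_hys = s2_s + s2_m + s_sm + diag(R_E),
                 no_cov = s2_s + s2_m + diag(H0) + diag(R_E))
  if (any(s2_p <= 0)) stop("non-positive phenotypic variance")
  h2_d <- diag(G_DM)[seq_len(m)] / s2_p
  h2_m <- diag(G_DM)[m + seq_len(m)] / s2_p
  sd_g <- sqrt(pmax(diag(G_DM), 0))
  denom <- outer(sd_g, sd_g)
  r_g <- G_DM / ifelse(denom > 0, denom, NA_real_)
  r_dm <- r_g[cbind(seq_len(m), m + seq_len(m))]
  structure(list(h2_direct = h2_d, h2_maternal = h2_m, r_dm = r_dm,
                 r_g = r_g, sigma2_p = s2_p, convention = convention),
            class = "genetic_parameters")
}

#' Posterior summaries of genetic parameters from a sire-MGS chain
#'
#' Applies [sire_mgs_to_animal()], [marginal_residual_covariance()] and
#' [genetic_parameters()] to every retained draw of a `sire_chain` fitted
#' with the sire-MGS design, then summarizes each derived scalar by its
#' posterior mean, 95% posterior probability interval, and effective sample
#' size. Ratios are computed per draw and then averaged (posterior mean of
#' the ratio), not as ratios of posterior means.
#'
#' @param chain A `sire_chain` from a sire-MGS fit.
#' @param convention Passed to [genetic_parameters()].
#' @return Data frame with one row per derived parameter (heritabilities,
#'   direct-maternal correlations, marginal residual variances).
#' @export
genetic_parameter_summary <- function(chain,
                                      convention = c("full", "no_hys",
                                                     "no_cov")) {
  convention <- match.arg(convention)
  if (chain$n_gtype != 2L) {
    stop("genetic_parameter_summary requires a sire-MGS fit")
  }
  m <- chain$m
  d <- 2 * m
  draws <- chain_parameter_draws(chain)
  G <- nrow(chain$samples)
  out <- matrix(NA_real_, G, 3 * m + m)
  nm <- c(paste0("h2_direct:", chain$traits),
          paste0("h2_maternal:", chain$traits),
          paste0("r_dm:", chain$traits),
          paste0("sigma2_E_marginal:", chain$traits))
  colnames(out) <- nm
  for (j in seq_len(G)) {
    G0 <- draws$G0[[j]]
    RE <- marginal_residual_covariance(draws$R0[[j]],
                                       if (chain$residual_family ==
                                           "student_t") draws$nu[j] else Inf)
    gp <- genetic_parameters(sire_mgs_to_animal(G0, m), draws$H0[[j]], RE,
                             convention)
    out[j, ] <- c(gp$h2_direct, gp$h2_maternal, gp$r_dm, diag(RE))
  }
  res <- do.call(rbind, lapply(nm, function(p) {
    summarize_scalar(out[, p], p)
  }))
  res$convention <- convention
  res
}

# Reconstruct the covariance matrices of every kept draw from the stored
# upper triangles.
chain_parameter_draws <- function(chain) {
  m <- chain$m
  d_g <- m * chain$n_gtype
  s <- chain$samples
  take <- function(prefix, d) {
    cols <- cov_names(prefix, d)
    lapply(seq_len(nrow(s)), function(j) sym_from_upper(s[j, cols], d))
  }
  list(G0 = take("G0", d_g), H0 = take("H0", m), R0 = take("R0", m),
       nu = s[, "nu"])
}
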