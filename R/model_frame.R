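#' Construct a validated phenotype table
#'
#' One row per animal, with `m` trait values, one level per fixed factor,
#' the level of the uncorrelated random factor (herd or herd-year-season),
#' and sire / maternal-grandsire identifiers. Complete records only: a
#' missing trait value is an error, mirroring the usual requirement of
#' complete multi-trait records in sire-model evaluations.
#'
#' @param data Data frame of records.
#' @param traits Character vector of trait column names (length `m >= 1`).
#' @param fixed Character vector of fixed-factor column names.
#' @param random Name of the uncorrelated random-factor column.
#' @param sire Name of the sire-id column.
#' @param mgs Optional name of the maternal-grandsire-id column.
#' @return A data frame of class `phenotype_table` with attributes `traits`,
#'   `fixed`, `random`, `sire`, `mgs`.
#' @export
phenotype_table <- function(data, traits, fixed, random, sire, mgs = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("phenotype table is empty")
  cols <- c(traits, fixed, random, sire, mgs)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop("phenotype data is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (length(traits) < 1L) stop("at least one trait is required")
  for (tr in traits) {
    v <- data[[tr]]
    if (!is.numeric(v)) stop("trait column '", tr, "' is not numeric")
    if (anyNA(v)) {
      stop("trait column '", tr, "' has missing value(s) at row(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    }
  }
  for (fc in c(fixed, random, sire)) {
    if (anyNA(data[[fc]])) {
      stop("factor column '", fc, "' has missing value(s) at row(s) ",
           paste(utils::head(which(is.na(data[[fc]])), 5), collapse = ", "))
    }
  }
  structure(as.data.frame(data), class = c("phenotype_table", "data.frame"),
            traits = traits, fixed = fixed, random = random,
            sire = sire, mgs = mgs)
}

# Factor levels interned in first-appearance order (stable, documented).
level_index <- function(x) {
  x <- as.character(x)
  levs <- unique(x)
  list(idx = match(x, levs), levels = levs)
}

#' Assemble the fitting substrate for the mixed model
#'
#' Builds the response matrix and sparse incidence matrices for the
#' multi-trait model \eqn{y_i = X_i b + Z_i a + W_i h + e_i}, together with
#' the relationship structure of the genetic effects. Genetic designs:
#' `"sire"` (one transmitting-ability effect per sire, \eqn{G_0} is
#' \eqn{m \times m}) or `"sire_mgs"` (sire and maternal-grandsire effects
#' per pedigree individual, \eqn{G_0} is \eqn{2m \times 2m} with scalar
#' layout sire-trait1, sire-trait2, mgs-trait1, mgs-trait2 per individual).
#'
#' Column order is deterministic: factor levels in first-appearance order;
#' genetic columns individual-major with the sire slot before the MGS slot.
#' The first fixed factor is fully dummy-coded; any further fixed factors
#' are treatment-coded (first level dropped) to keep the fixed block full
#' rank.
#'
#' @param phenotypes A [phenotype_table()].
#' @param genetic `"sire"` or `"sire_mgs"`.
#' @param relationship Optional `relationship_matrix` (from
#'   [build_relationship_matrix()]) covering all sires (and MGS). When
#'   `NULL`, genetic individuals are taken as unrelated (`A = I`).
#' @return An object of class `model_frame`.
#' @export
build_model_frame <- function(phenotypes, genetic = c("sire", "sire_mgs"),
                              relationship = NULL) {
  genetic <- match.arg(genetic)
  if (!inherits(phenotypes, "phenotype_table")) {
    stop("phenotypes must be a phenotype_table")
  }
  traits <- attr(phenotypes, "traits")
  fixed <- attr(phenotypes, "fixed")
  random <- attr(phenotypes, "random")
  sire <- attr(phenotypes, "sire")
  mgs <- attr(phenotypes, "mgs")
  n <- nrow(phenotypes)
  m <- length(traits)
  y <- as.matrix(phenotypes[traits])
  storage.mode(y) <- "double"

  # Fixed-effect incidence: full dummy for the first factor, treatment
  # coding for the rest.
  xlev <- list()
  Xi <- NULL
  Xj <- NULL
  xnames <- character(0)
  col0 <- 0L
  for (k in seq_along(fixed)) {
    li <- level_index(phenotypes[[fixed[k]]])
    xlev[[fixed[k]]] <- li$levels
    if (k == 1L) {
      Xi <- c(Xi, seq_len(n))
      Xj <- c(Xj, col0 + li$idx)
      xnames <- c(xnames, paste0(fixed[k], ":", li$levels))
      col0 <- col0 + length(li$levels)
    } else {
      keep <- li$idx > 1L
      Xi <- c(Xi, which(keep))
      Xj <- c(Xj, col0 + li$idx[keep] - 1L)
      xnames <- c(xnames, paste0(fixed[k], ":", li$levels[-1]))
      col0 <- col0 + length(li$levels) - 1L
    }
  }
  X <- Matrix::sparseMatrix(i = Xi, j = Xj, x = 1, dims = c(n, col0),
                            dimnames = list(NULL, xnames))

  # Uncorrelated random factor.
  wl <- level_index(phenotypes[[random]])
  W <- Matrix::sparseMatrix(i = seq_len(n), j = wl$idx, x = 1,
                            dims = c(n, length(wl$levels)),
                            dimnames = list(NULL, wl$levels))

  # Genetic incidence.
  sire_ids <- as.character(phenotypes[[sire]])
  mgs_ids <- if (genetic == "sire_mgs") {
    if (is.null(mgs)) stop("sire_mgs design requires an mgs column")
    as.character(phenotypes[[mgs]])
  } else NULL
  gen_ids <- unique(c(sire_ids, mgs_ids[!is.na(mgs_ids)]))
  if (!is.null(relationship)) {
    missing_ids <- setdiff(gen_ids, relationship$ids)
    if (length(missing_ids)) {
      stop("relationship matrix does not cover: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    }
    gen_ids <- intersect(relationship$ids, gen_ids)
    A <- relationship$A[gen_ids, gen_ids, drop = FALSE]
    A_inv <- chol2inv(chol(A))
  } else {
    A <- diag(length(gen_ids))
    dimnames(A) <- list(gen_ids, gen_ids)
    A_inv <- A
  }
  q_ind <- length(gen_ids)
  n_gtype <- if (genetic == "sire_mgs") 2L else 1L
  # Z columns: individual-major, (sire slot, mgs slot) within individual.
  s_idx <- match(sire_ids, gen_ids)
  if (genetic == "sire_mgs") {
    g_idx <- match(mgs_ids, gen_ids)
    if (anyNA(g_idx)) stop("unresolvable MGS id at row ",
                           which(is.na(g_idx))[1])
    Zi <- c(seq_len(n), seq_len(n))
    Zj <- c((s_idx - 1L) * 2L + 1L, (g_idx - 1L) * 2L + 2L)
    znames <- paste0(rep(gen_ids, each = 2), c(":sire", ":mgs"))
  } else {
    Zi <- seq_len(n)
    Zj <- s_idx
    znames <- gen_ids
  }
  Z <- Matrix::sparseMatrix(i = Zi, j = Zj, x = 1,
                            dims = c(n, q_ind * n_gtype),
                            dimnames = list(NULL, znames))

  structure(list(
    y = y, X = X, Z = Z, W = W,
    A = A, A_inv = A_inv,
    m = m, n = n,
    traits = traits,
    genetic = genetic, n_gtype = n_gtype,
    q_ind = q_ind, gen_ids = gen_ids,
    p = ncol(X), r = ncol(W),
    fixed_levels = xlev, random_levels = wl$levels,
    effect_layout = paste0(rep(c("sire", "mgs")[seq_len(n_gtype)], each = m),
                           ":trait", rep(seq_len(m), times = n_gtype))
  ), class = "model_frame")
}

#' @export
print.model_frame <- function(x, ...) {
  cat("model_frame:", x$n, "records,", x$m, "trait(s);",
      x$p, "fixed columns,", ncol(x$Z), "genetic columns (",
      x$genetic, "),", x$r, "uncorrelated random levels\n")
  invisible(x)
}
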