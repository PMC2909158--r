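#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix \eqn{A} by the
#' tabular method: individuals are processed parents-before-offspring, with
#' \eqn{a_{ii} = 1 + \tfrac12 a_{p_1 p_2}} and
#' \eqn{a_{ij} = \tfrac12 (a_{j p_1} + a_{j p_2})} for \eqn{j} already
#' tabulated. Unknown parents are treated as unrelated, non-inbred founders.
#'
#' @param pedigree A data frame with columns `individual`, `parent1`,
#'   `parent2` (character or factor; `NA` or `"0"` denotes an unknown
#'   parent). Rows may be in any order; a topological order is derived.
#' @return An object of class `relationship_matrix`: a list with elements
#'   `A` (dense symmetric matrix, dimnames = individual ids), `A_inv`
#'   (its inverse) and `ids`.
#' @examples
#' ped <- data.frame(individual = c("S", "D", "O"),
#'                   parent1 = c(NA, NA, "S"), parent2 = c(NA, NA, "D"))
#' A <- build_relationship_matrix(ped)$A
#' A["S", "O"]  # 0.5
#' @export
build_relationship_matrix <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  ids <- ped$individual
  n <- length(ids)
  p1 <- match(ped$parent1, ids)
  p2 <- match(ped$parent2, ids)
  ord <- pedigree_topological_order(ids, p1, p2)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- logical(n)
  for (i in ord) {
    f <- p1[i]
    m <- p2[i]
    prev <- which(done)
    if (length(prev)) {
      av <- numeric(length(prev))
      if (!is.na(f)) av <- av + 0.5 * A[prev, f]
      if (!is.na(m)) av <- av + 0.5 * A[prev, m]
      A[prev, i] <- av
      A[i, prev] <- av
    }
    aii <- 1
    if (!is.na(f) && !is.na(m)) aii <- 1 + 0.5 * A[f, m]
    A[i, i] <- aii
    done[i] <- TRUE
  }
  structure(list(A = A, A_inv = chol2inv(chol(A)), ids = ids),
            class = "relationship_matrix")
}

# Normalize/validate a pedigree table: unknown parents become NA, duplicate
# individuals and unresolvable parents are errors.
validate_pedigree <- function(pedigree) {
  stopifnot(is.data.frame(pedigree))
  need <- c("individual", "parent1", "parent2")
  miss <- setdiff(need, names(pedigree))
  if (length(miss)) {
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  }
  ped <- data.frame(lapply(pedigree[need], as.character),
                    stringsAsFactors = FALSE)
  unk <- function(x) {
    x[!is.na(x) & (x == "0" | x == "" | x == ".")] <- NA_character_
    x
  }
  ped$parent1 <- unk(ped$parent1)
  ped$parent2 <- unk(ped$parent2)
  if (anyNA(ped$individual)) stop("pedigree has missing individual ids")
  dup <- ped$individual[duplicated(ped$individual)]
  if (length(dup)) {
    stop("duplicate individual row(s) in pedigree: ",
         paste(unique(dup), collapse = ", "))
  }
  for (pc in c("parent1", "parent2")) {
    bad <- setdiff(ped[[pc]][!is.na(ped[[pc]])], ped$individual)
    if (length(bad)) {
      stop("pedigree ", pc, " refers to unknown individual(s): ",
           paste(bad, collapse = ", "))
    }
  }
  ped
}

# Kahn-style topological order (parents before offspring); cycles are an
# error naming an involved individual.
pedigree_topological_order <- function(ids, p1, p2) {
  n <- length(ids)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(p1[i], p2[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    stuck <- ids[setdiff(seq_len(n), ord)][1]
    stop("pedigree contains a cycle involving individual ", stuck)
  }
  ord
}

#' Expand sire-MGS records into a standard pedigree
#'
#' Field pedigrees for sire-maternal-grandsire models record, for each bull,
#' its sire and its maternal grandsire (MGS). The MGS is connected through
#' an unrecorded dam: for each individual with a known MGS a phantom dam is
#' inserted whose sire is the MGS and whose dam is unknown, after which the
#' ordinary tabular method applies.
#'
#' @param sire_mgs Data frame with columns `individual`, `sire`, `mgs`
#'   (`NA`/`"0"` for unknown).
#' @return A pedigree data frame (`individual`, `parent1`, `parent2`)
#'   including phantom-dam rows (ids prefixed `"phantom_dam:"`).
#' @export
expand_sire_mgs_pedigree <- function(sire_mgs) {
  stopifnot(is.data.frame(sire_mgs))
  need <- c("individual", "sire", "mgs")
  miss <- setdiff(need, names(sire_mgs))
  if (length(miss)) {
    stop("sire_mgs is missing column(s): ", paste(miss, collapse = ", "))
  }
  sm <- data.frame(lapply(sire_mgs[need], as.character),
                   stringsAsFactors = FALSE)
  unk <- function(x) {
    x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
    x
  }
  sm$sire <- unk(sm$sire)
  sm$mgs <- unk(sm$mgs)
  has_mgs <- !is.na(sm$mgs)
  dam_id <- ifelse(has_mgs, paste0("phantom_dam:", sm$individual),
                   NA_character_)
  ped <- data.frame(individual = sm$individual,
                    parent1 = sm$sire,
                    parent2 = dam_id,
                    stringsAsFactors = FALSE)
  if (any(has_mgs)) {
    ped <- rbind(ped,
                 data.frame(individual = dam_id[has_mgs],
                            parent1 = sm$mgs[has_mgs],
                            parent2 = NA_character_,
                            stringsAsFactors = FALSE))
  }
  ped
}
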