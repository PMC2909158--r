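#' Read a phenotype table from delimited text
#'
#' Reads a comma- or tab-delimited file (header row required; delimiter
#' sniffed from the header) and validates it into a [phenotype_table()].
#' Column roles default to the writer's conventions and can be renamed via
#' the `columns` mapping (as carried by a run-configuration file).
#'
#' @param path File path.
#' @param traits,fixed,random,sire,mgs Column roles (see
#'   [phenotype_table()]).
#' @return A `phenotype_table`.
#' @export
read_phenotypes <- function(path, traits, fixed, random, sire, mgs = NULL) {
  dat <- read_delimited(path)
  need <- c(traits, fixed, random, sire, mgs)
  miss <- setdiff(need, names(dat))
  if (length(miss)) {
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (tr in traits) {
    v <- dat[[tr]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value in trait column '", tr, "' at line ",
             bad[1] + 1L, " of ", path)
      }
      dat[[tr]] <- vn
    }
  }
  phenotype_table(dat, traits = traits, fixed = fixed, random = random,
                  sire = sire, mgs = mgs)
}

#' Read a pedigree (or sire-MGS) table from delimited text
#'
#' @param path File path.
#' @param columns Length-3 character vector naming the individual and the
#'   two parent columns (for sire-MGS tables: individual, sire, mgs).
#' @param sire_mgs When `TRUE` the two parent columns are interpreted as
#'   sire and maternal grandsire and expanded through
#'   [expand_sire_mgs_pedigree()].
#' @return Pedigree data frame ready for [build_relationship_matrix()].
#' @export
read_pedigree <- function(path,
                          columns = c("individual", "parent1", "parent2"),
                          sire_mgs = FALSE) {
  dat <- read_delimited(path)
  miss <- setdiff(columns, names(dat))
  if (length(miss)) {
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  ped <- dat[columns]
  if (sire_mgs) {
    names(ped) <- c("individual", "sire", "mgs")
    expand_sire_mgs_pedigree(ped)
  } else {
    names(ped) <- c("individual", "parent1", "parent2")
    ped
  }
}

# Header-sniffing delimited reader (tab if the header contains one,
# else comma).
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("file ", path, " is empty")
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a phenotype table (round-trip safe)
#'
#' @param phenotypes A data frame / `phenotype_table`.
#' @param path Output path (tab-delimited, header row).
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(as.data.frame(phenotypes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a run-configuration file
#'
#' YAML configuration with one top-level block per subcommand
#' (`simulate`, `fit`, `summarize`, `compare`, `evaluate`, `replicate`)
#' plus `paths` and `seed`. Unknown top-level or block keys are rejected
#' before any computation.
#'
#' @param path YAML file path.
#' @return Named list of validated configuration blocks.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("simulate", "fit", "summarize", "compare", "evaluate",
               "replicate", "paths", "seed", "columns")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  block_keys <- list(
    simulate = c(names(formals(sim_config)), "design",
                 names(formals(fieldlike_config))),
    fit = names(formals(fit_config)),
    replicate = c("n_replicates", "true_models", "burn_in", "n_keep",
                  "thin", "master_seed"),
    compare = "threshold",
    evaluate = "k",
    summarize = "convention")
  for (b in intersect(names(cfg), names(block_keys))) {
    bad <- setdiff(names(cfg[[b]]), unique(block_keys[[b]]))
    if (length(bad)) {
      stop("unknown key(s) in '", b, "' block: ",
           paste(bad, collapse = ", "))
    }
  }
  cfg
}

# Deterministic per-replicate seed from a master seed (kept below 2^31).
replicate_seed <- function(master_seed, replicate, stream = 0L) {
  as.integer((as.numeric(master_seed) * 1009 + as.numeric(replicate) * 97 +
                as.numeric(stream) * 7) %% 2147480009)
}
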