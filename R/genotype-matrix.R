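#' Construct a codominant genotype matrix
#'
#' The central container for diploid, codominant SSR data: for every
#' (accession, locus) cell an unordered pair of allele labels, where a label
#' is the amplified fragment size in base pairs (a positive integer).  A
#' fully missing call is allowed and stored as `NA` in both allele slots;
#' half-missing calls (one allele observed, one not) are rejected because
#' they make allele dosage ambiguous.
#'
#' @param a1,a2 integer matrices (accessions x loci) holding the two allele
#'   slots.  Pairs are stored unordered; the constructor canonicalises them
#'   so that `a1 <= a2` elementwise.
#' @param accession_ids,locus_ids character vectors of unique identifiers;
#'   default to the dimnames of `a1`.
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `a1`, `a2` (integer matrices with dimnames), `accession_ids`,
#'   `locus_ids`.
#' @export
genotype_matrix <- function(a1, a2, accession_ids = rownames(a1),
                            locus_ids = colnames(a1)) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices 'a1' and 'a2' must have identical dimensions")
  if (is.null(accession_ids) || is.null(locus_ids))
    stop("accession and locus identifiers are required")
  accession_ids <- as.character(accession_ids)
  locus_ids <- as.character(locus_ids)
  if (length(accession_ids) != nrow(a1))
    stop("length of 'accession_ids' does not match the number of rows")
  if (length(locus_ids) != ncol(a1))
    stop("length of 'locus_ids' does not match the number of columns")
  if (anyDuplicated(accession_ids))
    stop("duplicate accession id: ",
         paste(unique(accession_ids[duplicated(accession_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus id: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))

  storage.mode(a1) <- "double"
  storage.mode(a2) <- "double"
  bad_int <- function(x) !is.na(x) & (x != round(x) | x <= 0)
  if (any(bad_int(a1)) || any(bad_int(a2))) {
    idx <- which(bad_int(a1) | bad_int(a2), arr.ind = TRUE)[1L, ]
    stop(sprintf("allele labels must be positive integers (accession '%s', locus '%s')",
                 accession_ids[idx[1L]], locus_ids[idx[2L]]))
  }
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1L, ]
    stop(sprintf("half-missing genotype at accession '%s', locus '%s': both alleles must be observed or both missing",
                 accession_ids[idx[1L]], locus_ids[idx[2L]]))
  }
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  storage.mode(lo) <- "integer"
  storage.mode(hi) <- "integer"
  dimnames(lo) <- dimnames(hi) <- list(accession_ids, locus_ids)
  structure(list(a1 = lo, a2 = hi,
                 accession_ids = accession_ids, locus_ids = locus_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d loci (%d missing calls)\n",
              length(x$accession_ids), length(x$locus_ids),
              sum(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) {
  c(length(x$accession_ids), length(x$locus_ids))
}

#' Restrict a genotype matrix to a subset of accessions
#'
#' @param g a [genotype_matrix()].
#' @param ids character vector of accession ids to keep; order of the
#'   original matrix is preserved.
#' @return A `genotype_matrix` over the requested accessions.
#' @export
subset_accessions <- function(g, ids) {
  stopifnot(inherits(g, "genotype_matrix"))
  ids <- as.character(ids)
  missing_ids <- setdiff(ids, g$accession_ids)
  if (length(missing_ids))
    stop("unknown accession id(s): ", paste(missing_ids, collapse = ", "))
  keep <- g$accession_ids %in% ids
  genotype_matrix(g$a1[keep, , drop = FALSE], g$a2[keep, , drop = FALSE])
}

#' Construct a metabolite concentration table
#'
#' Holds per-accession concentrations (mg/g dry weight) for a set of
#' compounds -- by default the six coumarins quantified in Angelica roots.
#' Values must be non-negative and complete: accessions entering the LDSS
#' deletion rule need a defined total score, so no missing values are
#' permitted and nothing is imputed.
#'
#' @param values numeric matrix or data frame (accessions x compounds).
#' @param accession_ids,compound_ids identifiers; default to dimnames.
#' @return Object of class `"metabolite_table"`: a numeric matrix with
#'   dimnames plus a `total_score` attribute is *not* stored -- use
#'   [total_score()].
#' @export
metabolite_table <- function(values, accession_ids = rownames(values),
                             compound_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("metabolite values must be numeric")
  if (is.null(accession_ids) || is.null(compound_ids))
    stop("accession and compound identifiers are required")
  accession_ids <- as.character(accession_ids)
  compound_ids <- as.character(compound_ids)
  if (anyDuplicated(accession_ids))
    stop("duplicate accession id in metabolite table")
  if (length(accession_ids) != nrow(values) ||
      length(compound_ids) != ncol(values))
    stop("identifier lengths do not match the value matrix")
  if (anyNA(values))
    stop("missing metabolite values are not permitted (no imputation)")
  if (any(!is.finite(values)))
    stop("metabolite values must be finite")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative concentration at accession '%s', compound '%s'",
                 accession_ids[idx[1L]], compound_ids[idx[2L]]))
  }
  dimnames(values) <- list(accession_ids, compound_ids)
  structure(values, class = c("metabolite_table", "matrix"))
}

#' Total metabolite score per accession
#'
#' The unweighted sum over all compounds -- the "total coumarin content"
#' used by the LDSS deletion rule.
#'
#' @param m a [metabolite_table()].
#' @param weights optional per-compound weights (defaults to 1).
#' @return Named numeric vector of totals (mg/g).
#' @export
total_score <- function(m, weights = NULL) {
  stopifnot(inherits(m, "metabolite_table"))
  v <- unclass(m)
  if (is.null(weights)) weights <- rep(1, ncol(v))
  if (length(weights) != ncol(v))
    stop("'weights' must have one entry per compound")
  drop(v %*% weights)
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table: %d accessions x %d compounds (mg/g)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Construct a population map
#'
#' @param labels named character vector: `names(labels)` are accession ids,
#'   values are population labels.
#' @param genotypes optional [genotype_matrix()]; if given, every labelled
#'   accession must exist in it.
#' @return Named character vector of class `"population_map"`.
#' @export
population_map <- function(labels, genotypes = NULL) {
  labels <- vapply(labels, as.character, character(1))
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("population labels must be named by accession id")
  if (anyDuplicated(names(labels)))
    stop("duplicate accession id in population map")
  if (length(unique(labels)) < 1L)
    stop("at least one population is required")
  if (!is.null(genotypes)) {
    unknown <- setdiff(names(labels), genotypes$accession_ids)
    if (length(unknown))
      stop("population map names unknown accession(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(labels, class = "population_map")
}
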