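#' Read a codominant SSR genotype table
#'
#' Two dialects are supported.  `"genalex_csv"` is the GenAlEx codominant
#' layout: up to two leading metadata rows (counts and titles) which are
#' detected and skipped, then a header row with the accession column, an
#' optional `Pop` column, and two columns per locus (the locus name in the
#' first column of each pair); `0` encodes a missing allele.  `"simple_tsv"`
#' is a plain tab-separated table with one `a1/a2` cell per locus and `0/0`
#' for missing.
#'
#' A whole-locus missing call (`0 0` / `0/0`) is legal; a half-missing call
#' (`150 0`) is an error, as are duplicate accession ids and non-integer
#' allele labels.
#'
#' @param path file to read.
#' @param dialect `"genalex_csv"` or `"simple_tsv"`.
#' @return A [genotype_matrix()].  For the GenAlEx dialect, if a `Pop`
#'   column is present the labels are attached as attribute
#'   `"populations"` (a [population_map()]).
#' @export
read_genotypes <- function(path, dialect = c("genalex_csv", "simple_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         genalex_csv = read_genotypes_genalex(path),
         simple_tsv = read_genotypes_tsv(path))
}

read_genotypes_genalex <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, ",", fixed = TRUE)
  first_cell <- vapply(cells, function(x) trimws(x[1L]), character(1))
  # GenAlEx files open with a numeric parameter row and a title row
  skip <- 0L
  if (length(cells) && grepl("^[0-9]+$", first_cell[1L])) skip <- 2L
  if (length(cells) <= skip + 1L) stop("no genotype rows found in ", path)
  header <- trimws(cells[[skip + 1L]])
  body <- cells[(skip + 2L):length(cells)]

  has_pop <- length(header) >= 2L && tolower(header[2L]) %in% c("pop", "population")
  first_locus_col <- if (has_pop) 3L else 2L
  locus_cols <- seq(first_locus_col, length(header), by = 2L)
  locus_ids <- header[locus_cols]
  if (any(!nzchar(locus_ids)))
    stop("empty locus name in header of ", path)

  acc <- vapply(body, function(x) trimws(x[1L]), character(1))
  pops <- if (has_pop) vapply(body, function(x) trimws(x[2L]), character(1)) else NULL
  parse_allele <- function(x, accession, locus) {
    x <- trimws(x)
    if (!length(x) || is.na(x) || !nzchar(x)) x <- "0"
    if (!grepl("^[0-9]+$", x))
      stop(sprintf("non-integer allele '%s' at accession '%s', locus '%s'",
                   x, accession, locus))
    v <- as.integer(x)
    if (v == 0L) NA_integer_ else v
  }
  n <- length(body)
  L <- length(locus_ids)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    row <- body[[i]]
    for (j in seq_len(L)) {
      c1 <- locus_cols[j]
      a1[i, j] <- parse_allele(row[c1], acc[i], locus_ids[j])
      a2[i, j] <- parse_allele(row[c1 + 1L], acc[i], locus_ids[j])
    }
  }
  check_half_missing(a1, a2, acc, locus_ids)
  g <- genotype_matrix(a1, a2, accession_ids = acc, locus_ids = locus_ids)
  if (has_pop) attr(g, "populations") <- population_map(stats::setNames(pops, acc), g)
  g
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L) stop("simple TSV needs an accession column plus loci")
  acc <- trimws(tab[[1L]])
  locus_ids <- colnames(tab)[-1L]
  n <- nrow(tab)
  L <- length(locus_ids)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    parts <- strsplit(trimws(tab[[j + 1L]]), "/", fixed = TRUE)
    for (i in seq_len(n)) {
      p <- parts[[i]]
      if (length(p) != 2L || !all(grepl("^[0-9]+$", p)))
        stop(sprintf("malformed genotype '%s' at accession '%s', locus '%s' (expected 'a1/a2')",
                     tab[i, j + 1L], acc[i], locus_ids[j]))
      v <- as.integer(p)
      v[v == 0L] <- NA_integer_
      a1[i, j] <- v[1L]
      a2[i, j] <- v[2L]
    }
  }
  check_half_missing(a1, a2, acc, locus_ids)
  genotype_matrix(a1, a2, accession_ids = acc, locus_ids = locus_ids)
}

check_half_missing <- function(a1, a2, acc, loci) {
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1L, ]
    stop(sprintf("half-missing genotype at accession '%s', locus '%s'",
                 acc[idx[1L]], loci[idx[2L]]))
  }
  invisible(NULL)
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()]: `read_genotypes(write_genotypes(g))` is
#' the identity for both dialects (allele pairs are stored unordered, so
#' pairs round-trip in canonical `min/max` order).
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param dialect `"genalex_csv"` or `"simple_tsv"`.
#' @param populations optional [population_map()] written as the GenAlEx
#'   `Pop` column (ignored for the TSV dialect).
#' @export
write_genotypes <- function(g, path, dialect = c("genalex_csv", "simple_tsv"),
                            populations = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  dialect <- match.arg(dialect)
  a1 <- g$a1; a2 <- g$a2
  a1[is.na(a1)] <- 0L
  a2[is.na(a2)] <- 0L
  if (dialect == "simple_tsv") {
    cells <- matrix(paste(a1, a2, sep = "/"), nrow = nrow(a1))
    out <- data.frame(accession = g$accession_ids, cells,
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(out) <- c("accession", g$locus_ids)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  n <- length(g$accession_ids)
  L <- length(g$locus_ids)
  has_pop <- !is.null(populations)
  pops <- if (has_pop) unname(unclass(populations)[g$accession_ids]) else NULL
  n_pops <- if (has_pop) length(unique(pops)) else 1L
  header <- character(1L + has_pop + 2L * L)
  header[1L] <- "accession"
  if (has_pop) header[2L] <- "Pop"
  header[seq(1L + has_pop + 1L, length(header), by = 2L)] <- g$locus_ids
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(L, n, n_pops), collapse = ","), con)
  writeLines("corekit genotype export", con)
  writeLines(paste(header, collapse = ","), con)
  for (i in seq_len(n)) {
    row <- character(2L * L)
    row[seq(1L, 2L * L, by = 2L)] <- a1[i, ]
    row[seq(2L, 2L * L, by = 2L)] <- a2[i, ]
    lead <- if (has_pop) c(g$accession_ids[i], pops[i]) else g$accession_ids[i]
    writeLines(paste(c(lead, row), collapse = ","), con)
  }
  invisible(path)
}

#' Read a metabolite concentration table
#'
#' CSV with the accession id in the first column and one numeric column per
#' compound (mg/g).  Negative, non-numeric or empty cells are hard errors;
#' nothing is imputed.
#'
#' @param path CSV file.
#' @return A [metabolite_table()] with compound order preserved.
#' @export
read_metabolites <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("metabolite CSV needs an accession column plus >= 1 compound")
  acc <- trimws(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or empty concentration at accession '%s', compound '%s'",
                 acc[idx[1L]], colnames(num)[idx[2L]]))
  }
  rownames(num) <- acc
  metabolite_table(num)
}

#' Write a metabolite table as CSV
#' @param m a [metabolite_table()].
#' @param path output file.
#' @export
write_metabolites <- function(m, path) {
  stopifnot(inherits(m, "metabolite_table"))
  out <- data.frame(accession = rownames(m), unclass(m),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read population labels from a two-column TSV
#' @param path TSV with columns accession, population (header optional but
#'   recommended).
#' @param genotypes optional [genotype_matrix()] to validate against.
#' @return A [population_map()].
#' @export
read_populations <- function(path, genotypes = NULL) {
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L) stop("population TSV needs two columns")
  population_map(stats::setNames(trimws(tab[[2L]]), trimws(tab[[1L]])), genotypes)
}

#' Write a structured report as JSON or TSV
#'
#' JSON serialisation keeps full double precision so that reports
#' round-trip losslessly; the TSV format applies to tabular objects
#' (data frames, matrices, or objects with an `as.data.frame` method).
#'
#' @param obj object to serialise.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @export
write_report <- function(obj, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_payload(obj), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else {
    tab <- as.data.frame(obj)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

report_payload <- function(obj) {
  if (inherits(obj, "diversity_summary")) {
    list(per_locus = obj$per_locus, means = as.list(obj$means),
         total_alleles = obj$total_alleles, n_loci = nrow(obj$per_locus))
  } else if (inherits(obj, "amova_result")) {
    list(table = obj$table, variance_components = as.list(obj$components),
         percent_variance = as.list(obj$percent), phi_pt = obj$phi_pt,
         p_value = obj$p_value, n_permutations = obj$n_permutations)
  } else obj
}
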