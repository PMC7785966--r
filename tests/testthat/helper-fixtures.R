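# small genotype fixtures built in code ------------------------------------

# build a genotype_matrix from a list of per-locus call strings:
# make_geno(L1 = c("150/150", "150/152", "0/0"), ...)
make_geno <- function(..., ids = NULL) {
  loci <- list(...)
  n <- length(loci[[1]])
  if (is.null(ids)) ids <- sprintf("acc%02d", seq_len(n))
  parse <- function(calls) {
    m <- do.call(rbind, strsplit(calls, "/"))
    a <- matrix(as.integer(m), ncol = 2)
    a[a == 0L] <- NA_integer_
    a
  }
  mats <- lapply(loci, parse)
  a1 <- do.call(cbind, lapply(mats, function(m) m[, 1]))
  a2 <- do.call(cbind, lapply(mats, function(m) m[, 2]))
  rownames(a1) <- ids
  colnames(a1) <- names(loci)
  genotype_matrix(a1, a2, accession_ids = ids, locus_ids = names(loci))
}

# random small panel for property tests (complete or with missing calls)
random_geno <- function(n = 8, L = 3, max_alleles = 4, missing_rate = 0,
                        seed = 1) {
  set.seed(seed)
  a1 <- matrix(0L, n, L)
  a2 <- matrix(0L, n, L)
  for (j in seq_len(L)) {
    alleles <- 100L + 2L * seq_len(sample(2:max_alleles, 1))
    a1[, j] <- sample(alleles, n, replace = TRUE)
    a2[, j] <- sample(alleles, n, replace = TRUE)
  }
  if (missing_rate > 0) {
    mask <- matrix(runif(n * L) < missing_rate, n, L)
    for (j in seq_len(L)) if (all(mask[, j])) mask[1, j] <- FALSE
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
  }
  rownames(a1) <- sprintf("acc%02d", seq_len(n))
  colnames(a1) <- sprintf("loc%02d", seq_len(L))
  genotype_matrix(a1, a2)
}

random_metabolites <- function(g, n_compounds = 3, seed = 1) {
  set.seed(seed)
  n <- length(g$accession_ids)
  v <- matrix(rlnorm(n * n_compounds), n, n_compounds,
              dimnames = list(g$accession_ids,
                              paste0("cmp", seq_len(n_compounds))))
  metabolite_table(v)
}

temp_path <- function(ext = ".txt") tempfile(fileext = ext)
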