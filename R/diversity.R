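#' Per-locus allele frequencies
#'
#' Frequencies are computed by direct gene counting: each typed accession
#' contributes two allele copies; missing calls are dropped locus by locus
#' (pairwise deletion, the POPGENE convention), so the denominator at a
#' locus is `2 * n_typed` for that locus.
#'
#' @param g a [genotype_matrix()].
#' @param subset optional character vector of accession ids to restrict to.
#' @return Object of class `"allele_freq_table"`: a named list with one
#'   entry per locus, each a list with `freq` (named numeric, sums to 1)
#'   and `n_typed`.
#' @export
allele_frequencies <- function(g, subset = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(subset)) g <- subset_accessions(g, subset)
  out <- lapply(seq_along(g$locus_ids), function(j) {
    x1 <- g$a1[, j]
    x2 <- g$a2[, j]
    typed <- !is.na(x1)
    n_typed <- sum(typed)
    if (n_typed == 0L)
      stop("locus '", g$locus_ids[j], "' has no typed accessions in the subset")
    copies <- c(x1[typed], x2[typed])
    counts <- table(copies)
    freq <- as.numeric(counts) / (2 * n_typed)
    names(freq) <- names(counts)
    list(freq = freq, n_typed = n_typed)
  })
  names(out) <- g$locus_ids
  structure(out, class = "allele_freq_table")
}

#' Diversity statistics for one locus
#'
#' With allele frequencies `p_i` and `N` typed accessions:
#' \describe{
#'   \item{Na}{observed number of alleles}
#'   \item{Ne}{effective number of alleles, `1 / sum(p_i^2)`}
#'   \item{Ho}{observed heterozygosity: fraction of typed accessions with
#'     two different alleles}
#'   \item{H}{Nei's gene diversity, `1 - sum(p_i^2)` (plug-in)}
#'   \item{He}{unbiased expected heterozygosity, Levene's correction
#'     `2N / (2N - 1) * H`}
#'   \item{I}{Shannon's information index, `-sum(p_i * log(p_i))`}
#'   \item{PIC}{Botstein's polymorphism information content,
#'     `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`}
#' }
#'
#' @param g a [genotype_matrix()].
#' @param locus locus id.
#' @param subset optional accession ids.
#' @return Named numeric vector with elements `Na, Ne, Ho, He, I, H, PIC,
#'   n_typed`.
#' @export
locus_diversity <- function(g, locus, subset = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!locus %in% g$locus_ids) stop("unknown locus: ", locus)
  if (!is.null(subset)) g <- subset_accessions(g, subset)
  j <- match(locus, g$locus_ids)
  x1 <- g$a1[, j]
  x2 <- g$a2[, j]
  typed <- !is.na(x1)
  n <- sum(typed)
  if (n == 0L) stop("locus '", locus, "' has no typed accessions in the subset")
  copies <- c(x1[typed], x2[typed])
  p <- as.numeric(table(copies)) / (2 * n)
  sp2 <- sum(p^2)
  sp4 <- sum(p^4)
  ho <- mean(x1[typed] != x2[typed])
  h <- 1 - sp2
  he <- if (n >= 1L) (2 * n) / (2 * n - 1) * h else h
  c(Na = length(p),
    Ne = 1 / sp2,
    Ho = ho,
    He = he,
    I = -sum(p * log(p)),
    H = h,
    PIC = 1 - sp2 - (sp2^2 - sp4),
    n_typed = n)
}

#' Diversity summary over all loci
#'
#' Per-locus statistics plus their unweighted arithmetic means across loci
#' (every locus counts equally regardless of how many accessions were
#' typed at it) and the total allele count `sum(Na)`.
#'
#' @param g a [genotype_matrix()].
#' @param subset optional accession ids.
#' @return Object of class `"diversity_summary"`: list with `per_locus`
#'   (data frame, one row per locus), `means` (named numeric over
#'   `Na, Ne, Ho, He, I, H, PIC`) and `total_alleles`.
#' @export
diversity_summary <- function(g, subset = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(subset)) g <- subset_accessions(g, subset)
  stats <- t(vapply(g$locus_ids, function(l) locus_diversity(g, l),
                    numeric(8)))
  per_locus <- data.frame(locus = g$locus_ids, stats,
                          row.names = NULL, check.names = FALSE)
  cols <- c("Na", "Ne", "Ho", "He", "I", "H", "PIC")
  structure(list(per_locus = per_locus,
                 means = colMeans(stats[, cols, drop = FALSE]),
                 total_alleles = sum(stats[, "Na"]),
                 n_accessions = length(g$accession_ids)),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, digits = 3, ...) {
  cat(sprintf("diversity_summary: %d loci, %d accessions, %d alleles\n",
              nrow(x$per_locus), x$n_accessions, x$total_alleles))
  print(round(x$means, digits))
  invisible(x)
}

#' @export
as.data.frame.diversity_summary <- function(x, ...) x$per_locus

#' Allele retention rate of a subset
#'
#' `Ra = 100 * meanNa(subset) / meanNa(full)`: the percentage of the full
#' panel's mean allele number per locus retained by a candidate core
#' collection.  Both summaries must cover the same loci.  The value is
#' returned unrounded; reports print it to 2 decimals.
#'
#' @param subset_summary,full_summary [diversity_summary()] objects over
#'   identical locus sets, or bare numeric mean-Na values.
#' @return Percentage (numeric scalar).
#' @export
retention_rate <- function(subset_summary, full_summary) {
  mean_na <- function(s) {
    if (inherits(s, "diversity_summary")) s$means[["Na"]]
    else if (is.numeric(s) && length(s) == 1L) s
    else stop("expected a diversity_summary or a scalar mean Na")
  }
  if (inherits(subset_summary, "diversity_summary") &&
      inherits(full_summary, "diversity_summary") &&
      !identical(subset_summary$per_locus$locus, full_summary$per_locus$locus))
    stop("summaries cover different locus sets")
  100 * mean_na(subset_summary) / mean_na(full_summary)
}
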