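#' Paired t-test across loci
#'
#' Compares per-locus diversity values of a core collection against those
#' of the original panel, pairing by locus: with differences `d_l` over
#' `L` loci, `t = mean(d) / (sd(d) / sqrt(L))` and the two-sided p-value
#' comes from Student's t with `L - 1` degrees of freedom.  Degenerate
#' inputs: zero variance of the differences with zero mean gives `t = 0,
#' p = 1`; zero variance with non-zero mean gives an infinite `t` and
#' `p = 0` with a warning.
#'
#' @param x,y equal-length numeric vectors over the same loci (length
#'   >= 2).
#' @return Named numeric vector `c(t =, p =)`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  L <- length(x)
  if (L < 2L) stop("need at least 2 paired values")
  d <- x - y
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) return(c(t = 0, p = 1))
    warning("differences have zero variance but non-zero mean; p reported as 0")
    return(c(t = sign(m) * Inf, p = 0))
  }
  t <- m / (s / sqrt(L))
  c(t = t, p = 2 * stats::pt(-abs(t), df = L - 1))
}

#' Evaluate a candidate core collection
#'
#' Full quality report of a core subset against the original panel:
#' per-parameter means for original, core and removed sets; retention
#' percentages (`100 * core mean / original mean`); paired t-tests across
#' loci for `Ne`, `H` and `I`; per-compound and total metabolite means for
#' each set; and a PCoA of the full panel with core membership flags (the
#' panel is projected once, core members are flagged -- the core is not
#' re-ordinated alone).
#'
#' @param core_ids accession ids of the candidate core (a proper,
#'   non-empty subset of the panel).
#' @param g a [genotype_matrix()].
#' @param metabolites a [metabolite_table()].
#' @param populations optional [population_map()]; carried into the PCoA
#'   overlay table if given.
#' @param d optional precomputed `"gen_dist"` for the PCoA overlay.
#' @param n_axes PCoA axes to retain.
#' @return Object of class `"evaluation_report"`: list with `parameters`
#'   (data frame: parameter, original, core, removed, retention_percent),
#'   `t_tests` (data frame for Ne, H, I), `metabolites` (data frame of
#'   per-compound and total means by set), `pcoa` (data frame: accession,
#'   axes, in_core, population), `core_ids`, `removed_ids`.
#' @export
evaluate_core <- function(core_ids, g, metabolites, populations = NULL,
                          d = NULL, n_axes = 2) {
  stopifnot(inherits(g, "genotype_matrix"))
  core_ids <- as.character(core_ids)
  unknown <- setdiff(core_ids, g$accession_ids)
  if (length(unknown))
    stop("core names unknown accession(s): ", paste(unknown, collapse = ", "))
  if (length(core_ids) == 0L)
    stop("core collection is empty")
  removed_ids <- setdiff(g$accession_ids, core_ids)
  if (length(removed_ids) == 0L)
    stop("core equals the full panel; nothing to evaluate")

  s_orig <- diversity_summary(g)
  s_core <- diversity_summary(g, subset = core_ids)
  s_rem <- diversity_summary(g, subset = removed_ids)
  params <- c("Na", "Ne", "Ho", "He", "I", "H", "PIC")
  ptab <- data.frame(parameter = params,
                     original = s_orig$means[params],
                     core = s_core$means[params],
                     removed = s_rem$means[params],
                     retention_percent = 100 * s_core$means[params] / s_orig$means[params],
                     row.names = NULL)

  tt <- lapply(c("Ne", "H", "I"), function(p)
    paired_t(s_core$per_locus[[p]], s_orig$per_locus[[p]]))
  ttab <- data.frame(parameter = c("Ne", "H", "I"),
                     t = vapply(tt, `[[`, numeric(1), "t"),
                     p = vapply(tt, `[[`, numeric(1), "p"))

  met <- unclass(metabolites)[g$accession_ids, , drop = FALSE]
  set_means <- function(ids) {
    v <- met[ids, , drop = FALSE]
    c(colMeans(v), total = mean(rowSums(v)))
  }
  mtab <- data.frame(set = c("original", "core", "removed"),
                     rbind(set_means(g$accession_ids),
                           set_means(core_ids),
                           set_means(removed_ids)),
                     check.names = FALSE)

  if (is.null(d)) d <- genetic_distance(g)
  pc <- pcoa(d, n_axes = n_axes)
  overlay <- data.frame(accession = rownames(pc$coordinates),
                        pc$coordinates,
                        in_core = rownames(pc$coordinates) %in% core_ids,
                        stringsAsFactors = FALSE)
  if (!is.null(populations))
    overlay$population <- as.character(unclass(populations)[overlay$accession])

  structure(list(parameters = ptab, t_tests = ttab, metabolites = mtab,
                 pcoa = overlay, pcoa_percent_variance = pc$percent_variance,
                 core_ids = core_ids, removed_ids = removed_ids),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf("evaluation_report: core %d vs original %d accessions\n",
              length(x$core_ids), length(x$core_ids) + length(x$removed_ids)))
  tab <- x$parameters
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat("paired t-tests (core vs original):\n")
  print(transform(x$t_tests, t = round(t, 3), p = round(p, 4)), row.names = FALSE)
  invisible(x)
}

#' Random-subset baseline for core quality
#'
#' Distribution of the allele retention rate Ra and the total-metabolite
#' mean over uniformly random subsets of a given size: the null reference
#' against which a directed sampler (LDSS) is judged.
#'
#' @param g a [genotype_matrix()].
#' @param metabolites a [metabolite_table()].
#' @param size subset size, `1 <= size < n`.
#' @param reps number of random subsets.
#' @param seed RNG seed (sampling is fully reproducible).
#' @return List with vectors `ra` and `total_metabolite_mean` (length
#'   `reps`) and a `summary` data frame (mean, sd, quartiles of each).
#' @export
random_baseline <- function(g, metabolites, size, reps = 200, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$accession_ids)
  if (size < 1L || size >= n) stop("'size' must be in [1, n - 1]")
  if (reps < 1L) stop("'reps' must be >= 1")
  full <- diversity_summary(g)
  met <- unclass(metabolites)[g$accession_ids, , drop = FALSE]
  totals <- rowSums(met)
  draws <- with_seed(seed, replicate(reps, sample(g$accession_ids, size),
                                     simplify = FALSE))
  ra <- vapply(draws, function(ids)
    retention_rate(diversity_summary(g, subset = ids), full), numeric(1))
  tm <- vapply(draws, function(ids) mean(totals[ids]), numeric(1))
  qs <- function(x) c(mean = mean(x), sd = stats::sd(x),
                      stats::quantile(x, c(0.25, 0.5, 0.75)))
  list(ra = ra, total_metabolite_mean = tm,
       summary = data.frame(metric = c("Ra", "total_metabolite_mean"),
                            rbind(qs(ra), qs(tm)), check.names = FALSE))
}
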