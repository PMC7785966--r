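#' Target size of a core collection
#'
#' @param n panel size.
#' @param ratio sampling ratio in (0, 1].
#' @param rounding `"half_up"` (default), `"floor"` or `"ceil"`.
#' @return Integer target size, at least 1.
#' @export
target_size <- function(n, ratio, rounding = c("half_up", "floor", "ceil")) {
  rounding <- match.arg(rounding)
  if (n < 1L) stop("'n' must be >= 1")
  if (ratio <= 0 || ratio > 1) stop("'ratio' must be in (0, 1]")
  x <- n * ratio
  k <- switch(rounding,
              half_up = floor(x + 0.5),
              floor = floor(x),
              ceil = ceiling(x))
  as.integer(max(1L, k))
}

#' Least-distance stepwise sampling (LDSS)
#'
#' Builds nested core collections: at each step the pair of retained
#' accessions at globally minimum genetic distance is located (this is
#' exactly the first merge a fresh UPGMA run would make, so the procedure
#' is equivalent to repeated clustering), and the member of the pair with
#' the lower total metabolite score is removed.  Distances among the
#' remaining accessions are unaffected by a removal, so the matrix is
#' masked rather than recomputed.  Whenever the retained count reaches a
#' target size, that subset is checkpointed; checkpoints are therefore
#' nested along the whole ladder.
#'
#' Tie rules (making the log fully deterministic): equal minimum distances
#' resolve to the lowest (row, column) index pair in input accession
#' order; equal metabolite totals within the chosen pair remove the
#' lexicographically larger accession id.
#'
#' @param d a `"gen_dist"` matrix over the panel.
#' @param metabolites a [metabolite_table()] covering the same accessions.
#' @param ratios sampling ratios (e.g. `c(0.4, 0.3, 0.2)`); converted with
#'   [target_size()].
#' @param sizes explicit target sizes overriding `ratios` (the ladder of a
#'   published study can be reproduced verbatim this way).
#' @param rounding passed to [target_size()].
#' @param weights optional per-compound weights for [total_score()].
#' @return Object of class `"core_collection"`: list with `removal_log`
#'   (data frame: step, removed, partner, pair_distance, removed_total),
#'   `checkpoints` (named list of accession id vectors, one per target
#'   size, largest first), `target_sizes`, `accession_ids`.
#' @export
ldss_sample <- function(d, metabolites, ratios = NULL, sizes = NULL,
                        rounding = "half_up", weights = NULL) {
  D <- as.matrix(unclass(d))
  ids <- rownames(D)
  n <- length(ids)
  if (is.null(sizes)) {
    if (is.null(ratios)) stop("provide 'ratios' or 'sizes'")
    sizes <- vapply(ratios, function(r) target_size(n, r, rounding), integer(1))
    names(sizes) <- paste0(round(100 * ratios), "CC")
  } else {
    nm <- names(sizes)
    sizes <- as.integer(sizes)
    names(sizes) <- if (is.null(nm)) paste0("size", sizes) else nm
  }
  if (anyDuplicated(sizes)) stop("duplicate target sizes")
  if (any(sizes > n) || any(sizes < 1L)) stop("target sizes must be in [1, n]")
  ord <- order(sizes, decreasing = TRUE)
  sizes <- sizes[ord]

  if (!inherits(metabolites, "metabolite_table"))
    stop("'metabolites' must be a metabolite_table")
  missing_met <- setdiff(ids, rownames(metabolites))
  if (length(missing_met))
    stop("metabolite score missing for accession(s): ",
         paste(missing_met, collapse = ", "))
  totals <- total_score(metabolites, weights)[ids]

  M <- D
  diag(M) <- Inf
  retained <- rep(TRUE, n)
  log_step <- integer(0); log_removed <- character(0)
  log_partner <- character(0); log_dist <- numeric(0); log_total <- numeric(0)
  checkpoints <- vector("list", length(sizes))
  names(checkpoints) <- names(sizes)
  n_ret <- n
  ci <- 1L
  while (ci <= length(sizes) && sizes[ci] == n_ret) {
    checkpoints[[ci]] <- ids[retained]
    ci <- ci + 1L
  }
  min_target <- min(sizes)
  step <- 0L
  while (n_ret > min_target) {
    v <- M
    v[lower.tri(v, diag = TRUE)] <- Inf
    mn <- min(v)
    cand <- which(v == mn, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    ti <- totals[i]; tj <- totals[j]
    drop_idx <- if (ti < tj) i
      else if (tj < ti) j
      else if (ids[i] > ids[j]) i else j
    keep_idx <- if (drop_idx == i) j else i
    step <- step + 1L
    log_step[step] <- step
    log_removed[step] <- ids[drop_idx]
    log_partner[step] <- ids[keep_idx]
    log_dist[step] <- mn
    log_total[step] <- totals[drop_idx]
    retained[drop_idx] <- FALSE
    M[drop_idx, ] <- Inf
    M[, drop_idx] <- Inf
    n_ret <- n_ret - 1L
    while (ci <= length(sizes) && sizes[ci] == n_ret) {
      checkpoints[[ci]] <- ids[retained]
      ci <- ci + 1L
    }
  }
  structure(list(removal_log = data.frame(step = log_step,
                                          removed = log_removed,
                                          partner = log_partner,
                                          pair_distance = log_dist,
                                          removed_total = log_total,
                                          stringsAsFactors = FALSE),
                 checkpoints = checkpoints,
                 target_sizes = sizes,
                 accession_ids = ids),
            class = "core_collection")
}

#' @export
print.core_collection <- function(x, ...) {
  cat(sprintf("core_collection: %d accessions, %d removals, checkpoints: %s\n",
              length(x$accession_ids), nrow(x$removal_log),
              paste(sprintf("%s=%d", names(x$target_sizes), x$target_sizes),
                    collapse = ", ")))
  invisible(x)
}

#' LDSS ladder with per-checkpoint summaries
#'
#' Runs [ldss_sample()] over a ladder of sampling ratios and evaluates each
#' checkpoint: diversity summary, allele retention rate Ra against the
#' full panel, and per-compound plus total metabolite means (mg/g).
#'
#' @param g a [genotype_matrix()].
#' @param metabolites a [metabolite_table()].
#' @param ratios sampling ratios, largest first by convention (default the
#'   40--10 percent ladder).
#' @param sizes optional explicit sizes overriding `ratios`.
#' @param distance_method passed to [genetic_distance()].
#' @param d optional precomputed `"gen_dist"` matrix (overrides
#'   `distance_method`).
#' @inheritParams ldss_sample
#' @return Object of class `"ldss_ladder"`: list with `core` (the
#'   [ldss_sample()] result), `summaries` (named list of
#'   [diversity_summary()] per checkpoint), `table` (data frame in the
#'   style of a published core-collection comparison: name, ratio, size,
#'   the seven diversity means, Ra, compound means, total mean) and
#'   `original_summary`.
#' @export
ldss_ladder <- function(g, metabolites,
                        ratios = c(0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.10),
                        sizes = NULL,
                        distance_method = "band_sq_euclidean",
                        d = NULL, rounding = "half_up", weights = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(d)) d <- genetic_distance(g, distance_method)
  core <- ldss_sample(d, metabolites, ratios = ratios, sizes = sizes,
                      rounding = rounding, weights = weights)
  full <- diversity_summary(g)
  met <- unclass(metabolites)[g$accession_ids, , drop = FALSE]
  totals <- rowSums(met)
  ratio_of <- function(k) k / length(g$accession_ids)
  rows <- list()
  summaries <- vector("list", length(core$checkpoints))
  names(summaries) <- names(core$checkpoints)
  for (nm in names(core$checkpoints)) {
    ids <- core$checkpoints[[nm]]
    s <- diversity_summary(g, subset = ids)
    summaries[[nm]] <- s
    comp_means <- colMeans(met[ids, , drop = FALSE])
    rows[[nm]] <- data.frame(name = nm,
                             size = length(ids),
                             ratio = ratio_of(length(ids)),
                             t(s$means),
                             Ra = retention_rate(s, full),
                             t(comp_means),
                             total_coumarin = mean(totals[ids]),
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
  }
  orig_row <- data.frame(name = "original",
                         size = length(g$accession_ids),
                         ratio = 1,
                         t(full$means),
                         Ra = 100,
                         t(colMeans(met)),
                         total_coumarin = mean(totals),
                         check.names = FALSE,
                         stringsAsFactors = FALSE)
  tab <- do.call(rbind, c(list(orig_row), rows))
  rownames(tab) <- NULL
  structure(list(core = core, summaries = summaries, table = tab,
                 original_summary = full),
            class = "ldss_ladder")
}

#' @export
print.ldss_ladder <- function(x, digits = 3, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Select the best core collection from a ladder
#'
#' Codifies the trade-off "mainly genetic diversity, supplemented by
#' metabolite content": among checkpoints whose allele retention Ra meets
#' the threshold, prefer the smallest collection; break ties by higher
#' total-metabolite mean.
#'
#' @param ladder an [ldss_ladder()] result (or its `table`).
#' @param ra_threshold minimum acceptable Ra percentage (default 90).
#' @return The `name` of the selected checkpoint.
#' @export
select_core <- function(ladder, ra_threshold = 90) {
  tab <- if (inherits(ladder, "ldss_ladder")) ladder$table else as.data.frame(ladder)
  tab <- tab[tab$name != "original", , drop = FALSE]
  ok <- tab[tab$Ra >= ra_threshold, , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("no checkpoint reaches Ra >= ", ra_threshold)
  ok <- ok[order(ok$size, -ok$total_coumarin), , drop = FALSE]
  ok$name[1L]
}
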