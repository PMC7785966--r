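#' Binary band (allele incidence) matrix
#'
#' Bridges codominant calls to band-based similarity: one column per
#' distinct allele per locus, with entry 1 if the accession carries at
#' least one copy of that allele (dosage is collapsed), 0 if it carries
#' none, and `NA` for every allele column of a locus at which the
#' accession's call is missing (so the pair is excluded column-wise
#' downstream).
#'
#' @param g a [genotype_matrix()].
#' @return Numeric matrix (accessions x distinct alleles), columns named
#'   `locus.allele`.
#' @export
band_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  cols <- list()
  for (j in seq_along(g$locus_ids)) {
    x1 <- g$a1[, j]
    x2 <- g$a2[, j]
    alleles <- sort(unique(c(x1, x2)))
    alleles <- alleles[!is.na(alleles)]
    block <- matrix(0, nrow = length(x1), ncol = length(alleles))
    for (k in seq_along(alleles))
      block[, k] <- as.numeric(x1 == alleles[k] | x2 == alleles[k])
    block[is.na(x1), ] <- NA
    colnames(block) <- paste(g$locus_ids[j], alleles, sep = ".")
    cols[[j]] <- block
  }
  out <- do.call(cbind, cols)
  rownames(out) <- g$accession_ids
  out
}

new_dist_matrix <- function(m, ids, kind, squared) {
  dimnames(m) <- list(ids, ids)
  structure(m, class = c("gen_dist", "matrix"),
            kind = kind, squared = squared)
}

# pairwise sum over mutually-known columns of (x - y)^2, plus the count of
# mutually-known columns; handles NA cells via indicator algebra
pairwise_sq_diff <- function(bands) {
  known <- !is.na(bands)
  x <- bands
  x[!known] <- 0
  x2 <- x^2
  K <- known * 1
  cross <- tcrossprod(x)
  s <- tcrossprod(x2, K) + tcrossprod(K, x2) - 2 * cross
  m <- tcrossprod(K)
  list(sq = s, m = m)
}

#' Simple-matching distance between band vectors
#'
#' The simple matching coefficient counts matches including shared
#' absences: `SM(i,j) = matches / columns known in both`; the distance is
#' `1 - SM`.  For binary bands the mismatch count equals the squared
#' difference sum, so `d = mismatches / known`.
#'
#' @param bands a [band_matrix()] (or any 0/1 matrix with optional `NA`).
#' @return A `"gen_dist"` distance matrix, kind `"simple_matching"`.
#' @export
simple_matching_distance <- function(bands) {
  if (nrow(bands) < 2L) stop("need at least 2 accessions")
  pw <- pairwise_sq_diff(bands)
  if (any(pw$m[upper.tri(pw$m)] == 0)) {
    idx <- which(pw$m == 0 & upper.tri(pw$m), arr.ind = TRUE)[1L, ]
    stop(sprintf("accessions '%s' and '%s' share no mutually typed band columns",
                 rownames(bands)[idx[1L]], rownames(bands)[idx[2L]]))
  }
  d <- pw$sq / pw$m
  diag(d) <- 0
  new_dist_matrix(d, rownames(bands), "simple_matching", squared = FALSE)
}

#' Band squared-Euclidean distance
#'
#' The squared Euclidean distance between binary band vectors (the
#' GenAlEx-style individual distance for codominant data exported as band
#' presence/absence).  With missing bands, the sum over mutually known
#' columns is rescaled by `total columns / known columns` so distances stay
#' comparable across pairs.  The stored values are already squared
#' (attribute `squared = TRUE`); downstream consumers (PCoA, AMOVA) use
#' them directly without squaring again.
#'
#' @param bands a [band_matrix()].
#' @return A `"gen_dist"` distance matrix, kind `"band_sq_euclidean"`.
#' @export
band_sq_euclidean_distance <- function(bands) {
  if (nrow(bands) < 2L) stop("need at least 2 accessions")
  pw <- pairwise_sq_diff(bands)
  if (any(pw$m[upper.tri(pw$m)] == 0))
    stop("some accession pair shares no mutually typed band columns")
  d <- pw$sq * (ncol(bands) / pw$m)
  diag(d) <- 0
  new_dist_matrix(d, rownames(bands), "band_sq_euclidean", squared = TRUE)
}

#' Genetic distance between accessions
#'
#' Convenience wrapper: builds the band matrix and the requested distance.
#'
#' @param g a [genotype_matrix()].
#' @param method `"band_sq_euclidean"` (default, used for PCoA/AMOVA/LDSS)
#'   or `"simple_matching"` (used for UPGMA in the NTSYS tradition).
#' @return A `"gen_dist"` matrix.
#' @export
genetic_distance <- function(g, method = c("band_sq_euclidean", "simple_matching")) {
  method <- match.arg(method)
  b <- band_matrix(g)
  switch(method,
         band_sq_euclidean = band_sq_euclidean_distance(b),
         simple_matching = simple_matching_distance(b))
}

squared_values <- function(d) {
  if (isTRUE(attr(d, "squared"))) unclass(d) else unclass(d)^2
}

#' UPGMA clustering
#'
#' Standard unweighted pair-group average clustering: repeatedly merge the
#' pair of clusters at minimum distance, at node height `d/2`; the distance
#' from the merged cluster to any other is the size-weighted arithmetic
#' mean of the member distances.  Ties in the minimum are broken by lowest
#' (row, column) index in the current matrix order, which makes the output
#' deterministic.
#'
#' @param d a `"gen_dist"` matrix (or plain symmetric matrix with
#'   dimnames).
#' @return Object of class `"corekit_dendrogram"`: list with `merge`
#'   (hclust-style signed matrix), `height` (node heights, `d/2`),
#'   `labels`.
#' @export
upgma <- function(d) {
  D <- as.matrix(unclass(d))
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 accessions")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  node <- -seq_len(n)
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  M <- D
  for (step in seq_len(n - 1L)) {
    v <- M
    v[lower.tri(v, diag = TRUE)] <- Inf
    m <- min(v)
    cand <- which(v == m, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    merge[step, ] <- c(node[i], node[j])
    height[step] <- m / 2
    newrow <- (size[i] * M[i, ] + size[j] * M[j, ]) / (size[i] + size[j])
    M[i, ] <- newrow
    M[, i] <- newrow
    M[i, i] <- 0
    M <- M[-j, -j, drop = FALSE]
    size[i] <- size[i] + size[j]
    node[i] <- step
    size <- size[-j]
    node <- node[-j]
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "corekit_dendrogram")
}

#' @export
print.corekit_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, root height %.4g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Cophenetic distance matrix of a dendrogram
#'
#' The height at which two leaves first share a cluster, times 2 (so that
#' on an exactly ultrametric input UPGMA reproduces the original
#' distances).
#'
#' @param dend a `"corekit_dendrogram"`.
#' @return Symmetric numeric matrix.
#' @export
cophenetic_matrix <- function(dend) {
  n <- length(dend$labels)
  members <- vector("list", n - 1L)
  out <- matrix(0, n, n, dimnames = list(dend$labels, dend$labels))
  for (step in seq_len(n - 1L)) {
    kids <- lapply(dend$merge[step, ], function(k)
      if (k < 0) -k else members[[k]])
    for (a in kids[[1L]]) for (b in kids[[2L]])
      out[a, b] <- out[b, a] <- 2 * dend$height[step]
    members[[step]] <- c(kids[[1L]], kids[[2L]])
  }
  out
}

#' Serialise a dendrogram to Newick
#'
#' Branch lengths are height differences between parent and child nodes
#' (leaves sit at height 0), so the tree is ultrametric: every leaf is at
#' distance `root height` from the root.
#'
#' @param dend a `"corekit_dendrogram"`.
#' @param path optional file; if given the string (with trailing newline)
#'   is written there.
#' @param digits significant digits for branch lengths.
#' @return The Newick string, invisibly if `path` is given.
#' @export
write_tree_newick <- function(dend, path = NULL, digits = 10) {
  stopifnot(inherits(dend, "corekit_dendrogram"))
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  render <- function(k, parent_height) {
    if (k < 0) {
      sprintf("%s:%s", dend$labels[-k], fmt(parent_height))
    } else {
      h <- dend$height[k]
      sprintf("(%s,%s):%s",
              render(dend$merge[k, 1L], h),
              render(dend$merge[k, 2L], h),
              fmt(parent_height - h))
    }
  }
  root <- nrow(dend$merge)
  h <- dend$height[root]
  nwk <- sprintf("(%s,%s);",
                 render(dend$merge[root, 1L], h),
                 render(dend$merge[root, 2L], h))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Principal coordinates analysis
#'
#' Classical metric MDS: Gower double-centering of `-1/2 * d^2` (for
#' distances stored already squared, of `-1/2 * d`), eigendecomposition,
#' coordinates scaled by the square roots of the positive eigenvalues.
#' Negative eigenvalues (non-Euclidean input) are reported but excluded
#' from the percent-variance denominator.
#'
#' @param d a `"gen_dist"` matrix.
#' @param n_axes number of axes to retain (clipped to `n - 1` with a
#'   warning).
#' @return Object of class `"pcoa_result"`: list with `coordinates`
#'   (accessions x axes), `eigenvalues` (all, descending),
#'   `percent_variance` (per retained axis, over the positive eigenvalue
#'   sum).
#' @export
pcoa <- function(d, n_axes = 2) {
  D <- as.matrix(unclass(d))
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 accessions")
  if (n_axes > n - 1L) {
    warning("n_axes clipped to n - 1")
    n_axes <- n - 1L
  }
  A <- -0.5 * squared_values(d)
  rm_ <- rowMeans(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  vals <- e$values
  pos <- which(vals > max(abs(vals)) * 1e-12)
  k <- min(n_axes, length(pos))
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(vals[pos[seq_len(k)]]), k)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 percent_variance = 100 * vals[pos[seq_len(k)]] / sum(vals[pos]),
                 trace = sum(diag(G))),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "points,",
      ncol(x$coordinates), "axes;",
      paste(sprintf("%.2f%%", x$percent_variance), collapse = ", "),
      "variance\n")
  invisible(x)
}

#' One-level AMOVA with Phi-PT
#'
#' Excoffier-style analysis of molecular variance on squared inter-
#' individual distances, partitioning the total sum of squares into among-
#' and within-population components.  With groups `g` of sizes `n_g`:
#' `SS_total = sum_{i<j} d2_ij / n`, `SS_within = sum_g sum_{i<j in g}
#' d2_ij / n_g`, `SS_among = SS_total - SS_within`; degrees of freedom
#' `G - 1` and `n - G`; `sigma2_within = MS_within`, `sigma2_among =
#' (MS_among - MS_within) / n0` with `n0 = (n - sum n_g^2 / n) / (G - 1)`.
#' Negative component estimates are clamped to zero (with a warning).
#' `PhiPT = sigma2_among / (sigma2_among + sigma2_within)`; the permutation
#' p-value shuffles population labels with a fixed seed.
#'
#' @param d a `"gen_dist"` matrix.
#' @param populations a [population_map()] or named vector covering all
#'   accessions of `d`.
#' @param n_permutations number of label permutations for the p-value
#'   (0 = skip).
#' @param seed integer seed for the permutations.
#' @return Object of class `"amova_result"`.
#' @export
amova <- function(d, populations, n_permutations = 0, seed = 1) {
  D2 <- squared_values(d)
  ids <- rownames(D2)
  pops <- as.character(unclass(populations)[ids])
  if (anyNA(pops)) stop("population label missing for some accessions")
  sizes <- table(pops)
  if (length(sizes) < 2L) stop("need at least 2 populations")
  if (any(sizes < 2L))
    stop("population(s) of size 1: ", paste(names(sizes)[sizes < 2L], collapse = ", "))
  res <- amova_components(D2, pops)
  phi_obs <- res$phi_pt
  p_value <- NA_real_
  if (n_permutations > 0) {
    perm_phi <- with_seed(seed, vapply(seq_len(n_permutations), function(k) {
      amova_components(D2, sample(pops))$phi_pt
    }, numeric(1)))
    p_value <- (1 + sum(perm_phi >= phi_obs - 1e-12)) / (1 + n_permutations)
  }
  structure(c(res, list(p_value = p_value, n_permutations = n_permutations,
                        populations = sizes)),
            class = "amova_result")
}

amova_components <- function(D2, pops) {
  n <- nrow(D2)
  groups <- unique(pops)
  G <- length(groups)
  ut <- upper.tri(D2)
  ss_total <- sum(D2[ut]) / n
  ss_within <- 0
  for (g in groups) {
    idx <- which(pops == g)
    sub <- D2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1
  df_within <- n - G
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  sizes <- as.numeric(table(pops)[groups])
  n0 <- (n - sum(sizes^2) / n) / df_among
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  clamped <- FALSE
  if (sigma_among < 0) { sigma_among <- 0; clamped <- TRUE }
  tot <- sigma_among + sigma_within
  if (tot <= 0) {
    warning("all variance components are zero; PhiPT reported as 0")
    phi <- 0
    pct <- c(among = 0, within = 100)
  } else {
    phi <- sigma_among / tot
    pct <- c(among = 100 * sigma_among / tot, within = 100 * sigma_within / tot)
  }
  list(table = data.frame(source = c("Among populations", "Within populations", "Total"),
                          df = c(df_among, df_within, df_among + df_within),
                          SS = c(ss_among, ss_within, ss_total),
                          MS = c(ms_among, ms_within, NA)),
       components = c(among = sigma_among, within = sigma_within),
       percent = pct,
       phi_pt = phi,
       clamped = clamped)
}

#' @export
print.amova_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("PhiPT = %.4f (among %.1f%%, within %.1f%%)",
              x$phi_pt, x$percent[["among"]], x$percent[["within"]]))
  if (!is.na(x$p_value))
    cat(sprintf("; P = %.4g (%d permutations)", x$p_value, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Pairwise population differentiation (PhiPT)
#'
#' Runs [amova()] restricted to every pair of populations.
#'
#' @inheritParams amova
#' @return List with `phi_pt` (symmetric matrix, zero diagonal) and,
#'   when `n_permutations > 0`, `p_value` (matrix).
#' @export
pairwise_phipt <- function(d, populations, n_permutations = 0, seed = 1) {
  D <- as.matrix(unclass(d))
  ids <- rownames(D)
  pops <- as.character(unclass(populations)[ids])
  groups <- sort(unique(pops))
  if (length(groups) < 2L) stop("need at least 2 populations")
  k <- length(groups)
  phi <- matrix(0, k, k, dimnames = list(groups, groups))
  pval <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
    idx <- which(pops %in% groups[c(a, b)])
    sub <- d[idx, idx, drop = FALSE]
    sub <- new_dist_matrix(as.matrix(unclass(sub)), ids[idx],
                           attr(d, "kind"), isTRUE(attr(d, "squared")))
    res <- amova(sub, stats::setNames(pops[idx], ids[idx]),
                 n_permutations = n_permutations, seed = seed + a * k + b)
    phi[a, b] <- phi[b, a] <- res$phi_pt
    pval[a, b] <- pval[b, a] <- res$p_value
  }
  list(phi_pt = phi, p_value = if (n_permutations > 0) pval else NULL)
}
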