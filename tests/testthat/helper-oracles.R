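# independent brute-force reference implementations used as oracles --------

# diversity statistics by direct enumeration with explicit loops
oracle_locus_diversity <- function(g, locus) {
  j <- match(locus, g$locus_ids)
  copies <- c()
  n_typed <- 0L
  n_het <- 0L
  for (i in seq_along(g$accession_ids)) {
    x <- g$a1[i, j]; y <- g$a2[i, j]
    if (is.na(x)) next
    n_typed <- n_typed + 1L
    if (x != y) n_het <- n_het + 1L
    copies <- c(copies, x, y)
  }
  alleles <- unique(copies)
  p <- vapply(alleles, function(a) sum(copies == a) / length(copies), numeric(1))
  sp2 <- 0; i_sh <- 0
  for (pi in p) { sp2 <- sp2 + pi^2; i_sh <- i_sh - pi * log(pi) }
  pic <- 1 - sp2
  for (a in seq_along(p)) for (b in seq_along(p)) if (a < b)
    pic <- pic - 2 * p[a]^2 * p[b]^2
  c(Na = length(alleles), Ne = 1 / sp2, Ho = n_het / n_typed,
    He = (2 * n_typed) / (2 * n_typed - 1) * (1 - sp2),
    I = i_sh, H = 1 - sp2, PIC = pic, n_typed = n_typed)
}

# naive UPGMA: clusters as index lists; inter-cluster distance recomputed
# each step as the plain mean over all cross pairs of the ORIGINAL matrix
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      dij <- mean(D[clusters[[i]], clusters[[j]]])
      if (is.null(best) || dij < best$d - 1e-15) best <- list(i = i, j = j, d = dij)
    }
    h <- best$d / 2
    for (a in clusters[[best$i]]) for (b in clusters[[best$j]])
      coph[a, b] <- coph[b, a] <- 2 * h
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

# AMOVA sums of squares by direct double summation
oracle_amova_ss <- function(D2, pops) {
  n <- nrow(D2)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    ss_total <- ss_total + D2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(pops)) {
    idx <- which(pops == g)
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + D2[i, j]
    ss_within <- ss_within + acc / length(idx)
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

# naive O(n * k) microsatellite scan: every start position tried, repeats
# counted by character comparison; leftmost-maximal, irreducible motifs
oracle_ssr_scan <- function(seq, thresholds = c(10, 6, 5, 5, 5, 5)) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  out <- list()
  for (k in 1:6) {
    s <- 1L
    while (s + k - 1L <= n) {
      motif <- paste(chars[s:(s + k - 1L)], collapse = "")
      if (grepl("N", motif)) { s <- s + 1L; next }
      # count complete repeats
      reps <- 1L
      while (s + (reps + 1L) * k - 1L <= n &&
             all(chars[(s + reps * k):(s + (reps + 1L) * k - 1L)] ==
                 chars[s:(s + k - 1L)])) reps <- reps + 1L
      ok <- reps >= thresholds[k] &&
        nchar(corekit::canonical_motif(motif)) == k &&
        # reducible motifs have a shorter period; canonical_motif reduces
        identical(substr(motif, 1, k), motif) &&
        !(s > 1L && chars[s - 1L] == chars[s + k - 1L] && chars[s - 1L] != "N")
      # also require true irreducibility (canonical_motif may rotate)
      if (ok) {
        red <- k
        for (p in seq_len(k - 1)) if (k %% p == 0 &&
            motif == strrep(substr(motif, 1, p), k / p)) { red <- p; break }
        if (red < k) ok <- FALSE
      }
      if (ok) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = s + reps * k - 1L, motif = motif,
          repeat_count = reps, stringsAsFactors = FALSE)
        s <- s + reps * k
      } else s <- s + 1L
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), repeat_count = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random DNA with planted repeat runs
random_dna_with_runs <- function(len = 1000, n_runs = 3, seed = 1) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  seq <- paste(base, collapse = "")
  for (r in seq_len(n_runs)) {
    k <- sample(1:3, 1)
    motif <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                   collapse = "")
    reps <- sample(10:14, 1)
    pos <- sample(seq_len(len - reps * k), 1)
    substr(seq, pos, pos + reps * k - 1) <- strrep(motif, reps)
  }
  seq
}
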