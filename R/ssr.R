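#' Canonical form of an SSR motif
#'
#' Microsatellite motifs are grouped into strand- and phase-independent
#' classes (the familiar `A/T`, `AG/CT`, ... labels): the canonical form is
#' the lexicographic minimum over all cyclic rotations of the motif and of
#' its reverse complement.  Motifs that are themselves repetitions of a
#' shorter unit (e.g. `ATAT`) are first reduced to that unit (`AT`).
#'
#' @param motif character string over `ACGT`, length 1--6 (before
#'   reduction).
#' @return Canonical motif string.
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over ACGT")
  motif <- reduce_period(motif)
  k <- nchar(motif)
  rc <- rev_comp(motif)
  rots <- function(s) vapply(seq_len(k), function(i)
    paste0(substr(s, i, k), substr(s, 1, i - 1)), character(1))
  min(c(rots(motif), rots(rc)))
}

rev_comp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# smallest repeating unit of a string ("ATAT" -> "AT")
reduce_period <- function(s) {
  k <- nchar(s)
  for (p in seq_len(k - 1)) {
    if (k %% p == 0 &&
        s == strrep(substr(s, 1, p), k / p))
      return(substr(s, 1, p))
  }
  s
}

#' Find microsatellites in a DNA sequence
#'
#' MISA-style detection of perfect simple sequence repeats: for each motif
#' length 1--6 bp, maximal perfect runs with at least the per-length
#' minimum number of complete repeats are reported (defaults 10, 6, 5, 5,
#' 5, 5 repeats for mono- through hexanucleotides).  A run whose motif is
#' a repetition of a shorter unit is suppressed (it is already reported at
#' the shorter length), and `N` bases terminate runs.  Runs separated by
#' at most `max_interruption` bases (including overlapping runs) are
#' merged into a single compound record, which counts as one locus.
#'
#' @param sequence DNA string over `A, C, G, T, N` (case-insensitive).
#' @param thresholds integer vector of length 6: minimum repeat counts for
#'   motif lengths 1--6.
#' @param max_interruption maximum gap (bp) between neighbouring runs
#'   merged into a compound SSR.
#' @param sequence_id identifier recorded with each hit.
#' @return Data frame with columns `sequence_id, start, end, motif,
#'   repeat_count, kind, member_motifs` (1-based inclusive coordinates,
#'   ascending start; `repeat_count` is `NA` for compound records, whose
#'   member runs are listed as `(motif)count` joined by `-`).
#' @export
find_ssrs <- function(sequence, thresholds = c(10, 6, 5, 5, 5, 5),
                      max_interruption = 100, sequence_id = "seq1") {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains non-IUPAC characters (allowed: A, C, G, T, N)")
  if (length(thresholds) != 6L || any(thresholds < 2))
    stop("'thresholds' must give 6 minimum repeat counts (each >= 2)")
  runs <- empty_ssr_frame()
  for (k in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, thresholds[k] - 1L)
    m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (idx in seq_along(starts)) {
      motif <- substr(sequence, starts[idx], starts[idx] + k - 1L)
      if (nchar(reduce_period(motif)) < k) next  # sub-pattern of shorter run
      reps <- lens[idx] %/% k
      runs <- rbind(runs, data.frame(
        sequence_id = sequence_id,
        start = starts[idx],
        end = starts[idx] + reps * k - 1L,
        motif = motif,
        repeat_count = reps,
        kind = "simple",
        member_motifs = sprintf("(%s)%d", motif, reps),
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(runs) == 0L) return(runs)
  runs <- runs[order(runs$start, runs$end), , drop = FALSE]
  merge_compound(runs, max_interruption)
}

empty_ssr_frame <- function() {
  data.frame(sequence_id = character(0), start = integer(0), end = integer(0),
             motif = character(0), repeat_count = integer(0),
             kind = character(0), member_motifs = character(0),
             stringsAsFactors = FALSE)
}

merge_compound <- function(runs, max_interruption) {
  out <- list()
  cur <- runs[1L, , drop = FALSE]
  members <- cur$member_motifs
  for (i in seq_len(nrow(runs))[-1L]) {
    nxt <- runs[i, , drop = FALSE]
    gap <- nxt$start - cur$end - 1L
    if (gap <= max_interruption) {
      members <- c(members, nxt$member_motifs)
      cur$end <- max(cur$end, nxt$end)
      cur$kind <- "compound"
      cur$repeat_count <- NA_integer_
      cur$motif <- NA_character_
      cur$member_motifs <- paste(members, collapse = "-")
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- nxt
      members <- nxt$member_motifs
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mine SSRs from a FASTA file or named sequence vector
#'
#' @param fasta path to a (multi-record) FASTA file, or a named character
#'   vector of sequences.
#' @inheritParams find_ssrs
#' @return Combined per-locus data frame (see [find_ssrs()]) with an
#'   attribute `n_sequences`.
#' @export
mine_ssrs <- function(fasta, thresholds = c(10, 6, 5, 5, 5, 5),
                      max_interruption = 100) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA requires the Biostrings package")
    set <- Biostrings::readDNAStringSet(fasta)
    seqs <- stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
  } else {
    seqs <- fasta
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  hits <- lapply(names(seqs), function(id)
    find_ssrs(seqs[[id]], thresholds, max_interruption, sequence_id = id))
  out <- do.call(rbind, c(list(empty_ssr_frame()), hits))
  rownames(out) <- NULL
  attr(out, "n_sequences") <- length(seqs)
  out
}

#' Summarise a set of SSR records
#'
#' @param records data frame from [find_ssrs()] / [mine_ssrs()].
#' @param n_sequences number of sequences searched (defaults to the
#'   attribute left by [mine_ssrs()]).
#' @return Object of class `"ssr_summary"`: counts of sequences with SSRs,
#'   loci, simple/compound records, counts by motif length, by repeat
#'   number and by canonical motif class, plus `frequency_percent = 100 *
#'   n_loci / n_sequences` (stored at full precision; print rounds to 2
#'   decimals).
#' @export
summarize_ssrs <- function(records, n_sequences = attr(records, "n_sequences")) {
  if (is.null(n_sequences) || n_sequences == 0)
    stop("'n_sequences' must be a positive count")
  n_loci <- nrow(records)
  simple <- records[records$kind == "simple", , drop = FALSE]
  per_seq <- table(factor(records$sequence_id))
  by_len <- table(factor(nchar(simple$motif), levels = 1:6))
  names(by_len) <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  by_reps <- table(simple$repeat_count)
  by_class <- if (nrow(simple)) {
    sort(table(vapply(simple$motif, canonical_motif, character(1))),
         decreasing = TRUE)
  } else table(character(0))
  structure(list(n_sequences = n_sequences,
                 n_sequences_with_ssr = length(per_seq[per_seq > 0]),
                 n_sequences_multi_ssr = sum(per_seq > 1),
                 n_loci = n_loci,
                 n_simple = nrow(simple),
                 n_compound = sum(records$kind == "compound"),
                 by_motif_length = as.list(by_len),
                 by_repeat_number = as.list(by_reps),
                 by_motif_class = as.list(by_class),
                 frequency_percent = 100 * n_loci / n_sequences),
            class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf("SSR summary: %d loci in %d/%d sequences (frequency %.2f%%); %d simple, %d compound\n",
              x$n_loci, x$n_sequences_with_ssr, x$n_sequences,
              round(x$frequency_percent, 2), x$n_simple, x$n_compound))
  invisible(x)
}
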