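#' Map reads to a genome by exact full-length matching
#'
#' A minimal exact-match short-read mapper so the pipeline can run on
#' synthetic (error-free) data without an external aligner; real libraries
#' should be mapped externally and supplied as SAM to [read_alignments()].
#' Every exact occurrence of a read, or of its reverse complement, in the
#' genome is reported (up to `max_report` per read). Reverse-complement hits
#' carry strand `"-"` with coordinates on the forward axis. A read is flagged
#' unique iff it has exactly one occurrence genome-wide (both strands
#' counted). `N` in the genome never matches. Unmapped reads are absent from
#' the output.
#'
#' Matching is batched through [Biostrings::matchPDict()] on constant-width
#' pattern dictionaries, one batch per distinct read length.
#'
#' @param reads A `QualityScaledDNAStringSet`, `DNAStringSet` or character
#'   vector (names become read ids; unnamed reads get `read_<i>`).
#' @param genome A named `DNAStringSet`.
#' @param max_report Maximum alignments reported per read (default 10).
#' @return Alignment data.frame (`read_id`, `replicon_id`, `start`, `end`,
#'   `strand`, `is_unique`), sorted by replicon, start, strand, read id.
#' @export
map_reads <- function(reads, genome, max_report = 10L) {
  stopifnot(max_report >= 1L)
  seqs <- toupper(as.character(reads))
  ids <- names(seqs)
  if (is.null(ids)) ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read_", seq_along(seqs))
  ok <- nchar(seqs) > 0L & grepl("^[ACGT]+$", seqs)
  seqs <- seqs[ok]
  ids <- ids[ok]
  if (length(seqs) == 0L) return(new_alignments())

  useqs <- unique(seqs)
  hits <- find_exact_hits(useqs, genome)
  if (nrow(hits) == 0L) return(new_alignments())

  occ <- tabulate(hits$pattern, nbins = length(useqs))
  hits$is_unique <- occ[hits$pattern] == 1L
  # deterministic order, then cap per pattern
  hits <- hits[order(hits$pattern, hits$replicon_id, hits$start, hits$strand), ,
               drop = FALSE]
  rank_in_pattern <- stats::ave(seq_len(nrow(hits)), hits$pattern,
                                FUN = seq_along)
  hits <- hits[rank_in_pattern <= max_report, , drop = FALSE]

  # expand unique-sequence hits back to individual reads
  pat_of_read <- match(seqs, useqs)
  hit_rows <- split(seq_len(nrow(hits)), hits$pattern)
  rows <- hit_rows[as.character(pat_of_read)]
  n_each <- lengths(rows)
  idx <- unlist(rows, use.names = FALSE)
  aln <- new_alignments(
    read_id = rep(ids, n_each),
    replicon_id = hits$replicon_id[idx],
    start = hits$start[idx],
    end = hits$end[idx],
    strand = hits$strand[idx],
    is_unique = hits$is_unique[idx])
  aln[order(aln$replicon_id, aln$start, aln$strand, aln$read_id), ,
      drop = FALSE]
}

# All exact occurrences of `useqs` (and their reverse complements) in
# `genome`. Returns data.frame(pattern = index into useqs, replicon_id,
# start, end, strand). Variable-width patterns are matched in one pass per
# strand and replicon through a trusted-band PDict anchored on the shortest
# pattern width; tails beyond the band are verified exactly.
find_exact_hits <- function(useqs, genome) {
  widths <- nchar(useqs)
  tb <- min(widths)
  out <- vector("list", 0L)
  fwd <- Biostrings::DNAStringSet(useqs)
  rev <- Biostrings::reverseComplement(fwd)
  for (strand in c("+", "-")) {
    pats <- if (strand == "+") fwd else rev
    pd <- Biostrings::PDict(pats, tb.start = 1L, tb.end = tb)
    for (rid in names(genome)) {
      m <- Biostrings::matchPDict(pd, genome[[rid]], max.mismatch = 0)
      starts <- Biostrings::startIndex(m)
      n_each <- lengths(starts)
      if (sum(n_each) == 0L) next
      st <- unlist(starts, use.names = FALSE)
      pat <- rep(seq_along(useqs), n_each)
      out[[length(out) + 1L]] <- data.frame(
        pattern = pat,
        replicon_id = rid,
        start = st,
        end = st + widths[pat] - 1L,
        strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(pattern = integer(), replicon_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
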