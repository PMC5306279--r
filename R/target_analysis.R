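#' Map an asRNA onto its target's CDS coordinate system
#'
#' Expresses the overlap between a cis-antisense RNA and its target gene in
#' CDS-relative coordinates, where position 1 is the first base of the start
#' codon counted along the target's strand. An asRNA overhanging the CDS is
#' clamped to the CDS boundaries and flagged `fully_contained = FALSE`.
#' The reported `length` is the inclusive span of the overlap.
#'
#' @param asrna A one-row units data.frame (or list with `unit_id`,
#'   `replicon_id`, `strand`, `start`, `end`).
#' @param target A one-length feature `GRanges` (or list with `feature_id`,
#'   `replicon_id`, `strand`, `start`, `end`).
#' @return A list of class `antisense_map`: `asrna_id`, `target_feature_id`,
#'   `cds_start_pos`, `cds_end_pos`, `length`, `fully_contained`.
#' @export
antisense_map <- function(asrna, target) {
  a <- as_interval(asrna, id_field = "unit_id")
  t <- as_interval(target, id_field = "feature_id")
  if (a$replicon_id != t$replicon_id)
    stop("asRNA and target are on different replicons")
  if (a$strand == t$strand)
    stop("asRNA and target must be on opposite strands")
  ov_start <- max(a$start, t$start)
  ov_end <- min(a$end, t$end)
  if (ov_start > ov_end)
    stop("asRNA and target do not overlap")
  # genomic -> CDS-relative, position 1 = first base of the start codon
  if (t$strand == "+") {
    cds_lo <- ov_start - t$start + 1L
    cds_hi <- ov_end - t$start + 1L
  } else {
    cds_lo <- t$end - ov_end + 1L
    cds_hi <- t$end - ov_start + 1L
  }
  structure(list(asrna_id = a$id, target_feature_id = t$id,
                 cds_start_pos = cds_lo, cds_end_pos = cds_hi,
                 length = cds_hi - cds_lo + 1L,
                 fully_contained = a$start >= t$start & a$end <= t$end),
            class = "antisense_map")
}

as_interval <- function(x, id_field) {
  if (methods::is(x, "GRanges")) {
    stopifnot(length(x) == 1L)
    return(list(id = S4Vectors::mcols(x)[[id_field]],
                replicon_id = as.character(GenomeInfoDb::seqnames(x)),
                strand = as.character(BiocGenerics::strand(x)),
                start = BiocGenerics::start(x), end = BiocGenerics::end(x)))
  }
  x <- as.list(x)
  id <- x[[id_field]]
  if (is.null(id)) id <- NA_character_
  list(id = id, replicon_id = x$replicon_id, strand = x$strand,
       start = as.integer(x$start), end = as.integer(x$end))
}

#' Inclusive fragment length between a TSS and a 3' end
#'
#' The RACE arithmetic: the length of a transcript whose 5' end (TSS) and 3'
#' end are both given as genomic positions is the inclusive distance
#' `|end3 - tss| + 1`, regardless of strand orientation.
#'
#' @param tss Genomic position of the transcription start site.
#' @param end3 Genomic position of the 3' end.
#' @return Fragment length in nt (vectorized).
#' @export
fragment_length <- function(tss, end3) {
  abs(as.numeric(end3) - as.numeric(tss)) + 1
}

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
                 R = "AG", Y = "CT", W = "AT", S = "CG", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Scan a sequence for a degenerate IUPAC motif
#'
#' Reports every (possibly overlapping) match of an IUPAC pattern such as
#' the RNase E cleavage consensus `RAUUW` (R = A or G; W = A or U). DNA and
#' RNA input are equivalent: `T` and `U` are identified on both sides.
#'
#' @param seq Sequence to scan (DNA or RNA text, or an `XString`).
#' @param pattern IUPAC pattern over `{A,C,G,T/U,R,Y,W,S,K,M,B,D,H,V,N}`.
#' @param window Optional `c(start, end)` 1-based inclusive interval of
#'   `seq` to scan; hit positions stay relative to the full sequence.
#' @return A data.frame with one row per hit: `position` (1-based) and
#'   `matched` (the matched subsequence, RNA alphabet).
#' @export
scan_motif <- function(seq, pattern, window = NULL) {
  seq <- toupper(as.character(seq))
  seq_dna <- chartr("U", "T", seq)
  pattern <- toupper(chartr("uU", "tT", as.character(pattern)))
  bad <- setdiff(strsplit(pattern, "")[[1]], names(IUPAC_CODES))
  if (length(bad))
    stop("invalid IUPAC code(s) in pattern: ", paste(bad, collapse = ", "))
  offset <- 0L
  scan_to <- nchar(seq_dna)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] >= 1L,
              window[2] <= nchar(seq_dna), window[1] <= window[2])
    offset <- as.integer(window[1]) - 1L
    seq_dna <- substr(seq_dna, window[1], window[2])
  }
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq_dna),
                                   fixed = "subject")
  pos <- BiocGenerics::start(hits) + offset
  matched <- chartr("T", "U", as.character(hits))
  data.frame(position = pos, matched = unname(matched),
             stringsAsFactors = FALSE)
}
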