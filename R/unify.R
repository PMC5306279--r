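#' Unification parameters
#'
#' Controls the merging of near-identical alignments into transcript units.
#' `end_tolerance` is the maximum distance, in nt, allowed between a cluster
#' seed's 5' (and, independently, 3') end and an absorbed alignment's
#' corresponding end — reads "differing by only the addition of several
#' nucleotides at the ends" collapse into one unit. Setting
#' `end_tolerance_3p = Inf` emulates 5'-anchored merging where only the
#' transcription start is required to agree.
#'
#' @param end_tolerance Per-end tolerance in nt (default 5).
#' @param max_unit_length Units longer than this are flagged `oversize`
#'   rather than dropped (default 310 nt, the upper end of the expected
#'   small-RNA size range).
#' @param end_tolerance_3p Tolerance for the 3' end only; defaults to
#'   `end_tolerance`.
#' @return A list of class `unify_params`.
#' @export
unify_params <- function(end_tolerance = 5L, max_unit_length = 310L,
                         end_tolerance_3p = end_tolerance) {
  stopifnot(end_tolerance >= 0, end_tolerance_3p >= 0, max_unit_length >= 1L)
  structure(list(end_tolerance = end_tolerance,
                 end_tolerance_3p = end_tolerance_3p,
                 max_unit_length = as.integer(max_unit_length)),
            class = "unify_params")
}

#' Merge aligned reads into putative transcript units
#'
#' Alignments are partitioned into clusters per (replicon, strand). Distinct
#' intervals are processed in descending multiplicity (number of identical
#' alignments; ties broken by leftmost start, then shortest interval). Each
#' seed absorbs every still-unclustered interval whose 5' end lies within
#' `end_tolerance` of the seed's 5' end and whose 3' end lies within the 3'
#' tolerance of the seed's 3' end. The unit keeps the seed's interval — the
#' most abundant boundary pair, i.e. the putative TSS and terminus — rather
#' than the cluster's min/max span. The ordering rule makes the greedy seed
#' choice canonical, so output is invariant under permutation of the input.
#'
#' @param aln Alignment data.frame (see [read_alignments()]).
#' @param genome A named `DNAStringSet`, used for the representative
#'   sequence (reverse-complemented for `-` strand units).
#' @param params A [unify_params()] object.
#' @param condition Condition label stamped on every unit (e.g. "NL", "HL").
#' @return A data.frame of transcript units with columns `unit_id`,
#'   `replicon_id`, `strand`, `start`, `end`, `length`, `read_count`
#'   (absorbed unique alignments), `total_count` (all absorbed alignments),
#'   `oversize`, `condition`, `representative_sequence`; sorted by replicon,
#'   start, strand.
#' @export
unify <- function(aln, genome, params = unify_params(), condition = "NL") {
  validate_alignments(aln, genome)
  if (nrow(aln) == 0L) return(empty_units())
  groups <- split(seq_len(nrow(aln)),
                  list(aln$replicon_id, aln$strand), drop = TRUE)
  units <- lapply(groups, function(rows) {
    unify_group(aln[rows, , drop = FALSE], params)
  })
  units <- do.call(rbind, units)
  units <- units[order(units$replicon_id, units$start, units$strand), ,
                 drop = FALSE]
  rownames(units) <- NULL
  units$unit_id <- paste0(condition, "_u", seq_len(nrow(units)))
  units$length <- units$end - units$start + 1L
  units$oversize <- units$length > params$max_unit_length
  units$condition <- condition
  rep_seq <- Biostrings::subseq(genome[units$replicon_id],
                                start = units$start, end = units$end)
  neg <- units$strand == "-"
  if (any(neg))
    rep_seq[neg] <- Biostrings::reverseComplement(rep_seq[neg])
  units$representative_sequence <- as.character(rep_seq)
  units[, c("unit_id", "replicon_id", "strand", "start", "end", "length",
            "read_count", "total_count", "oversize", "condition",
            "representative_sequence")]
}

empty_units <- function() {
  data.frame(unit_id = character(), replicon_id = character(),
             strand = character(), start = integer(), end = integer(),
             length = integer(), read_count = integer(),
             total_count = integer(), oversize = logical(),
             condition = character(),
             representative_sequence = character(),
             stringsAsFactors = FALSE)
}

# Greedy clustering of one (replicon, strand) group.
unify_group <- function(aln, params) {
  tol5 <- params$end_tolerance
  tol3 <- params$end_tolerance_3p
  strand <- aln$strand[1L]
  # on the forward coordinate axis the 5' end of a - strand read is `end`
  if (strand == "+") { tol_start <- tol5; tol_end <- tol3 }
  else               { tol_start <- tol3; tol_end <- tol5 }

  key <- paste(aln$start, aln$end)
  agg <- stats::aggregate(
    cbind(total = rep(1L, nrow(aln)), uniq = as.integer(aln$is_unique)),
    by = list(start = aln$start, end = aln$end), FUN = sum)
  agg <- agg[order(-agg$total, agg$start, agg$end - agg$start), , drop = FALSE]
  n <- nrow(agg)
  by_start <- order(agg$start)
  starts_sorted <- agg$start[by_start]
  cluster <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    s <- agg$start[i]; e <- agg$end[i]
    lo <- findInterval(s - tol_start - 0.5, starts_sorted) + 1L
    hi <- findInterval(s + tol_start + 0.5, starts_sorted)
    if (hi < lo) next
    cand <- by_start[lo:hi]
    cand <- cand[is.na(cluster[cand]) & abs(agg$end[cand] - e) <= tol_end]
    cluster[cand] <- i
  }
  seeds <- sort(unique(cluster))
  total <- vapply(seeds, function(i) sum(agg$total[cluster == i]), integer(1))
  uniq <- vapply(seeds, function(i) sum(agg$uniq[cluster == i]), integer(1))
  data.frame(replicon_id = aln$replicon_id[1L], strand = strand,
             start = agg$start[seeds], end = agg$end[seeds],
             read_count = uniq, total_count = total,
             stringsAsFactors = FALSE)
}

#' Write transcript units to TSV or GFF3
#'
#' GFF3 output uses feature type `transcript_unit` with `read_count`,
#' `total_count` and `condition` attributes. Rows are sorted by replicon,
#' start, strand.
#'
#' @param units Units data.frame from [unify()].
#' @param path Output path.
#' @param format `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_units <- function(units, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  units <- units[order(units$replicon_id, units$start, units$strand), ,
                 drop = FALSE]
  if (format == "tsv") {
    utils::write.table(units, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- c("##gff-version 3", paste(
      units$replicon_id, "srnapipe", "transcript_unit",
      units$start, units$end, units$total_count, units$strand, ".",
      paste0("ID=", units$unit_id, ";read_count=", units$read_count,
             ";total_count=", units$total_count,
             ";condition=", units$condition),
      sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}
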