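#' Classification parameters
#'
#' @param upstream_window Width in nt of the 5' leader window immediately
#'   upstream of an annotated gene start (default 300).
#' @param min_unique_reads Candidate filter: minimum uniquely aligned reads
#'   per unit (default 10, inclusive).
#' @param sense_overlap_min_frac Fraction of the unit's length that must lie
#'   inside a same-strand ORF for the unit to be called ORF (default 0.5);
#'   antisense overlap needs only 1 nt.
#' @param lr5_strict Require the unit to be fully contained in the upstream
#'   window for an LR5 call (default `FALSE`: any intersection suffices).
#' @return A list of class `classify_params`.
#' @export
classify_params <- function(upstream_window = 300L, min_unique_reads = 10L,
                            sense_overlap_min_frac = 0.5,
                            lr5_strict = FALSE) {
  stopifnot(upstream_window >= 0L, min_unique_reads >= 1L,
            sense_overlap_min_frac > 0, sense_overlap_min_frac <= 1)
  structure(list(upstream_window = as.integer(upstream_window),
                 min_unique_reads = as.integer(min_unique_reads),
                 sense_overlap_min_frac = sense_overlap_min_frac,
                 lr5_strict = lr5_strict),
            class = "classify_params")
}

units_granges <- function(units) {
  GenomicRanges::GRanges(
    seqnames = units$replicon_id,
    ranges = IRanges::IRanges(start = units$start, end = units$end),
    strand = units$strand)
}

#' Upstream (5' leader) windows of annotated genes
#'
#' The window covers the `width` nt immediately 5' of the gene start on the
#' gene's own strand: `[start - width, start - 1]` for `+` genes and
#' `[end + 1, end + width]` for `-` genes, truncated at position 1 (windows
#' running past a replicon end are not truncated here; overlap queries are
#' unaffected).
#'
#' @param features Feature `GRanges` (only `kind == "ORF"` rows are used).
#' @param width Window width in nt.
#' @return A `GRanges` parallel to the ORF subset of `features`, with
#'   `feature_id` carried over.
#' @export
upstream_windows <- function(features, width = 300L) {
  orf <- features[features$kind == "ORF"]
  if (length(orf) == 0L || width == 0L)
    return(GenomicRanges::GRanges(feature_id = character()))
  plus <- as.character(BiocGenerics::strand(orf)) == "+"
  ws <- ifelse(plus, BiocGenerics::start(orf) - width, BiocGenerics::end(orf) + 1L)
  we <- ifelse(plus, BiocGenerics::start(orf) - 1L, BiocGenerics::end(orf) + width)
  ws <- pmax(ws, 1L)
  keep <- ws <= we
  GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(orf)[keep],
    ranges = IRanges::IRanges(start = ws[keep], end = we[keep]),
    strand = BiocGenerics::strand(orf)[keep],
    feature_id = orf$feature_id[keep])
}

#' Assign each transcript unit a genomic-context category
#'
#' Categories are resolved by the first matching rule, in priority order:
#' \enumerate{
#'   \item overlaps an rRNA feature on either strand -> `rRNA`;
#'   \item overlaps a tRNA feature on either strand -> `tRNA`;
#'   \item overlaps a same-strand ORF by at least
#'     `sense_overlap_min_frac` of the unit's length -> `ORF`;
#'   \item overlaps an opposite-strand ORF by >= 1 nt -> `AS`, associated
#'     with the maximal-overlap ORF (ties: leftmost feature start);
#'   \item intersects the `upstream_window` nt immediately 5' of a
#'     same-strand gene start -> `LR5`, associated with that gene
#'     (maximal window overlap, ties: leftmost feature start);
#'   \item otherwise -> `IGR`.
#' }
#' Structural-RNA contamination therefore dominates (rules 1–2), and
#' antisense outranks intergenic so asRNAs that only partially overlap an
#' ORF are not lost.
#'
#' @param units Units data.frame from [unify()].
#' @param features Feature `GRanges` from [read_annotation()].
#' @param params A [classify_params()] object.
#' @return `units` with added columns `category` (one of rRNA, tRNA, ORF,
#'   AS, IGR, LR5) and `associated_feature_id` (`NA` unless AS or LR5).
#' @export
classify_units <- function(units, features, params = classify_params()) {
  n <- nrow(units)
  units$category <- rep("IGR", n)
  units$associated_feature_id <- rep(NA_character_, n)
  if (n == 0L || length(features) == 0L) return(units)
  u <- units_granges(units)
  unassigned <- rep(TRUE, n)

  for (kind in c("rRNA", "tRNA")) {
    f <- features[features$kind == kind]
    if (length(f)) {
      hit <- IRanges::overlapsAny(u, f, ignore.strand = TRUE)
      units$category[unassigned & hit] <- kind
      unassigned <- unassigned & !hit
    }
  }

  orf <- features[features$kind == "ORF"]
  if (length(orf)) {
    ov <- GenomicRanges::findOverlaps(u, orf, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- BiocGenerics::width(IRanges::pintersect(
      IRanges::ranges(u)[qh], IRanges::ranges(orf)[sh]))
    same <- as.character(BiocGenerics::strand(u))[qh] ==
      as.character(BiocGenerics::strand(orf))[sh]

    # rule 3: sense ORF by fraction of the unit
    sense <- same & w >= params$sense_overlap_min_frac *
      BiocGenerics::width(u)[qh]
    hit3 <- unique(qh[sense])
    sel3 <- unassigned[hit3]
    units$category[hit3[sel3]] <- "ORF"
    unassigned[hit3[sel3]] <- FALSE

    # rule 4: antisense ORF, best overlap wins
    anti <- !same
    if (any(anti)) {
      aq <- qh[anti]; as_ <- sh[anti]; aw <- w[anti]
      keep <- unassigned[aq]
      aq <- aq[keep]; as_ <- as_[keep]; aw <- aw[keep]
      if (length(aq)) {
        o <- order(aq, -aw, BiocGenerics::start(orf)[as_])
        first <- !duplicated(aq[o])
        best_q <- aq[o][first]; best_s <- as_[o][first]
        units$category[best_q] <- "AS"
        units$associated_feature_id[best_q] <- orf$feature_id[best_s]
        unassigned[best_q] <- FALSE
      }
    }
  }

  # rule 5: 5' leader window, same strand
  win <- upstream_windows(features, params$upstream_window)
  if (length(win)) {
    type <- if (params$lr5_strict) "within" else "any"
    ov <- GenomicRanges::findOverlaps(u, win, type = type,
                                      ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    keep <- unassigned[qh]
    qh <- qh[keep]; sh <- sh[keep]
    if (length(qh)) {
      w <- BiocGenerics::width(IRanges::pintersect(
        IRanges::ranges(u)[qh], IRanges::ranges(win)[sh]))
      o <- order(qh, -w, BiocGenerics::start(win)[sh])
      first <- !duplicated(qh[o])
      best_q <- qh[o][first]; best_s <- sh[o][first]
      units$category[best_q] <- "LR5"
      units$associated_feature_id[best_q] <- win$feature_id[best_s]
      unassigned[best_q] <- FALSE
    }
  }
  units
}

#' Classify a single unit
#'
#' @param unit A one-row units data.frame.
#' @inheritParams classify_units
#' @return A list with `category` and `associated_feature_id`.
#' @export
classify_unit <- function(unit, features, params = classify_params()) {
  stopifnot(nrow(unit) == 1L)
  res <- classify_units(unit, features, params)
  list(category = res$category, associated_feature_id = res$associated_feature_id)
}

srna_class_map <- c(AS = "asRNA", IGR = "IGR", LR5 = "LR5")

#' Apply the sRNA candidate filter
#'
#' Keeps classified units in the three sRNA classes (antisense, intergenic,
#' 5' leader) that are supported by at least `min_unique_reads` uniquely
#' aligned reads (inclusive threshold).
#'
#' @param units Classified units data.frame from [classify_units()].
#' @param params A [classify_params()] object.
#' @return The surviving rows with an added `srna_class` column
#'   (`asRNA`, `IGR` or `LR5`).
#' @export
filter_candidates <- function(units, params = classify_params()) {
  stopifnot("category" %in% names(units))
  keep <- units$category %in% names(srna_class_map) &
    units$read_count >= params$min_unique_reads
  out <- units[keep, , drop = FALSE]
  out$srna_class <- unname(srna_class_map[out$category])
  rownames(out) <- NULL
  out
}

#' Breakdown of units and reads by genomic-context category
#'
#' @param units Classified units data.frame.
#' @return A data.frame with one row per category present: `category`,
#'   `n_units`, `total_reads` (summed `total_count`) and `pct_reads`
#'   (percentage of all reads; sums to 100 within rounding).
#' @export
category_breakdown <- function(units) {
  stopifnot("category" %in% names(units))
  if (nrow(units) == 0L)
    return(data.frame(category = character(), n_units = integer(),
                      total_reads = integer(), pct_reads = numeric(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(
    cbind(n_units = rep(1L, nrow(units)), total_reads = units$total_count),
    by = list(category = units$category), FUN = sum)
  agg$pct_reads <- 100 * agg$total_reads / sum(agg$total_reads)
  agg[order(-agg$total_reads), , drop = FALSE]
}

#' Write sRNA candidates to GFF3 or TSV
#'
#' GFF3 rows use type `ncRNA` with `class` and `target` attributes.
#'
#' @param candidates Candidate data.frame from [filter_candidates()].
#' @param path Output path.
#' @param format `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  candidates <- candidates[order(candidates$replicon_id, candidates$start,
                                 candidates$strand), , drop = FALSE]
  if (format == "tsv") {
    utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    target <- ifelse(is.na(candidates$associated_feature_id), "",
                     paste0(";target=", candidates$associated_feature_id))
    lines <- c("##gff-version 3", paste(
      candidates$replicon_id, "srnapipe", "ncRNA",
      candidates$start, candidates$end, candidates$read_count,
      candidates$strand, ".",
      paste0("ID=", candidates$unit_id, ";class=", candidates$srna_class,
             target),
      sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}
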