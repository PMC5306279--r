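#' Differential-filter parameters
#'
#' The two-condition differential call uses three thresholds: a matched pair
#' must share >= `min_overlap_frac` of the shorter unit's length, the
#' HL-over-NL read ratio must reach `min_ratio` (up) or fall below its
#' reciprocal (down), and the better-supported side must carry at least
#' `min_reads` uniquely aligned reads.
#'
#' @param min_overlap_frac Minimum interval overlap as a fraction of the
#'   shorter unit (default 0.10, inclusive).
#' @param min_ratio Minimum fold change (default 2, inclusive both ways).
#' @param min_reads Minimum unique-read support under either condition
#'   (default 10, inclusive).
#' @param normalize Use counts per million unique mapped reads instead of
#'   raw counts (default `FALSE`; raw counts match threshold-style filters
#'   on libraries of comparable depth).
#' @param reciprocal_overlap Require the overlap fraction against both
#'   units' lengths, not just the shorter (default `FALSE`).
#' @return A list of class `diff_params`.
#' @export
diff_params <- function(min_overlap_frac = 0.10, min_ratio = 2,
                        min_reads = 10L, normalize = FALSE,
                        reciprocal_overlap = FALSE) {
  stopifnot(min_overlap_frac > 0, min_overlap_frac <= 1, min_ratio >= 1,
            min_reads >= 0L)
  structure(list(min_overlap_frac = min_overlap_frac, min_ratio = min_ratio,
                 min_reads = as.integer(min_reads), normalize = normalize,
                 reciprocal_overlap = reciprocal_overlap),
            class = "diff_params")
}

#' Match candidate units across the two condition libraries
#'
#' Candidate pairs must lie on the same replicon and strand and overlap by at
#' least `min_overlap_frac` of the shorter unit's length. Matching is greedy
#' one-to-one in descending overlap fraction (ties: larger summed read
#' counts, then leftmost pair), so each unit contributes to at most one
#' differential call.
#'
#' @param nl,hl Candidate data.frames (see [filter_candidates()]) for the
#'   two conditions.
#' @param params A [diff_params()] object.
#' @return A list with `pairs` (data.frame: `nl_unit_id`, `hl_unit_id`,
#'   `overlap_frac`), `unmatched_nl` and `unmatched_hl` (unit id vectors).
#' @export
match_units <- function(nl, hl, params = diff_params()) {
  empty <- data.frame(nl_unit_id = character(), hl_unit_id = character(),
                      overlap_frac = numeric(), stringsAsFactors = FALSE)
  if (nrow(nl) == 0L || nrow(hl) == 0L)
    return(list(pairs = empty, unmatched_nl = nl$unit_id,
                unmatched_hl = hl$unit_id))
  ov <- GenomicRanges::findOverlaps(units_granges(nl), units_granges(hl),
                                    ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (length(qh) == 0L)
    return(list(pairs = empty, unmatched_nl = nl$unit_id,
                unmatched_hl = hl$unit_id))
  inter <- pmin(nl$end[qh], hl$end[sh]) - pmax(nl$start[qh], hl$start[sh]) + 1L
  denom <- if (params$reciprocal_overlap) pmax(nl$length[qh], hl$length[sh])
           else pmin(nl$length[qh], hl$length[sh])
  frac <- inter / denom
  keep <- frac >= params$min_overlap_frac
  qh <- qh[keep]; sh <- sh[keep]; frac <- frac[keep]
  sum_counts <- nl$read_count[qh] + hl$read_count[sh]
  o <- order(-frac, -sum_counts, pmin(nl$start[qh], hl$start[sh]), qh, sh)
  used_nl <- logical(nrow(nl)); used_hl <- logical(nrow(hl))
  pick <- logical(length(o))
  for (k in o) {
    if (!used_nl[qh[k]] && !used_hl[sh[k]]) {
      pick[k] <- TRUE
      used_nl[qh[k]] <- TRUE
      used_hl[sh[k]] <- TRUE
    }
  }
  pairs <- data.frame(nl_unit_id = nl$unit_id[qh[pick]],
                      hl_unit_id = hl$unit_id[sh[pick]],
                      overlap_frac = frac[pick], stringsAsFactors = FALSE)
  list(pairs = pairs,
       unmatched_nl = nl$unit_id[!used_nl],
       unmatched_hl = hl$unit_id[!used_hl])
}

#' Call differential status for matched pairs and library-unique units
#'
#' Effective counts are uniquely aligned reads (or counts per million unique
#' mapped reads when `params$normalize` is set). A singleton with at least
#' `min_reads` support is `unique_NL` / `unique_HL`; below the threshold it
#' is dropped (reported with status `dropped` when `keep_dropped = TRUE`).
#' For a matched pair, if neither side reaches `min_reads` the pair is
#' dropped; otherwise the ratio HL/NL calls `up` (ratio >= `min_ratio`),
#' `down` (ratio <= 1/`min_ratio`) or `unchanged`. A matched unit with zero
#' reads on one side is treated as unique to the other library rather than
#' as an infinite ratio.
#'
#' @param nl,hl Candidate data.frames for the two conditions.
#' @param params A [diff_params()] object.
#' @param nl_mapped,hl_mapped Library sizes (unique mapped reads) used when
#'   `normalize = TRUE`; default: sum of candidate read counts.
#' @param keep_dropped Keep sub-threshold calls with status `"dropped"`
#'   instead of removing them (default `FALSE`).
#' @return A data.frame of calls: `nl_unit_id`, `hl_unit_id`, `replicon_id`,
#'   `strand`, `start`, `end`, `srna_class`, `nl_count`, `hl_count`,
#'   `overlap_frac`, `ratio`, `status`.
#' @export
diff_calls <- function(nl, hl, params = diff_params(),
                       nl_mapped = NULL, hl_mapped = NULL,
                       keep_dropped = FALSE) {
  m <- match_units(nl, hl, params)
  nl_i <- match(m$pairs$nl_unit_id, nl$unit_id)
  hl_i <- match(m$pairs$hl_unit_id, hl$unit_id)
  scale_nl <- scale_hl <- 1
  if (params$normalize) {
    if (is.null(nl_mapped)) nl_mapped <- sum(nl$read_count)
    if (is.null(hl_mapped)) hl_mapped <- sum(hl$read_count)
    scale_nl <- 1e6 / nl_mapped
    scale_hl <- 1e6 / hl_mapped
  }
  rows <- list()

  if (nrow(m$pairs)) {
    cn <- nl$read_count[nl_i] * scale_nl
    ch <- hl$read_count[hl_i] * scale_hl
    ratio <- ifelse(cn > 0, ch / cn, NA_real_)
    status <- rep("unchanged", length(cn))
    status[!is.na(ratio) & ratio >= params$min_ratio] <- "up"
    status[!is.na(ratio) & ratio <= 1 / params$min_ratio] <- "down"
    status[cn == 0 & ch > 0] <- "unique_HL"
    status[ch == 0 & cn > 0] <- "unique_NL"
    status[pmax(cn, ch) < params$min_reads] <- "dropped"
    rows$pairs <- data.frame(
      nl_unit_id = m$pairs$nl_unit_id, hl_unit_id = m$pairs$hl_unit_id,
      replicon_id = nl$replicon_id[nl_i], strand = nl$strand[nl_i],
      start = pmin(nl$start[nl_i], hl$start[hl_i]),
      end = pmax(nl$end[nl_i], hl$end[hl_i]),
      srna_class = nl$srna_class[nl_i],
      nl_count = cn, hl_count = ch,
      overlap_frac = m$pairs$overlap_frac, ratio = ratio, status = status,
      stringsAsFactors = FALSE)
  }
  singleton <- function(cand, ids, side, scale) {
    i <- match(ids, cand$unit_id)
    if (length(i) == 0L) return(NULL)
    cnt <- cand$read_count[i] * scale
    status <- ifelse(cnt >= params$min_reads,
                     paste0("unique_", side), "dropped")
    data.frame(
      nl_unit_id = if (side == "NL") cand$unit_id[i] else NA_character_,
      hl_unit_id = if (side == "HL") cand$unit_id[i] else NA_character_,
      replicon_id = cand$replicon_id[i], strand = cand$strand[i],
      start = cand$start[i], end = cand$end[i],
      srna_class = cand$srna_class[i],
      nl_count = if (side == "NL") cnt else 0,
      hl_count = if (side == "HL") cnt else 0,
      overlap_frac = NA_real_, ratio = NA_real_, status = status,
      stringsAsFactors = FALSE)
  }
  rows$nl <- singleton(nl, m$unmatched_nl, "NL", scale_nl)
  rows$hl <- singleton(hl, m$unmatched_hl, "HL", scale_hl)
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(calls)) {
    calls <- data.frame(nl_unit_id = character(), hl_unit_id = character(),
                        replicon_id = character(), strand = character(),
                        start = integer(), end = integer(),
                        srna_class = character(), nl_count = numeric(),
                        hl_count = numeric(), overlap_frac = numeric(),
                        ratio = numeric(), status = character(),
                        stringsAsFactors = FALSE)
  }
  if (!keep_dropped)
    calls <- calls[calls$status != "dropped", , drop = FALSE]
  calls <- calls[order(calls$replicon_id, calls$start, calls$strand), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Summarize differential calls by status
#'
#' @param calls Calls data.frame from [diff_calls()].
#' @return A list with `overall` (data.frame status/count) and `by_class`
#'   (data.frame status x srna_class counts).
#' @export
diff_summary <- function(calls) {
  statuses <- c("up", "down", "unchanged", "unique_NL", "unique_HL")
  if (nrow(calls) == 0L)
    return(list(overall = data.frame(status = character(), n = integer(),
                                     stringsAsFactors = FALSE),
                by_class = data.frame(status = character(),
                                      srna_class = character(), n = integer(),
                                      stringsAsFactors = FALSE)))
  keep <- calls$status %in% statuses
  calls <- calls[keep, , drop = FALSE]
  overall <- as.data.frame(table(status = calls$status),
                           stringsAsFactors = FALSE)
  names(overall) <- c("status", "n")
  by_class <- as.data.frame(table(status = calls$status,
                                  srna_class = calls$srna_class),
                            stringsAsFactors = FALSE)
  names(by_class) <- c("status", "srna_class", "n")
  list(overall = overall, by_class = by_class)
}
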