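#' Preprocessing parameters
#'
#' Read-level filters applied after 3' adapter trimming. Defaults follow the
#' usual small-RNA screening rules: reads shorter than 18 nt are discarded as
#' "short", and reads with mean Phred quality below 20 as "low_quality".
#' `max_length` bounds transcript units (gel size selection acts upstream of
#' sequencing), not reads; it is carried here so one object describes the
#' size regime of the experiment.
#'
#' @param adapter_3p 3' adapter sequence (DNA text), required for trimming.
#' @param min_length Minimum kept read length in nt (default 18).
#' @param min_mean_phred Minimum mean Phred score (default 20).
#' @param max_length Maximum transcript size selected for sequencing
#'   (default 200 nt).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(adapter_3p = NULL, min_length = 18L,
                              min_mean_phred = 20, max_length = 200L) {
  stopifnot(min_length >= 1L, min_mean_phred >= 0, min_mean_phred <= 60,
            max_length >= min_length)
  if (!is.null(adapter_3p)) {
    adapter_3p <- toupper(adapter_3p)
    stopifnot(nchar(adapter_3p) >= 1L,
              grepl("^[ACGTN]+$", adapter_3p))
  }
  structure(list(adapter_3p = adapter_3p,
                 min_length = as.integer(min_length),
                 min_mean_phred = min_mean_phred,
                 max_length = as.integer(max_length)),
            class = "preprocess_params")
}

#' Trim the 3' adapter from reads
#'
#' Each read is truncated at the leftmost position where the adapter matches
#' exactly: either the full adapter occurs (anything 3' of it, adapter
#' included, is removed) or a prefix of the adapter of at least `min_match`
#' nt runs off the read's 3' end. Matching is exact; reads without a match
#' are returned unchanged. Qualities are truncated in lockstep.
#'
#' @param reads A `QualityScaledDNAStringSet` (or plain `DNAStringSet` /
#'   character vector, returned in kind).
#' @param adapter_3p Adapter sequence, DNA text.
#' @param min_match Minimum adapter prefix length to accept at the 3' end
#'   (default 5).
#' @return Trimmed reads of the same class as the input. Reads trimmed to
#'   length zero are kept (they are removed later by [filter_reads()]).
#' @export
trim_adapter <- function(reads, adapter_3p, min_match = 5L) {
  stopifnot(!is.null(adapter_3p), nchar(adapter_3p) >= 1L)
  adapter_3p <- toupper(adapter_3p)
  seqs <- as.character(reads)
  len <- nchar(seqs)
  alen <- nchar(adapter_3p)
  # leftmost full-adapter occurrence
  cut <- regexpr(adapter_3p, seqs, fixed = TRUE)
  cut[cut < 0L] <- NA_integer_
  # longest adapter prefix (>= min_match) running off the 3' end; the longest
  # prefix corresponds to the leftmost suffix position, so scan long -> short
  # and keep the first (smallest) position found
  suffix_cut <- rep(NA_integer_, length(seqs))
  if (alen - 1L >= min_match) {
    for (m in seq(alen - 1L, min_match)) {
      p <- len - m + 1L
      ok <- is.na(suffix_cut) & p >= 1L &
        substr(seqs, p, len) == substr(adapter_3p, 1L, m)
      suffix_cut[ok] <- p[ok]
    }
  }
  cut <- pmin(cut, suffix_cut, na.rm = TRUE)
  keep_to <- ifelse(is.na(cut), len, cut - 1L)
  if (is.character(reads))
    return(substr(seqs, 1L, keep_to))
  try(S4Vectors::mcols(reads) <- NULL, silent = TRUE)
  Biostrings::subseq(reads, start = 1L, end = as.integer(keep_to))
}

#' Filter adapter-trimmed reads by length and mean quality
#'
#' Keeps reads with length >= `min_length` and mean Phred >= `min_mean_phred`.
#' Rejections are counted by reason with precedence short -> low_quality, so
#' the report partitions the input exactly: `total == kept + short +
#' low_quality`.
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param params A [preprocess_params()] object.
#' @return A list with `kept` (the surviving reads) and `report` (named
#'   integer vector: total, kept, short, low_quality).
#' @export
filter_reads <- function(reads, params = preprocess_params()) {
  stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
  n <- length(reads)
  if (n == 0L)
    return(list(kept = reads,
                report = c(total = 0L, kept = 0L, short = 0L,
                           low_quality = 0L)))
  len <- BiocGenerics::width(reads)
  qual <- methods::as(Biostrings::quality(reads), "IntegerList")
  mean_q <- ifelse(len > 0L, sum(qual) / pmax(len, 1L), 0)
  short <- len < params$min_length
  lowq <- !short & mean_q < params$min_mean_phred
  kept <- !short & !lowq
  list(kept = reads[kept],
       report = c(total = n, kept = sum(kept), short = sum(short),
                  low_quality = sum(lowq)))
}

#' Trim adapters then apply read filters
#'
#' Convenience wrapper: [trim_adapter()] (when `params$adapter_3p` is set)
#' followed by [filter_reads()].
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param params A [preprocess_params()] object.
#' @return As [filter_reads()].
#' @export
preprocess_reads <- function(reads, params) {
  if (!is.null(params$adapter_3p))
    reads <- trim_adapter(reads, params$adapter_3p)
  filter_reads(reads, params)
}
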