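#' Run the full two-condition sRNA discovery pipeline
#'
#' FASTQ to differential calls: adapter trimming and read filters
#' ([preprocess_reads()]), exact-match mapping ([map_reads()]) with a SAM
#' round trip through [write_sam()]/[read_alignments()], unification into
#' transcript units ([unify()]), genomic-context classification and the
#' candidate filter ([classify_units()], [filter_candidates()]),
#' cross-condition matching and differential status calls ([diff_calls()]),
#' and the descriptive statistics ([fit_length_distribution()],
#' [replicon_breakdown()], [category_breakdown()]).
#'
#' Real libraries mapped with an external aligner can be supplied as SAM via
#' `alignments_nl` / `alignments_hl`, in which case the FASTQ arguments and
#' the internal mapper are skipped.
#'
#' @param genome_fasta Path to the genome FASTA (or a `DNAStringSet`).
#' @param annotation_gff3 Path to the annotation GFF3 (or a feature
#'   `GRanges`).
#' @param fastq_nl,fastq_hl Paths to the condition libraries (or
#'   `QualityScaledDNAStringSet` objects).
#' @param adapter_3p 3' adapter sequence; `NULL` skips trimming.
#' @param pre,uni,cls,dif Parameter objects ([preprocess_params()],
#'   [unify_params()], [classify_params()], [diff_params()]).
#' @param alignments_nl,alignments_hl Optional paths to pre-mapped SAM/BED
#'   files, bypassing preprocessing and mapping.
#' @param workdir Directory for intermediate SAM files (default: a
#'   tempdir).
#' @param max_report Mapper cap on alignments per read.
#' @return A list: `genome`, `features`, per-condition `preprocess` reports,
#'   `units`, `candidates`, the differential `calls`, and `summary`
#'   (category breakdowns, differential summary, length fits, replicon
#'   breakdowns).
#' @export
run_pipeline <- function(genome_fasta, annotation_gff3,
                         fastq_nl = NULL, fastq_hl = NULL,
                         adapter_3p = NULL,
                         pre = preprocess_params(adapter_3p = adapter_3p),
                         uni = unify_params(),
                         cls = classify_params(),
                         dif = diff_params(),
                         alignments_nl = NULL, alignments_hl = NULL,
                         workdir = tempfile("srnapipe_"),
                         max_report = 10L) {
  genome <- if (methods::is(genome_fasta, "DNAStringSet")) genome_fasta
            else read_genome(genome_fasta)
  features <- if (methods::is(annotation_gff3, "GRanges")) annotation_gff3
              else read_annotation(annotation_gff3, genome)
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)

  one_condition <- function(fastq, sam_in, cond) {
    report <- NULL
    if (is.null(sam_in)) {
      reads <- if (methods::is(fastq, "QualityScaledDNAStringSet")) fastq
               else read_fastq(fastq)
      pp <- preprocess_reads(reads, pre)
      report <- pp$report
      aln <- map_reads(pp$kept, genome, max_report = max_report)
      sam <- file.path(workdir, paste0(cond, ".sam"))
      write_sam(aln, genome, sam)
      aln <- read_alignments(sam, genome)
    } else {
      aln <- read_alignments(sam_in, genome)
    }
    units <- unify(aln, genome, uni, condition = cond)
    units <- classify_units(units, features, cls)
    cands <- filter_candidates(units, cls)
    list(report = report, alignments = aln, units = units,
         candidates = cands)
  }
  nl <- one_condition(fastq_nl, alignments_nl, "NL")
  hl <- one_condition(fastq_hl, alignments_hl, "HL")

  calls <- diff_calls(nl$candidates, hl$candidates, dif,
                      nl_mapped = sum(nl$alignments$is_unique),
                      hl_mapped = sum(hl$alignments$is_unique))
  fit <- function(cands) {
    if (nrow(cands) >= 2L) fit_length_distribution(cands) else NULL
  }
  list(genome = genome, features = features,
       preprocess = list(NL = nl$report, HL = hl$report),
       alignments = list(NL = nl$alignments, HL = hl$alignments),
       units = list(NL = nl$units, HL = hl$units),
       candidates = list(NL = nl$candidates, HL = hl$candidates),
       calls = calls,
       summary = list(
         category_breakdown = list(NL = category_breakdown(nl$units),
                                   HL = category_breakdown(hl$units)),
         diff = diff_summary(calls),
         length_fit = list(NL = fit(nl$candidates),
                           HL = fit(hl$candidates)),
         replicon_breakdown = list(
           NL = replicon_breakdown(nl$candidates, genome),
           HL = replicon_breakdown(hl$candidates, genome))))
}

reciprocal_overlap_match <- function(query, subject, min_frac = 0.9) {
  # index into `subject` of the best reciprocal-overlap match per query row,
  # NA where nothing reaches min_frac; same replicon and strand required
  out <- rep(NA_integer_, nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(out)
  ov <- GenomicRanges::findOverlaps(units_granges(query),
                                    units_granges(subject),
                                    ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (length(qh) == 0L) return(out)
  inter <- pmin(query$end[qh], subject$end[sh]) -
    pmax(query$start[qh], subject$start[sh]) + 1L
  frac <- inter / pmax(query$end[qh] - query$start[qh] + 1L,
                       subject$end[sh] - subject$start[sh] + 1L)
  keep <- frac >= min_frac
  qh <- qh[keep]; sh <- sh[keep]; frac <- frac[keep]
  o <- order(qh, -frac)
  first <- !duplicated(qh[o])
  out[qh[o][first]] <- sh[o][first]
  out
}

#' Score pipeline output against a scenario's truth manifest
#'
#' Compares what the pipeline recovered with what the generator planted:
#' unit-recovery recall (a planted unit counts as recovered when some unit
#' in that library matches it at reciprocal overlap >= `min_overlap`, same
#' replicon and strand), classification accuracy on the recovered units,
#' and the differential-status confusion matrix over planted units that
#' meet the candidate read filter.
#'
#' @param result Output of [run_pipeline()] on the generated scenario.
#' @param manifest Truth manifest from [generate_scenario()].
#' @param min_overlap Reciprocal-overlap threshold for matching (default
#'   0.9).
#' @param min_reads Read filter that planted units must meet to be expected
#'   in the candidate set (default 10).
#' @return A list: `unit_recall` (named NL/HL), `class_accuracy`,
#'   `de_confusion` (table planted x called), `de_accuracy`.
#' @export
evaluate_against_truth <- function(result, manifest, min_overlap = 0.9,
                                   min_reads = 10L) {
  truth <- manifest$units
  class_to_category <- c(asRNA = "AS", IGR = "IGR", LR5 = "LR5")

  recall <- c(NL = NA_real_, HL = NA_real_)
  class_ok <- integer(0); class_n <- 0L
  for (lib in c("NL", "HL")) {
    cnt <- if (lib == "NL") truth$nl_count else truth$hl_count
    expected <- truth[cnt >= min_reads, , drop = FALSE]
    if (nrow(expected) == 0L) next
    units <- result$units[[lib]]
    m <- reciprocal_overlap_match(expected, units, min_overlap)
    recall[[lib]] <- mean(!is.na(m))
    hit <- !is.na(m)
    class_ok <- c(class_ok,
                  units$category[m[hit]] ==
                    unname(class_to_category[expected$class[hit]]))
    class_n <- class_n + sum(hit)
  }
  class_accuracy <- if (class_n > 0L) mean(class_ok) else NA_real_

  ## differential statuses: planted truth vs calls
  expected <- truth[pmax(truth$nl_count, truth$hl_count) >= min_reads, ,
                    drop = FALSE]
  calls <- result$calls
  m <- reciprocal_overlap_match(expected, calls, min_overlap)
  called <- ifelse(is.na(m), "missed", calls$status[m])
  de_confusion <- table(planted = expected$status, called = called)
  de_accuracy <- mean(called == expected$status)
  list(unit_recall = recall, class_accuracy = class_accuracy,
       de_confusion = de_confusion, de_accuracy = de_accuracy)
}
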