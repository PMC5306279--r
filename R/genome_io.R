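#' Read a multi-replicon genome from FASTA
#'
#' Loads a reference genome (chromosome plus any plasmids) into a
#' [Biostrings::DNAStringSet]. Residues are upper-cased and `U` is mapped to
#' `T`, so RNA-alphabet records are accepted. Record ids are taken as the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file with one record per replicon.
#' @return A `DNAStringSet` named by replicon id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr", "ACGT"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  genome <- Biostrings::readBStringSet(path)
  if (length(genome) == 0L)
    stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(ids))
    stop("duplicate replicon ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("u", "t", toupper(as.character(genome)))
  seqs <- chartr("U", "T", seqs)
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- ids
  genome
}

#' Write a genome to FASTA
#'
#' @param genome A named `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(methods::is(genome, "DNAStringSet"), !is.null(names(genome)))
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Classify replicons as chromosome or plasmid
#'
#' By convention the longest replicon is the chromosome and all others are
#' plasmids, unless the replicon id itself says otherwise (contains
#' "plasmid"/"pSYS" or "chr", case-insensitively).
#'
#' @param genome A named `DNAStringSet`.
#' @return Named character vector, values `"chromosome"` or `"plasmid"`.
#' @export
replicon_kinds <- function(genome) {
  ids <- names(genome)
  kind <- rep(NA_character_, length(ids))
  kind[grepl("plasmid|^pSYS", ids, ignore.case = TRUE)] <- "plasmid"
  kind[grepl("chr", ids, ignore.case = TRUE)] <- "chromosome"
  if (anyNA(kind)) {
    # longest undecided replicon is the chromosome unless one is already named
    if (!"chromosome" %in% kind) {
      longest <- which.max(BiocGenerics::width(genome))
      kind[longest] <- "chromosome"
    }
    kind[is.na(kind)] <- "plasmid"
  }
  stats::setNames(kind, ids)
}

#' Default GFF3 feature-type mapping
#'
#' Maps GFF3 `type` values onto the pipeline's three feature kinds. Types not
#' present in the table are skipped with a warning by [read_annotation()].
#'
#' @return Named character vector: GFF3 type -> {ORF, tRNA, rRNA}.
#' @export
default_type_map <- function() {
  c(CDS = "ORF", gene = "ORF", tRNA = "tRNA", rRNA = "rRNA",
    tRNA_gene = "tRNA", rRNA_gene = "rRNA")
}

#' Read gene annotation from GFF3
#'
#' Imports annotated features and validates them against the genome.
#' Coordinates are kept 1-based inclusive as written in the GFF3. When both
#' a `gene` and its `CDS` line describe the same interval only one feature is
#' kept (first occurrence wins on identical id/coordinates).
#'
#' @param path Path to a GFF3 file.
#' @param genome A named `DNAStringSet` from [read_genome()].
#' @param type_map Named character vector mapping GFF3 types to
#'   `{ORF, tRNA, rRNA}`; see [default_type_map()].
#' @return A [GenomicRanges::GRanges] with metadata columns `feature_id` and
#'   `kind`.
#' @export
read_annotation <- function(path, genome, type_map = default_type_map()) {
  stopifnot(file.exists(path))
  gff <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gff$type)
  known <- types %in% names(type_map)
  if (any(!known)) {
    skipped <- unique(types[!known])
    warning("ignoring unmapped GFF3 feature types: ",
            paste(skipped, collapse = ", "))
    gff <- gff[known]
    types <- types[known]
  }
  if (length(gff) == 0L)
    return(GenomicRanges::GRanges(feature_id = character(), kind = character()))
  ids <- gff$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gff))
  ids[is.na(ids)] <- paste0("feature_", seq_len(length(gff)))[is.na(ids)]
  feat <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(gff),
    ranges = IRanges::ranges(gff),
    strand = BiocGenerics::strand(gff),
    feature_id = as.character(ids),
    kind = unname(type_map[types]))
  bad_rep <- !as.character(GenomeInfoDb::seqnames(feat)) %in% names(genome)
  if (any(bad_rep))
    stop("feature(s) on unknown replicon: ",
         paste(unique(as.character(GenomeInfoDb::seqnames(feat))[bad_rep]),
               collapse = ", "))
  lens <- stats::setNames(BiocGenerics::width(genome), names(genome))
  over <- BiocGenerics::end(feat) >
    lens[as.character(GenomeInfoDb::seqnames(feat))]
  if (any(over) || any(BiocGenerics::start(feat) < 1L))
    stop("feature outside replicon bounds: ",
         paste(feat$feature_id[over | BiocGenerics::start(feat) < 1L],
               collapse = ", "))
  if (any(as.character(BiocGenerics::strand(feat)) == "*"))
    stop("feature without strand: ",
         paste(feat$feature_id[as.character(BiocGenerics::strand(feat)) == "*"],
               collapse = ", "))
  # drop duplicate (id, interval) rows, e.g. gene + CDS describing one locus
  key <- paste(feat$feature_id, GenomeInfoDb::seqnames(feat),
               BiocGenerics::start(feat), BiocGenerics::end(feat))
  feat <- feat[!duplicated(key)]
  o <- order(as.character(GenomeInfoDb::seqnames(feat)),
             BiocGenerics::start(feat),
             as.character(BiocGenerics::strand(feat)))
  feat[o]
}

#' Write features to GFF3
#'
#' @param features A `GRanges` with `feature_id` and `kind` metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(features, path) {
  kind_to_type <- c(ORF = "CDS", tRNA = "tRNA", rRNA = "rRNA")
  lines <- c("##gff-version 3")
  o <- order(as.character(GenomeInfoDb::seqnames(features)),
             BiocGenerics::start(features),
             as.character(BiocGenerics::strand(features)))
  features <- features[o]
  lines <- c(lines, paste(
    as.character(GenomeInfoDb::seqnames(features)),
    "srnapipe",
    kind_to_type[features$kind],
    BiocGenerics::start(features),
    BiocGenerics::end(features),
    ".",
    as.character(BiocGenerics::strand(features)),
    ".",
    paste0("ID=", features$feature_id),
    sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

new_alignments <- function(read_id = character(), replicon_id = character(),
                           start = integer(), end = integer(),
                           strand = character(), is_unique = logical()) {
  data.frame(read_id = as.character(read_id),
             replicon_id = as.character(replicon_id),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand), is_unique = as.logical(is_unique),
             stringsAsFactors = FALSE)
}

validate_alignments <- function(aln, genome) {
  if (nrow(aln) == 0L) return(invisible(aln))
  stopifnot(all(aln$strand %in% c("+", "-")), all(aln$start <= aln$end))
  lens <- stats::setNames(BiocGenerics::width(genome), names(genome))
  if (!all(aln$replicon_id %in% names(genome)))
    stop("alignment on unknown replicon")
  if (any(aln$start < 1L) || any(aln$end > lens[aln$replicon_id]))
    stop("alignment outside replicon bounds")
  invisible(aln)
}

read_sam_alignments <- function(path, genome) {
  bam <- tryCatch(
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE),
    error = function(e) stop("failed to parse SAM '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0L) return(new_alignments())
  flag <- S4Vectors::mcols(ga)$flag
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  qname <- S4Vectors::mcols(ga)$qname
  placements <- table(qname)
  aln <- new_alignments(
    read_id = qname,
    replicon_id = as.character(GenomeInfoDb::seqnames(ga)),
    start = BiocGenerics::start(ga),
    end = BiocGenerics::end(ga),
    strand = as.character(BiocGenerics::strand(ga)),
    is_unique = !secondary & !supplementary &
      as.integer(placements[qname]) == 1L)
  aln
}

read_bed_alignments <- function(path, genome) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start0", "end0", "name",
                                         "score", "strand"))
  if (!all(bed$strand %in% c("+", "-")))
    stop("BED6 strand column must be '+' or '-'")
  placements <- table(bed$name)
  # BED is 0-based half-open; internal coordinates are 1-based inclusive
  new_alignments(
    read_id = bed$name,
    replicon_id = bed$chrom,
    start = bed$start0 + 1L,
    end = bed$end0,
    strand = bed$strand,
    is_unique = as.integer(placements[bed$name]) == 1L)
}

#' Read mapped alignments from SAM or BED6
#'
#' SAM records are parsed through Rsamtools/GenomicAlignments: the alignment
#' end is derived from reference-consuming CIGAR operations, and unmapped
#' records are dropped. BED6 input is converted from 0-based half-open to the
#' package's 1-based inclusive coordinates. A read is flagged unique when it
#' has exactly one placement in the file and that placement is a primary
#' alignment.
#'
#' @param path Path to a `.sam` or `.bed` file.
#' @param genome A named `DNAStringSet`; alignments are validated against
#'   replicon bounds.
#' @param format `"auto"` (by extension), `"sam"` or `"bed"`.
#' @return A data.frame with columns `read_id`, `replicon_id`, `start`,
#'   `end`, `strand`, `is_unique`.
#' @export
read_alignments <- function(path, genome, format = c("auto", "sam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "bed") "bed" else "sam"
  }
  aln <- switch(format,
                sam = read_sam_alignments(path, genome),
                bed = read_bed_alignments(path, genome))
  validate_alignments(aln, genome)
  aln[order(aln$replicon_id, aln$start, aln$strand, aln$read_id), ,
      drop = FALSE]
}

#' Write alignments as SAM
#'
#' Emits a minimal valid SAM file (`@HD`, one `@SQ` per replicon; FLAG 0/16;
#' CIGAR `<len>M`). The SEQ field carries the forward-strand reference
#' subsequence of the aligned interval, matching the SAM convention that SEQ
#' is stored in reference orientation. Records are sorted by replicon, start,
#' strand so output is diffable.
#'
#' @param aln Alignment data.frame as returned by [map_reads()] or
#'   [read_alignments()].
#' @param genome A named `DNAStringSet`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, genome, path) {
  validate_alignments(aln, genome)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(genome), "\tLN:",
                     BiocGenerics::width(genome)))
  o <- order(aln$replicon_id, aln$start, aln$strand, aln$read_id)
  aln <- aln[o, , drop = FALSE]
  if (nrow(aln)) {
    seq <- as.character(Biostrings::subseq(
      genome[aln$replicon_id], start = aln$start, end = aln$end))
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    body <- paste(aln$read_id, flag, aln$replicon_id, aln$start, 255L,
                  paste0(aln$end - aln$start + 1L, "M"),
                  "*", 0L, 0L, seq, "*", sep = "\t")
  } else body <- character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read small-RNA reads from FASTQ
#'
#' @param path FASTQ path (Phred+33).
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
read_fastq <- function(path) {
  # the reader emits a harmless note about dropping its own interim mcols
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}
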