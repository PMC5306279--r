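test_that("FASTA genomes load with one replicon per record", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr", "ACGT"), fa)
  g <- read_genome(fa)
  expect_s4_class(g, "DNAStringSet")
  expect_equal(length(g), 1L)
  expect_equal(unname(BiocGenerics::width(g)), 4L)
  expect_equal(names(g), "chr")

  # chromosome + four plasmids, lower case and RNA alphabet normalized
  writeLines(c(">chr desc", "acgu", ">p1", "AAAA", ">p2", "CCCC",
               ">p3", "GGGG", ">p4", "TTTT"), fa)
  g <- read_genome(fa)
  expect_equal(length(g), 5L)
  expect_equal(as.character(g[["chr"]]), "ACGT")
  kinds <- replicon_kinds(g)
  expect_equal(sum(kinds == "chromosome"), 1L)
  expect_equal(sum(kinds == "plasmid"), 4L)
})

test_that("degenerate FASTA input is rejected", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr", "ACGT", ">chr", "TTTT"), fa)
  expect_error(read_genome(fa), "duplicate")
  writeLines(character(), fa)
  expect_error(read_genome(fa), "empty")
})

test_that("genomes round-trip through FASTA unchanged", {
  g <- random_genome(c(chr = 3000, pA = 500), seed = 11)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, fa)
  g2 <- read_genome(fa)
  expect_equal(names(g2), names(g))
  expect_equal(as.character(g2), as.character(g))
})

test_that("GFF3 annotation is parsed, typed and validated", {
  g <- random_genome(c(chr = 1000), seed = 1)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t100\t400\t.\t+\t.\tID=orf1",
               "chr\tsrc\ttRNA\t500\t580\t.\t-\t.\tID=t1",
               "chr\tsrc\trRNA\t600\t900\t.\t+\t.\tID=r1"), gff)
  f <- read_annotation(gff, g)
  expect_equal(length(f), 3L)
  orf <- f[f$feature_id == "orf1"]
  expect_equal(orf$kind, "ORF")
  expect_equal(BiocGenerics::start(orf), 100L)
  expect_equal(BiocGenerics::end(orf), 400L)
  expect_equal(as.character(BiocGenerics::strand(orf)), "+")
  expect_setequal(f$kind, c("ORF", "tRNA", "rRNA"))

  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t100\t1400\t.\t+\t.\tID=orf1"), gff)
  expect_error(read_annotation(gff, g), "bounds")
  writeLines(c("##gff-version 3",
               "nope\tsrc\tCDS\t100\t400\t.\t+\t.\tID=orf1"), gff)
  expect_error(read_annotation(gff, g), "unknown replicon")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t100\t400\t.\t+\t.\tID=orf1",
               "chr\tsrc\tregion\t1\t1000\t.\t+\t.\tID=x"), gff)
  expect_warning(f <- read_annotation(gff, g), "ignoring")
  expect_equal(length(f), 1L)
})

test_that("SAM alignments carry CIGAR-derived ends, strand and uniqueness", {
  g <- random_genome(c(chr = 500), seed = 2)
  sam <- withr::local_tempfile(fileext = ".sam")
  seq50 <- substr(as.character(g[["chr"]]), 100, 149)
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:chr\tLN:500",
               paste("r1", 0, "chr", 100, 255, "50M", "*", 0, 0, seq50, "*",
                     sep = "\t"),
               paste("r2", 16, "chr", 200, 255, "30M", "*", 0, 0,
                     substr(as.character(g[["chr"]]), 200, 229), "*",
                     sep = "\t"),
               paste("r3", 0, "chr", 10, 255, "20M", "*", 0, 0,
                     substr(as.character(g[["chr"]]), 10, 29), "*",
                     sep = "\t"),
               paste("r3", 0, "chr", 300, 255, "20M", "*", 0, 0,
                     substr(as.character(g[["chr"]]), 300, 319), "*",
                     sep = "\t")), sam)
  aln <- read_alignments(sam, g)
  r1 <- aln[aln$read_id == "r1", ]
  expect_equal(r1$start, 100L)
  expect_equal(r1$end, 149L)
  expect_equal(r1$strand, "+")
  expect_true(r1$is_unique)
  expect_equal(aln$strand[aln$read_id == "r2"], "-")
  r3 <- aln[aln$read_id == "r3", ]
  expect_equal(nrow(r3), 2L)
  expect_false(any(r3$is_unique))
})

test_that("SAM end coordinates agree with a brute-force CIGAR walker", {
  set.seed(42)
  g <- random_genome(c(chr = 2000))
  gc <- as.character(g[["chr"]])
  recs <- character(); starts <- integer(); widths <- integer()
  for (i in 1:40) {
    cig <- random_cigar()
    qw <- oracle_cigar_query_width(cig)
    rw <- oracle_cigar_ref_width(cig)
    pos <- sample(1000, 1)
    recs <- c(recs, paste(paste0("r", i), 0, "chr", pos, 255, cig, "*", 0, 0,
                          paste(sample(c("A", "C", "G", "T"), qw,
                                       replace = TRUE), collapse = ""),
                          "*", sep = "\t"))
    starts <- c(starts, pos); widths <- c(widths, rw)
  }
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr\tLN:2000", recs), sam)
  aln <- read_alignments(sam, g)
  aln <- aln[match(paste0("r", 1:40), aln$read_id), ]
  expect_equal(aln$end, starts + widths - 1L)
  # every parsed interval lies within its replicon
  expect_true(all(aln$start >= 1L & aln$end <= 2000L))
})

test_that("BED6 input converts to 1-based inclusive coordinates", {
  g <- random_genome(c(chr = 500), seed = 3)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr\t99\t149\tr1\t0\t+",
               "chr\t199\t229\tr2\t0\t-",
               "chr\t9\t29\tr3\t0\t+",
               "chr\t299\t319\tr3\t0\t+"), bed)
  aln <- read_alignments(bed, g)
  r1 <- aln[aln$read_id == "r1", ]
  expect_equal(r1$start, 100L)
  expect_equal(r1$end, 149L)
  expect_true(r1$is_unique)
  expect_false(any(aln$is_unique[aln$read_id == "r3"]))
})

test_that("alignments outside replicon bounds are rejected", {
  g <- random_genome(c(chr = 100), seed = 4)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr\t80\t150\tr1\t0\t+", bed)
  expect_error(read_alignments(bed, g), "bounds")
})

test_that("FASTQ reads round-trip with qualities intact", {
  r <- make_reads(c("ACGTACGTACGTACGTAC", "TTTTAAAACCCCGGGGTT"), phred = 31L)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r, fq)
  r2 <- read_fastq(fq)
  expect_equal(as.character(r2), as.character(r), ignore_attr = TRUE)
  expect_equal(as.character(Biostrings::quality(r2)),
               as.character(Biostrings::quality(r)), ignore_attr = TRUE)
})
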