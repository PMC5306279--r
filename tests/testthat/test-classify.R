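toy_features <- function() {
  make_features(data.frame(
    replicon_id = "chr",
    start = c(1000L, 3000L, 5000L, 7000L, 9000L),
    end = c(1900L, 3080L, 6500L, 7800L, 9900L),
    strand = c("+", "-", "+", "-", "+"),
    feature_id = c("orfA", "trna1", "rrna1", "orfB", "orfC"),
    kind = c("ORF", "tRNA", "rRNA", "ORF", "ORF"),
    stringsAsFactors = FALSE))
}

unit_at <- function(start, end, strand = "+", read_count = 20L) {
  make_units(data.frame(replicon_id = "chr", start = as.integer(start),
                        end = as.integer(end), strand = strand,
                        read_count = as.integer(read_count),
                        total_count = as.integer(read_count) + 5L,
                        stringsAsFactors = FALSE))
}

test_that("category rules fire in priority order", {
  f <- toy_features()
  # antisense fully inside an ORF body
  r <- classify_unit(unit_at(1100, 1250, "-"), f)
  expect_equal(r$category, "AS")
  expect_equal(r$associated_feature_id, "orfA")
  # sense transcript inside an ORF
  expect_equal(classify_unit(unit_at(1100, 1250, "+"), f)$category, "ORF")
  # nothing within 300 nt -> intergenic
  r <- classify_unit(unit_at(2300, 2450, "+"), f)
  expect_equal(r$category, "IGR")
  expect_true(is.na(r$associated_feature_id))
  # + strand unit spanning [start-120, start-40] of a + strand gene
  r <- classify_unit(unit_at(1000 - 120, 1000 - 40, "+"), f)
  expect_equal(r$category, "LR5")
  expect_equal(r$associated_feature_id, "orfA")
  # minus-strand gene: the leader window sits right of the gene end
  r <- classify_unit(unit_at(7801 + 10, 7801 + 120, "-"), f)
  expect_equal(r$category, "LR5")
  expect_equal(r$associated_feature_id, "orfB")
  # structural RNA wins on either strand, even over antisense
  expect_equal(classify_unit(unit_at(5100, 5220, "-"), f)$category, "rRNA")
  expect_equal(classify_unit(unit_at(3010, 3060, "+"), f)$category, "tRNA")
})

test_that("sense calls respect the overlap fraction, antisense needs 1 nt", {
  f <- toy_features()
  # 100 nt unit with 30 nt inside orfA on the same strand: not ORF, but the
  # unit intersects orfA's upstream window -> LR5
  r <- classify_unit(unit_at(930, 1029, "+"), f)
  expect_equal(r$category, "LR5")
  # same geometry, opposite strand: 30 nt antisense overlap suffices
  r <- classify_unit(unit_at(930, 1029, "-"), f)
  expect_equal(r$category, "AS")
  # exactly half inside on the same strand -> ORF (threshold inclusive)
  expect_equal(classify_unit(unit_at(951, 1050, "+"), f)$category, "ORF")
})

test_that("classification agrees with a brute-force all-rules evaluator", {
  f <- toy_features()
  fdf <- data.frame(replicon_id = as.character(GenomeInfoDb::seqnames(f)),
                    start = BiocGenerics::start(f),
                    end = BiocGenerics::end(f),
                    strand = as.character(BiocGenerics::strand(f)),
                    kind = f$kind, stringsAsFactors = FALSE)
  set.seed(51)
  units <- do.call(rbind, lapply(1:300, function(i) {
    s <- sample(10500, 1)
    unit_at(s, s + sample(18:310, 1), sample(c("+", "-"), 1))
  }))
  got <- classify_units(units, f)
  want <- vapply(seq_len(nrow(units)), function(i)
    oracle_classify(units[i, ], fdf), character(1))
  expect_equal(got$category, want)
  # partition: every unit gets exactly one category
  expect_false(anyNA(got$category))
})

test_that("the candidate filter keeps sRNA classes at >= 10 unique reads", {
  f <- toy_features()
  units <- rbind(unit_at(1100, 1250, "-", read_count = 9L),   # AS, too few
                 unit_at(1300, 1420, "-", read_count = 10L),  # AS, boundary
                 unit_at(2300, 2400, "+", read_count = 10L),  # IGR
                 unit_at(1100, 1250, "+", read_count = 500L)) # ORF
  units <- classify_units(units, f)
  cand <- filter_candidates(units)
  expect_equal(nrow(cand), 2L)
  expect_setequal(cand$srna_class, c("asRNA", "IGR"))
  expect_false(any(cand$read_count < 10L))
})

test_that("raising the read threshold never adds candidates", {
  f <- toy_features()
  set.seed(52)
  units <- do.call(rbind, lapply(1:100, function(i) {
    s <- sample(10000, 1)
    unit_at(s, s + 100, sample(c("+", "-"), 1),
            read_count = sample(1:40, 1))
  }))
  units <- classify_units(units, f)
  n_prev <- Inf
  for (thr in c(1, 5, 10, 20, 40)) {
    n <- nrow(filter_candidates(units, classify_params(min_unique_reads = thr)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("category breakdown partitions reads into percentages", {
  f <- toy_features()
  all_orf <- classify_units(rbind(unit_at(1100, 1300), unit_at(1200, 1400)), f)
  b <- category_breakdown(all_orf)
  expect_equal(b$category, "ORF")
  expect_equal(b$pct_reads, 100)

  two <- rbind(unit_at(1100, 1250, "-"), unit_at(2300, 2400, "+"))
  two$total_count <- c(40L, 40L)
  b <- category_breakdown(classify_units(two, f))
  expect_equal(sort(b$pct_reads), c(50, 50))

  set.seed(53)
  many <- do.call(rbind, lapply(1:80, function(i) {
    s <- sample(10000, 1)
    unit_at(s, s + sample(20:200, 1), sample(c("+", "-"), 1),
            read_count = sample(10:60, 1))
  }))
  b <- category_breakdown(classify_units(many, f))
  expect_equal(sum(b$pct_reads), 100, tolerance = 1e-9)
  expect_equal(sum(b$n_units), 80L)
})
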