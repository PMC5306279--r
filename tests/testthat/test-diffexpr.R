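mk_cand <- function(start, end, read_count, strand = "+", cond = "NL",
                    cls = "asRNA", replicon = "chr", id = NULL) {
  n <- max(length(start), length(end), length(read_count))
  start <- rep_len(as.integer(start), n); end <- rep_len(as.integer(end), n)
  data.frame(unit_id = if (is.null(id)) sprintf("%s_u%d", cond, seq_len(n))
             else id,
             replicon_id = rep_len(replicon, n), strand = rep_len(strand, n),
             start = start, end = end, length = end - start + 1L,
             read_count = rep_len(as.integer(read_count), n),
             total_count = rep_len(as.integer(read_count), n),
             srna_class = rep_len(cls, n), condition = rep_len(cond, n),
             stringsAsFactors = FALSE)
}

test_that("unit matching requires strand, replicon and 10% overlap", {
  nl <- mk_cand(100, 199, 20)
  hl <- mk_cand(100, 199, 20, cond = "HL")
  m <- match_units(nl, hl)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$overlap_frac, 1.0)

  # 10 shared nt over two 100-nt units: exactly at the boundary, matched
  hl <- mk_cand(190, 289, 20, cond = "HL")
  m <- match_units(nl, hl)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$overlap_frac, 0.10)

  # 9 shared nt: below the threshold
  m <- match_units(nl, mk_cand(191, 290, 20, cond = "HL"))
  expect_equal(nrow(m$pairs), 0L)

  # same interval, opposite strands
  m <- match_units(nl, mk_cand(100, 199, 20, strand = "-", cond = "HL"))
  expect_equal(nrow(m$pairs), 0L)
  expect_equal(m$unmatched_nl, nl$unit_id)
})

test_that("jittered planted pairs match one-to-one, singletons stay unmatched", {
  set.seed(61)
  starts <- sort(sample(seq(100, 50000, by = 400), 25))
  nl <- mk_cand(starts[1:20], starts[1:20] + 120, 30)
  hl <- mk_cand(starts[1:20] + sample(-5:5, 20, replace = TRUE),
                starts[1:20] + 120 + sample(-5:5, 20, replace = TRUE),
                30, cond = "HL")
  nl_extra <- mk_cand(starts[21:23], starts[21:23] + 120, 30,
                      id = paste0("NL_x", 1:3))
  hl_extra <- mk_cand(starts[24:25], starts[24:25] + 120, 30, cond = "HL",
                      id = paste0("HL_x", 1:2))
  m <- match_units(rbind(nl, nl_extra), rbind(hl, hl_extra))
  expect_equal(nrow(m$pairs), 20L)
  expect_setequal(m$unmatched_nl, paste0("NL_x", 1:3))
  expect_setequal(m$unmatched_hl, paste0("HL_x", 1:2))
  # one-to-one: no unit appears twice
  expect_false(anyDuplicated(m$pairs$nl_unit_id) > 0)
  expect_false(anyDuplicated(m$pairs$hl_unit_id) > 0)
})

test_that("status calls follow the ratio and read thresholds", {
  pair_status <- function(nl_count, hl_count) {
    calls <- diff_calls(mk_cand(100, 199, nl_count),
                        mk_cand(100, 199, hl_count, cond = "HL"))
    list(status = calls$status, ratio = calls$ratio)
  }
  r <- pair_status(10, 30)
  expect_equal(r$status, "up")
  expect_equal(r$ratio, 3.0)
  r <- pair_status(40, 20)  # ratio 0.5: boundary inclusive
  expect_equal(r$status, "down")
  expect_equal(r$ratio, 0.5)
  r <- pair_status(12, 18)
  expect_equal(r$status, "unchanged")
  expect_equal(r$ratio, 1.5)
  r <- pair_status(10, 20)  # ratio 2: boundary inclusive
  expect_equal(r$status, "up")

  # singleton handling
  calls <- diff_calls(mk_cand(100, 199, 15), mk_cand(5000, 5100, 12, cond = "HL"))
  expect_setequal(calls$status, c("unique_NL", "unique_HL"))
  # sub-threshold singleton and pair are dropped
  calls <- diff_calls(mk_cand(100, 199, 9), mk_cand(100, 199, 8, cond = "HL"))
  expect_equal(nrow(calls), 0L)
  calls <- diff_calls(mk_cand(100, 199, 9), mk_cand(100, 199, 8, cond = "HL"),
                      keep_dropped = TRUE)
  expect_equal(calls$status, "dropped")
})

test_that("every candidate lands in exactly one call or the dropped set", {
  set.seed(62)
  starts <- sample(seq(100, 80000, by = 300), 60)
  nl <- mk_cand(starts[1:40], starts[1:40] + sample(50:150, 40, replace = TRUE),
                sample(5:60, 40, replace = TRUE))
  hl <- mk_cand(starts[15:55] + sample(-10:10, 41, replace = TRUE),
                starts[15:55] + sample(60:160, 41, replace = TRUE),
                sample(5:60, 41, replace = TRUE), cond = "HL")
  calls <- diff_calls(nl, hl, keep_dropped = TRUE)
  n_nl <- sum(!is.na(calls$nl_unit_id))
  n_hl <- sum(!is.na(calls$hl_unit_id))
  expect_equal(n_nl, nrow(nl))
  expect_equal(n_hl, nrow(hl))
  expect_false(anyDuplicated(stats::na.omit(calls$nl_unit_id)) > 0)
  expect_false(anyDuplicated(stats::na.omit(calls$hl_unit_id)) > 0)
})

test_that("swapping the condition labels mirrors every call", {
  set.seed(63)
  starts <- sample(seq(100, 80000, by = 300), 50)
  nl <- mk_cand(starts[1:35], starts[1:35] + sample(50:150, 35, replace = TRUE),
                sample(8:80, 35, replace = TRUE),
                strand = sample(c("+", "-"), 35, replace = TRUE))
  hl <- mk_cand(starts[10:50] + sample(-8:8, 41, replace = TRUE),
                starts[10:50] + sample(60:160, 41, replace = TRUE),
                sample(8:80, 41, replace = TRUE),
                strand = sample(c("+", "-"), 41, replace = TRUE), cond = "HL")
  fwd <- diff_calls(nl, hl)
  swp <- diff_calls(hl, nl)
  mirror <- c(up = "down", down = "up", unchanged = "unchanged",
              unique_NL = "unique_HL", unique_HL = "unique_NL")
  tf <- table(factor(fwd$status, levels = names(mirror)))
  ts <- table(factor(swp$status, levels = names(mirror)))
  expect_equal(as.integer(tf), as.integer(ts[mirror[names(tf)]]))
})

test_that("planted fold changes are recovered under Poisson counting noise", {
  set.seed(64)
  n <- 120
  starts <- seq(100, by = 500, length.out = n)
  truth <- sample(c("up", "down", "unchanged"), n, replace = TRUE)
  lam_nl <- rep(50, n)
  lam_hl <- ifelse(truth == "up", 200, ifelse(truth == "down", 12.5, 50))
  nl <- mk_cand(starts, starts + 120, stats::rpois(n, lam_nl))
  hl <- mk_cand(starts, starts + 120, stats::rpois(n, lam_hl), cond = "HL")
  calls <- diff_calls(nl, hl)
  called <- calls$status[match(nl$unit_id, calls$nl_unit_id)]
  de <- truth != "unchanged"
  sens <- mean(called[de] == truth[de], na.rm = TRUE)
  expect_gte(sens, 0.9)
})

test_that("summaries count statuses overall and per class", {
  set.seed(65)
  starts <- seq(100, by = 400, length.out = 80)
  truth <- c(rep("up", 30), rep("down", 50))
  nl <- mk_cand(starts, starts + 100, 20,
                cls = sample(c("asRNA", "IGR", "LR5"), 80, replace = TRUE))
  hl <- mk_cand(starts, starts + 100, ifelse(truth == "up", 80, 10),
                cond = "HL")
  s <- diff_summary(diff_calls(nl, hl))
  expect_equal(s$overall$n[s$overall$status == "up"], 30L)
  expect_equal(s$overall$n[s$overall$status == "down"], 50L)
  expect_equal(sum(s$by_class$n), 80L)

  # all ratios 1 -> everything unchanged
  s <- diff_summary(diff_calls(mk_cand(starts, starts + 100, 20),
                               mk_cand(starts, starts + 100, 20, cond = "HL")))
  expect_equal(s$overall$status, "unchanged")
  # empty input -> empty tables
  s <- diff_summary(diff_calls(mk_cand(integer(), integer(), integer()),
                               mk_cand(integer(), integer(), integer(),
                                       cond = "HL")))
  expect_equal(nrow(s$overall), 0L)
})
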