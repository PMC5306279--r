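# Independent brute-force oracles and small fixture builders. These are
# deliberately naive re-implementations kept free of the package's own code
# paths so the tests have a second opinion to compare against.

make_reads <- function(seqs, phred = 35L, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read_", seq_along(seqs))
  q <- vapply(nchar(seqs), function(n)
    paste(rep(rawToChar(as.raw(phred + 33L)), n), collapse = ""), character(1))
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(q))
  names(out) <- ids
  out
}

random_genome <- function(lens, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- Biostrings::DNAStringSet(vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1)))
  names(g) <- names(lens)
  g
}

make_features <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$replicon_id,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand, feature_id = df$feature_id, kind = df$kind)
}

make_units <- function(df, condition = "NL") {
  n <- nrow(df)
  defaults <- list(unit_id = paste0(condition, "_t", seq_len(n)),
                   length = df$end - df$start + 1L,
                   read_count = 20L, total_count = 25L, oversize = FALSE,
                   condition = condition)
  for (f in names(defaults)) if (is.null(df[[f]])) df[[f]] <- defaults[[f]]
  df
}

# --- adapter trimming: scan every position, longest prefix must match ----
oracle_trim <- function(seq, adapter, min_match = 5L) {
  len <- nchar(seq); alen <- nchar(adapter)
  for (p in seq_len(len)) {
    m <- min(alen, len - p + 1L)
    if (m < min_match) break
    if (substr(seq, p, p + m - 1L) == substr(adapter, 1L, m))
      return(substr(seq, 1L, p - 1L))
  }
  seq
}

# --- CIGAR walker: reference width = sum of M, D, N, =, X ----------------
oracle_cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

oracle_cigar_query_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(n[op %in% c("M", "I", "S", "=", "X")])
}

random_cigar <- function() {
  n_ops <- sample(1:5, 1)
  ops <- sample(c("M", "I", "D", "=", "X"), n_ops, replace = TRUE,
                prob = c(4, 1, 1, 1, 1))
  ops[1] <- "M"  # start on a reference/query match
  lens <- sample(1:30, n_ops, replace = TRUE)
  # no two consecutive identical ops (SAM validity nicety), optional clips
  keep <- c(TRUE, ops[-1] != ops[-n_ops])
  ops <- ops[keep]; lens <- lens[keep]
  cig <- paste0(lens, ops, collapse = "")
  if (stats::runif(1) < 0.3) cig <- paste0(sample(1:10, 1), "S", cig)
  if (stats::runif(1) < 0.3) cig <- paste0(cig, sample(1:10, 1), "S")
  cig
}

# --- naive quadratic mapper ----------------------------------------------
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

oracle_map_one <- function(seq, genome_chr) {
  hits <- list()
  for (rid in names(genome_chr)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else revcomp_chr(seq)
      p <- gregexpr(pat, genome_chr[[rid]], fixed = TRUE)[[1]]
      # gregexpr misses overlapping occurrences; rescan manually
      subj <- genome_chr[[rid]]
      starts <- integer()
      from <- 1L
      while (from <= nchar(subj) - nchar(pat) + 1L) {
        i <- regexpr(pat, substr(subj, from, nchar(subj)), fixed = TRUE)
        if (i < 0L) break
        starts <- c(starts, from + i - 1L)
        from <- from + i
      }
      if (length(starts))
        hits[[length(hits) + 1L]] <- data.frame(
          replicon_id = rid, start = starts,
          end = starts + nchar(seq) - 1L, strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(replicon_id = character(), start = integer(),
                  end = integer(), strand = character(),
                  stringsAsFactors = FALSE)
}

# --- independent greedy unification --------------------------------------
oracle_unify <- function(aln, tol) {
  out <- list()
  for (grp in split(aln, paste(aln$replicon_id, aln$strand))) {
    key <- paste(grp$start, grp$end)
    tab <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- do.call(rbind, strsplit(tab$key, " "))
    tab$start <- as.integer(parts[, 1]); tab$end <- as.integer(parts[, 2])
    tab <- tab[order(-tab$Freq, tab$start, tab$end - tab$start), ]
    done <- rep(FALSE, nrow(tab))
    for (i in seq_len(nrow(tab))) {
      if (done[i]) next
      mem <- !done & abs(tab$start - tab$start[i]) <= tol &
        abs(tab$end - tab$end[i]) <= tol
      done[mem] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        replicon_id = grp$replicon_id[1], strand = grp$strand[1],
        start = tab$start[i], end = tab$end[i],
        total_count = sum(tab$Freq[mem]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$replicon_id, res$start, res$strand), ]
}

# --- all-rules classification evaluator ----------------------------------
oracle_classify <- function(unit, feats, upstream = 300L, sense_frac = 0.5) {
  ov_len <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2) + 1L)
  f <- feats[feats$replicon_id == unit$replicon_id, , drop = FALSE]
  ulen <- unit$end - unit$start + 1L
  ov <- vapply(seq_len(nrow(f)), function(i)
    ov_len(unit$start, unit$end, f$start[i], f$end[i]), integer(1))
  if (any(ov > 0 & f$kind == "rRNA")) return("rRNA")
  if (any(ov > 0 & f$kind == "tRNA")) return("tRNA")
  if (any(ov >= sense_frac * ulen & f$kind == "ORF" &
            f$strand == unit$strand)) return("ORF")
  if (any(ov > 0 & f$kind == "ORF" & f$strand != unit$strand)) return("AS")
  orf <- f[f$kind == "ORF" & f$strand == unit$strand, , drop = FALSE]
  for (i in seq_len(nrow(orf))) {
    if (orf$strand[i] == "+") {
      ws <- orf$start[i] - upstream; we <- orf$start[i] - 1L
    } else {
      ws <- orf$end[i] + 1L; we <- orf$end[i] + upstream
    }
    if (ov_len(unit$start, unit$end, ws, we) > 0) return("LR5")
  }
  "IGR"
}

# --- IUPAC regex oracle ---------------------------------------------------
iupac_regex <- function(pattern) {
  codes <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
             R = "AG", Y = "CT", W = "AT", S = "CG", K = "GT", M = "AC",
             B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  chars <- strsplit(toupper(chartr("u", "T", pattern)), "")[[1]]
  paste0(vapply(chars, function(ch) {
    ex <- codes[[ch]]
    if (nchar(ex) == 1L) ex else paste0("[", ex, "]")
  }, character(1)), collapse = "")
}

oracle_scan <- function(seq, pattern) {
  seq <- toupper(chartr("uU", "tT", seq))
  re <- iupac_regex(pattern)
  k <- nchar(pattern)
  n <- nchar(seq)
  pos <- integer()
  if (n >= k)
    for (i in seq_len(n - k + 1L))
      if (grepl(paste0("^", re, "$"), substr(seq, i, i + k - 1L)))
        pos <- c(pos, i)
  pos
}
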