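#' Synthetic sRNA-Seq scenario configuration
#'
#' Describes a complete two-condition small-RNA sequencing experiment on a
#' multi-replicon genome with known ground truth. Defaults emulate the study
#' design the pipeline targets, scaled to desk size: a chromosome plus four
#' plasmids; planted candidate lengths drawn from a Gaussian centered at
#' 146 nt (sd 55; condition-exclusive HL units use 167/67); a differentially
#' expressed subset at 4-fold change; library-unique units; and a background
#' of rRNA/tRNA/ORF reads at the fractions observed in real libraries
#' (roughly half of all reads structural RNA, about a fifth ORF-derived).
#'
#' @param seed Integer RNG seed; same seed + config gives byte-identical
#'   outputs.
#' @param replicon_lengths Named integer vector of replicon lengths in nt.
#' @param n_orfs,n_trna,n_rrna Numbers of annotated features to place.
#' @param n_asrna,n_igr,n_lr5 Planted sRNA candidate counts per class.
#' @param length_mean,length_sd Gaussian parameters (nt) for planted unit
#'   lengths; draws are truncated to `[18, 310]`.
#' @param hl_length_mean,hl_length_sd Length parameters for HL-exclusive
#'   units.
#' @param frac_de_up,frac_de_down,frac_unique_nl,frac_unique_hl Fractions of
#'   planted units assigned each differential status (deterministic
#'   `floor(frac * n)` counts); the remainder is unchanged.
#' @param de_fold Fold change applied in HL to the DE subset (default 4).
#' @param depth_per_unit Expected reads per planted unit per library
#'   (Poisson mean, default 50).
#' @param background_fracs Named fractions of total library reads drawn from
#'   rRNA, tRNA and ORF features.
#' @param frac_plasmid Fraction of planted candidates located on plasmids
#'   (default 0.11).
#' @param adapter_3p 3' adapter appended to every read.
#' @param read_error_rate Per-base substitution probability (default 0:
#'   error-free reads, as the exact-match test mapper assumes).
#' @param read_length Instrument read length cap; `Inf` (default) sequences
#'   the full insert so transcript boundaries are directly observable.
#' @param jitter_frac Fraction of each unit's reads with ends jittered by up
#'   to `jitter_max` nt (default 0.3), so unification sees realistic
#'   boundary variation while the exact interval stays the most abundant.
#' @param jitter_max Maximum per-end jitter in nt (default 2; keep below the
#'   unification tolerance).
#' @param frac_short,frac_lowqual Fractions of additional junk reads that
#'   are too short after trimming, or of mean Phred below 20.
#' @param deterministic_counts Use `round(lambda)` instead of Poisson draws
#'   for per-unit read counts (exact-recovery switch for tests).
#' @param phred Base quality assigned to regular reads (default 35).
#' @param upstream_window 5' leader window used when placing LR5 units
#'   (default 300, matching [classify_params()]).
#' @param min_spacing Minimum gap in nt between annotated features
#'   (default 400; guarantees planted units have >= 1 nt clearance from
#'   every classification rule boundary).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            replicon_lengths = c(chr = 200000L,
                                                 pSYSA = 10000L,
                                                 pSYSG = 10000L,
                                                 pSYSM = 10000L,
                                                 pSYSX = 10000L),
                            n_orfs = 80L, n_trna = 6L, n_rrna = 3L,
                            n_asrna = 64L, n_igr = 18L, n_lr5 = 8L,
                            length_mean = 146, length_sd = 55,
                            hl_length_mean = 167, hl_length_sd = 67,
                            frac_de_up = 0.15, frac_de_down = 0.45,
                            frac_unique_nl = 0.2, frac_unique_hl = 0.1,
                            de_fold = 4, depth_per_unit = 50,
                            background_fracs = c(rRNA = 0.27, tRNA = 0.25,
                                                 ORF = 0.22),
                            frac_plasmid = 0.11,
                            adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                            read_error_rate = 0, read_length = Inf,
                            jitter_frac = 0.3, jitter_max = 2L,
                            frac_short = 0.02, frac_lowqual = 0.02,
                            deterministic_counts = FALSE, phred = 35L,
                            upstream_window = 300L, min_spacing = 400L) {
  fr <- c(frac_de_up, frac_de_down, frac_unique_nl, frac_unique_hl)
  stopifnot(all(fr >= 0), all(fr <= 1), sum(fr) <= 1,
            all(c(n_orfs, n_trna, n_rrna, n_asrna, n_igr, n_lr5) >= 0),
            length_mean > 0, de_fold >= 1, depth_per_unit > 0,
            all(background_fracs >= 0), sum(background_fracs) < 1,
            frac_plasmid >= 0, frac_plasmid <= 1,
            grepl("^[ACGT]+$", adapter_3p),
            read_error_rate >= 0, read_error_rate < 1,
            jitter_frac >= 0, jitter_frac <= 1, jitter_max >= 0,
            min_spacing > upstream_window)
  structure(as.list(environment()), class = "scenario_config")
}

# truncated-Gaussian integer lengths, per-element bounds
draw_trunc_norm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(integer())
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- as.integer(round(stats::rnorm(length(todo), mean, sd)))
    ok <- x >= lo[todo] & x <= hi[todo]
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a complete ground-truthed sRNA-Seq scenario
#'
#' Produces a genome, an annotation, two condition libraries (NL and HL) and
#' a truth manifest. Replicon sequences are i.i.d. uniform DNA. Annotated
#' features are placed without overlap and at least `min_spacing` nt apart;
#' planted asRNAs sit strictly inside ORF bodies on the opposite strand, 5'
#' leaders strictly inside the upstream window of their gene, and intergenic
#' units at least 301 nt away from any feature, so every planted unit has
#' unambiguous class under the classification rules. Reads are exact genome
#' substrings of their unit's interval (strand-aware) with the adapter
#' appended; per-unit counts are Poisson unless `deterministic_counts` is
#' set. Everything is reproducible from the seed.
#'
#' @param config A [scenario_config()] object.
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `NL.fastq`, `HL.fastq` and `manifest.json` there.
#' @return Invisibly, a list with `genome` (DNAStringSet), `features`
#'   (GRanges), `reads` (list of NL/HL `QualityScaledDNAStringSet`),
#'   `manifest` (truth list, see below) and `paths` (when `out_dir` given).
#'   The manifest holds the planted-unit table (coordinates, class,
#'   associated feature, per-library counts, differential status), the
#'   adapter, the seed and a config echo.
#' @export
generate_scenario <- function(config = scenario_config(), out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  cfg <- config

  ## genome
  genome <- Biostrings::DNAStringSet(
    vapply(cfg$replicon_lengths, random_dna, character(1)))
  names(genome) <- names(cfg$replicon_lengths)
  kinds <- replicon_kinds(genome)
  plasmids <- names(kinds)[kinds == "plasmid"]
  chrom <- names(kinds)[kinds == "chromosome"][1L]

  ## feature plan: a few ORFs per plasmid, everything else on the chromosome
  per_plasmid <- if (length(plasmids)) min(3L, cfg$n_orfs %/%
                                             max(length(plasmids), 1L)) else 0L
  n_plasmid_orfs <- per_plasmid * length(plasmids)
  feat_plan <- data.frame(
    kind = c(rep("ORF", cfg$n_orfs), rep("tRNA", cfg$n_trna),
             rep("rRNA", cfg$n_rrna)),
    replicon_id = c(rep(plasmids, each = per_plasmid),
                    rep(chrom, cfg$n_orfs - n_plasmid_orfs),
                    rep(chrom, cfg$n_trna + cfg$n_rrna)),
    stringsAsFactors = FALSE)
  feat_plan$length <- ifelse(
    feat_plan$kind == "ORF", sample(600:1500, nrow(feat_plan), replace = TRUE),
    ifelse(feat_plan$kind == "tRNA",
           sample(75:90, nrow(feat_plan), replace = TRUE),
           sample(1400:1600, nrow(feat_plan), replace = TRUE)))
  feat_plan$strand <- sample(c("+", "-"), nrow(feat_plan), replace = TRUE)

  ## planted-unit plan: class, status, length
  n_cand <- cfg$n_asrna + cfg$n_igr + cfg$n_lr5
  units <- data.frame(
    class = c(rep("asRNA", cfg$n_asrna), rep("IGR", cfg$n_igr),
              rep("LR5", cfg$n_lr5)),
    stringsAsFactors = FALSE)
  n_up <- floor(cfg$frac_de_up * n_cand)
  n_down <- floor(cfg$frac_de_down * n_cand)
  n_unl <- floor(cfg$frac_unique_nl * n_cand)
  n_uhl <- floor(cfg$frac_unique_hl * n_cand)
  status_pool <- c(rep("up", n_up), rep("down", n_down),
                   rep("unique_NL", n_unl), rep("unique_HL", n_uhl),
                   rep("unchanged", n_cand - n_up - n_down - n_unl - n_uhl))
  units$status <- sample(status_pool)
  is_hl_only <- units$status == "unique_HL"
  cap <- ifelse(units$class == "LR5", min(280L, cfg$upstream_window - 20L), 310L)
  units$length <- NA_integer_
  units$length[!is_hl_only] <- draw_trunc_norm(
    sum(!is_hl_only), cfg$length_mean, cfg$length_sd, 18L, cap[!is_hl_only])
  units$length[is_hl_only] <- draw_trunc_norm(
    sum(is_hl_only), cfg$hl_length_mean, cfg$hl_length_sd, 18L,
    cap[is_hl_only])

  ## replicon assignment of planted units (plasmid quota per class)
  units$replicon_id <- NA_character_
  for (cls in c("asRNA", "IGR", "LR5")) {
    idx <- which(units$class == cls)
    q <- if (length(plasmids)) round(cfg$frac_plasmid * length(idx)) else 0L
    q <- min(q, length(idx))
    on_plasmid <- if (q > 0L) sample(idx, q) else integer()
    units$replicon_id[on_plasmid] <-
      rep_len(plasmids, length(on_plasmid))
    units$replicon_id[setdiff(idx, on_plasmid)] <- chrom
  }

  ## lay out each replicon: features and IGR units left to right
  placed <- place_scenario(genome, feat_plan, units, cfg)
  features <- placed$features
  units <- placed$units

  ## per-library read counts
  draw_count <- function(lambda) {
    if (cfg$deterministic_counts) as.integer(round(lambda))
    else stats::rpois(length(lambda), lambda)
  }
  d <- cfg$depth_per_unit
  nl_lambda <- ifelse(units$status == "unique_HL", 0, d)
  hl_lambda <- ifelse(units$status == "unique_NL", 0,
               ifelse(units$status == "up", d * cfg$de_fold,
               ifelse(units$status == "down", d / cfg$de_fold, d)))
  units$nl_count <- ifelse(nl_lambda > 0, draw_count(nl_lambda), 0L)
  units$hl_count <- ifelse(hl_lambda > 0, draw_count(hl_lambda), 0L)

  ## reads
  reads <- list(
    NL = build_library(genome, features, units, units$nl_count, "NL", cfg),
    HL = build_library(genome, features, units, units$hl_count, "HL", cfg))

  manifest <- list(
    seed = cfg$seed,
    adapter_3p = cfg$adapter_3p,
    units = units,
    features = data.frame(
      feature_id = features$feature_id, kind = features$kind,
      replicon_id = as.character(GenomeInfoDb::seqnames(features)),
      strand = as.character(BiocGenerics::strand(features)),
      start = BiocGenerics::start(features),
      end = BiocGenerics::end(features), stringsAsFactors = FALSE),
    library_stats = lapply(reads, function(r) attr(r, "stats")),
    config = unclass(cfg)[setdiff(names(cfg), "replicon_lengths")])
  manifest$config$replicon_lengths <- as.list(cfg$replicon_lengths)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome = file.path(out_dir, "genome.fa"),
                  annotation = file.path(out_dir, "annotation.gff3"),
                  NL = file.path(out_dir, "NL.fastq"),
                  HL = file.path(out_dir, "HL.fastq"),
                  manifest = file.path(out_dir, "manifest.json"))
    write_genome(genome, paths$genome)
    write_annotation(features, paths$annotation)
    write_fastq(reads$NL, paths$NL)
    write_fastq(reads$HL, paths$HL)
    man_json <- manifest
    man_json$config$read_length <-
      if (is.infinite(cfg$read_length)) "Inf" else cfg$read_length
    jsonlite::write_json(man_json, paths$manifest, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(list(genome = genome, features = features, reads = reads,
                 manifest = manifest, paths = paths))
}

# Sequential left-to-right placement of features and intergenic units on
# each replicon; then coordinates for asRNA (inside host ORF, opposite
# strand) and LR5 (inside the upstream window, same strand) units.
place_scenario <- function(genome, feat_plan, units, cfg) {
  lens <- stats::setNames(BiocGenerics::width(genome), names(genome))
  feat_plan$start <- NA_integer_; feat_plan$end <- NA_integer_
  units$start <- NA_integer_; units$end <- NA_integer_
  units$strand <- NA_character_
  units$associated_feature_id <- NA_character_
  igr_clearance <- 301L

  for (rid in names(genome)) {
    f_idx <- which(feat_plan$replicon_id == rid)
    i_idx <- which(units$replicon_id == rid & units$class == "IGR")
    # interleave IGR slots among features at random positions in the queue
    queue <- data.frame(
      what = c(rep("feature", length(f_idx)), rep("igr", length(i_idx))),
      idx = c(f_idx, i_idx), stringsAsFactors = FALSE)
    queue <- queue[sample(nrow(queue)), , drop = FALSE]
    cursor <- 150L
    for (k in seq_len(nrow(queue))) {
      if (queue$what[k] == "feature") {
        i <- queue$idx[k]
        start <- cursor + cfg$min_spacing + sample(0:200, 1L)
        end <- start + feat_plan$length[i] - 1L
        feat_plan$start[i] <- start; feat_plan$end[i] <- end
      } else {
        i <- queue$idx[k]
        start <- cursor + igr_clearance + sample(0:80, 1L)
        end <- start + units$length[i] - 1L
        units$start[i] <- start; units$end[i] <- end
        units$strand[i] <- sample(c("+", "-"), 1L)
        end <- end + igr_clearance - cfg$min_spacing  # next feature gap covers it
      }
      cursor <- max(cursor, end)
    }
    if (cursor > lens[rid] - 350L)
      stop("infeasible placement on replicon '", rid,
           "': features exceed replicon length")
  }
  feat_plan$feature_id <- sprintf("%s_%03d", tolower(feat_plan$kind),
                                  seq_len(nrow(feat_plan)))

  ## hosts for asRNA and LR5 units, per replicon, without replacement
  orfs <- which(feat_plan$kind == "ORF")
  taken <- logical(nrow(feat_plan))
  for (cls in c("asRNA", "LR5")) {
    for (i in which(units$class == cls)) {
      pool <- orfs[feat_plan$replicon_id[orfs] == units$replicon_id[i] &
                     !taken[orfs]]
      if (length(pool) == 0L)
        stop("infeasible placement: not enough host ORFs on replicon '",
             units$replicon_id[i], "'")
      h <- if (length(pool) == 1L) pool else sample(pool, 1L)
      taken[h] <- TRUE
      fs <- feat_plan$start[h]; fe <- feat_plan$end[h]
      fstrand <- feat_plan$strand[h]
      L <- units$length[i]
      units$associated_feature_id[i] <- feat_plan$feature_id[h]
      if (cls == "asRNA") {
        # strictly inside the ORF body, opposite strand
        lo <- fs + 1L; hi <- fe - 1L - L + 1L
        units$start[i] <- lo + sample(0:(hi - lo), 1L)
        units$end[i] <- units$start[i] + L - 1L
        units$strand[i] <- if (fstrand == "+") "-" else "+"
      } else {
        # strictly inside the upstream window, same strand
        w <- cfg$upstream_window
        if (fstrand == "+") {
          lo <- fs - w + 2L; hi <- fs - 2L - L + 1L
        } else {
          lo <- fe + 2L; hi <- fe + w - 1L - L + 1L
        }
        units$start[i] <- lo + sample(0:(hi - lo), 1L)
        units$end[i] <- units$start[i] + L - 1L
        units$strand[i] <- fstrand
      }
    }
  }
  units$unit_id <- sprintf("planted_%03d", seq_len(nrow(units)))
  units <- units[, c("unit_id", "class", "replicon_id", "strand", "start",
                     "end", "length", "associated_feature_id", "status")]
  features <- GenomicRanges::GRanges(
    seqnames = feat_plan$replicon_id,
    ranges = IRanges::IRanges(start = feat_plan$start, end = feat_plan$end),
    strand = feat_plan$strand,
    feature_id = feat_plan$feature_id, kind = feat_plan$kind)
  list(features = features, units = units)
}

# Strand-aware batch extraction of genome subsequences.
extract_inserts <- function(genome, rid, s, e, strand) {
  out <- character(length(rid))
  for (r in unique(rid)) {
    sel <- which(rid == r)
    x <- Biostrings::DNAStringSet(genome[[r]], start = s[sel], end = e[sel])
    neg <- strand[sel] == "-"
    if (any(neg)) x[neg] <- Biostrings::reverseComplement(x[neg])
    out[sel] <- as.character(x)
  }
  out
}

# One condition library: planted reads + structural/ORF background + junk.
build_library <- function(genome, features, units, counts, lib, cfg) {
  seqs <- character(); quals <- character(); ids <- character()
  lens <- stats::setNames(BiocGenerics::width(genome), names(genome))

  finish <- function(insert) {
    r <- paste0(insert, cfg$adapter_3p)
    if (is.finite(cfg$read_length))
      r <- substr(r, 1L, cfg$read_length)
    r
  }

  ## planted units: per-read intervals, a jittered subset per unit
  counts <- as.integer(counts)
  ui <- rep(seq_len(nrow(units)), counts)
  if (length(ui)) {
    rs <- units$start[ui]; re <- units$end[ui]
    jitter <- unlist(lapply(counts, function(c_i) {
      nj <- round(cfg$jitter_frac * c_i)
      if (c_i == 0L) return(logical())
      x <- rep(FALSE, c_i)
      if (nj > 0L) x[sample(seq_len(c_i), nj)] <- TRUE
      x
    }), use.names = FALSE)
    if (any(jitter) && cfg$jitter_max > 0L) {
      nj <- sum(jitter)
      d5 <- sample((-cfg$jitter_max):cfg$jitter_max, nj, replace = TRUE)
      d3 <- sample((-cfg$jitter_max):cfg$jitter_max, nj, replace = TRUE)
      rs[jitter] <- pmax(1L, rs[jitter] + d5)
      re[jitter] <- pmin(lens[units$replicon_id[ui[jitter]]],
                         re[jitter] + d3)
    }
    ins <- extract_inserts(genome, units$replicon_id[ui], rs, re,
                           units$strand[ui])
    seqs <- finish(ins)
    ids <- sprintf("%s_%s_r%04d", lib, units$unit_id[ui],
                   unlist(lapply(counts, seq_len), use.names = FALSE))
  }
  n_planted <- length(seqs)

  ## background reads from rRNA / tRNA / ORF features
  f_bg <- sum(cfg$background_fracs)
  bg_counts <- integer(0)
  if (f_bg > 0 && n_planted > 0) {
    bg_counts <- round(n_planted * cfg$background_fracs / (1 - f_bg))
    for (kind in names(bg_counts)) {
      nk <- bg_counts[[kind]]
      f <- features[features$kind == kind]
      if (nk == 0L || length(f) == 0L) next
      pick <- sample(seq_along(f), nk, replace = TRUE,
                     prob = BiocGenerics::width(f))
      rl <- pmin(50L, BiocGenerics::width(f)[pick])
      off <- floor(stats::runif(nk) *
                     (BiocGenerics::width(f)[pick] - rl + 1L))
      s <- BiocGenerics::start(f)[pick] + as.integer(off)
      e <- s + rl - 1L
      rid <- as.character(GenomeInfoDb::seqnames(f))[pick]
      strand <- as.character(BiocGenerics::strand(f))[pick]
      ins <- extract_inserts(genome, rid, s, e, strand)
      seqs <- c(seqs, finish(ins))
      ids <- c(ids, sprintf("%s_bg_%s_r%05d", lib, tolower(kind),
                            seq_len(nk)))
    }
  }
  n_regular <- length(seqs)
  quals <- strrep(rawToChar(as.raw(cfg$phred + 33L)), nchar(seqs))

  ## junk: too-short inserts and low-quality reads
  junk_seq <- function(n, insert_len) {
    rid <- sample(names(genome), n, replace = TRUE, prob = lens)
    il <- if (length(insert_len) > 1L)
      sample(insert_len, n, replace = TRUE) else rep(insert_len, n)
    s <- as.integer(floor(stats::runif(n) * (lens[rid] - il))) + 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    finish(extract_inserts(genome, rid, s, s + il - 1L, strand))
  }
  n_short <- round(cfg$frac_short * n_regular)
  n_lowq <- round(cfg$frac_lowqual * n_regular)
  if (n_short > 0L) {
    x <- junk_seq(n_short, 8:17)
    seqs <- c(seqs, x)
    quals <- c(quals, strrep(rawToChar(as.raw(cfg$phred + 33L)), nchar(x)))
    ids <- c(ids, sprintf("%s_junk_short_r%04d", lib, seq_len(n_short)))
  }
  if (n_lowq > 0L) {
    x <- junk_seq(n_lowq, 30L)
    seqs <- c(seqs, x)
    quals <- c(quals, strrep(rawToChar(as.raw(10L + 33L)), nchar(x)))
    ids <- c(ids, sprintf("%s_junk_lowqual_r%04d", lib, seq_len(n_lowq)))
  }

  ## optional sequencing errors
  if (cfg$read_error_rate > 0) {
    seqs <- vapply(seqs, mutate_read, character(1),
                   rate = cfg$read_error_rate, USE.NAMES = FALSE)
  }
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(out) <- ids
  attr(out, "stats") <- c(planted = n_planted,
                          as.list(bg_counts),
                          short = n_short, low_quality = n_lowq,
                          total = length(seqs))
  out
}

mutate_read <- function(seq, rate) {
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (p in hit)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}
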