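#' Fit a Gaussian to transcript-unit lengths
#'
#' Fits by sample moments: mean and standard deviation (n - 1 denominator)
#' of the unit lengths. Moment fitting is histogram-bin-width independent;
#' the histogram returned alongside is descriptive only.
#'
#' @param x A numeric vector of lengths, or a units/candidates data.frame
#'   with a `length` column.
#' @param bin_width Histogram bin width in nt (default 10).
#' @return A list of class `gaussian_fit`: `mean`, `sd`, `n`, and
#'   `histogram` (data.frame `bin_start`, `bin_end`, `count`).
#' @export
fit_length_distribution <- function(x, bin_width = 10L) {
  if (is.data.frame(x)) {
    stopifnot("length" %in% names(x))
    x <- x$length
  }
  x <- as.numeric(x)
  if (length(x) < 2L)
    stop("need at least 2 lengths to fit a distribution")
  breaks <- seq(floor(min(x) / bin_width) * bin_width,
                ceiling(max(x) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  structure(list(mean = mean(x), sd = stats::sd(x), n = length(x),
                 histogram = data.frame(bin_start = utils::head(h$breaks, -1),
                                        bin_end = h$breaks[-1],
                                        count = h$counts)),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian length fit: mean %.1f nt, sd %.1f nt (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Replicon-location breakdown of sRNA candidates
#'
#' Counts candidates per replicon, as counts and percentages, plus a
#' chromosome-versus-plasmids rollup (see [replicon_kinds()]).
#'
#' @param candidates Candidate (or unit) data.frame with a `replicon_id`
#'   column.
#' @param genome A named `DNAStringSet`; replicons with no candidate are
#'   reported with count 0.
#' @return A list with `per_replicon` (data.frame `replicon_id`, `kind`,
#'   `n`, `pct`) and `rollup` (data.frame `kind`, `n`, `pct`).
#' @export
replicon_breakdown <- function(candidates, genome) {
  stopifnot(all(candidates$replicon_id %in% names(genome)))
  kinds <- replicon_kinds(genome)
  n <- table(factor(candidates$replicon_id, levels = names(genome)))
  total <- max(sum(n), 1L)
  per <- data.frame(replicon_id = names(genome), kind = unname(kinds),
                    n = as.integer(n), pct = 100 * as.integer(n) / total,
                    stringsAsFactors = FALSE)
  roll <- stats::aggregate(per$n, by = list(kind = per$kind), FUN = sum)
  names(roll) <- c("kind", "n")
  roll$pct <- 100 * roll$n / total
  list(per_replicon = per, rollup = roll[order(roll$kind), , drop = FALSE])
}
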