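---
title: "Methods: small RNA discovery and differential calling with srnapipe"
author: "srnapipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA discovery and differential calling with srnapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapipe)
```

## The problem

Bacterial small RNAs (sRNAs) — cis-antisense RNAs, intergenic trans-acting
RNAs and 5' leader transcripts — are discovered by sequencing size-selected
RNA from two growth conditions, mapping reads to a multi-replicon genome
(one chromosome plus plasmids), merging near-identical alignments into
transcript units, classifying each unit by its genomic context, and calling
condition-dependent expression with simple count thresholds. srnapipe
implements this whole chain as composable functions, plus a ground-truthed
simulator so that every stage can be validated without any external data.

## Preprocessing

Reads carry a 3' sequencing adapter. `trim_adapter()` truncates each read
at the leftmost exact occurrence of the adapter, or of an adapter prefix of
at least 5 nt running off the read's 3' end. Matching is exact rather than
error-tolerant: the trimming contract is then deterministic and can be
checked against a brute-force scan of every adapter prefix at every
position, which is how the tests verify it. After trimming,
`filter_reads()` discards reads shorter than 18 nt ("short") and reads with
mean Phred quality below 20 ("low_quality"), in that order of precedence,
so the rejection report partitions the input exactly. Both thresholds are
inclusive on the keep side (18 nt and mean 20 survive).

## Mapping

`map_reads()` is an exact-match mapper: every occurrence of a read or its
reverse complement in the genome is reported, with reverse-complement hits
expressed on the forward coordinate axis with strand `-`. It exists so the
simulator's error-free reads can drive the pipeline end to end; real
libraries should be mapped with a production aligner and handed to
`read_alignments()` as SAM. A read is *uniquely aligned* when it has
exactly one placement; multi-mappers are kept but flagged, because
downstream filters count unique reads only. Internally the mapper batches
all read sequences into a single trusted-band `PDict` per strand, anchored
on the shortest read length, which makes matching linear in genome size
rather than in reads × genome.

Coordinates are 1-based inclusive everywhere inside the package; BED I/O
converts at the boundary. Antisense intervals keep forward-axis coordinates
with strand `-` — there is no coordinate flip.

## Unification into transcript units

Identical and nearly identical alignments (ends differing by a few
nucleotides) are merged by `unify()`. Distinct intervals are ranked by
multiplicity (ties: leftmost, then shortest) and processed greedily: each
seed absorbs every unassigned interval whose 5' and 3' ends both lie within
`end_tolerance` (default 5 nt) of the seed's ends. The unit keeps the
*seed's* interval — the modal boundary pair, i.e. the putative TSS and
terminus — not the cluster's min/max span, so a transcript with two
distinct 3' ends resolves into two units rather than one smeared one. The
ranking rule makes the greedy choice canonical, hence output is invariant
under permutation of the input, and with tolerance 0 units are exactly the
distinct `(replicon, strand, start, end)` tuples. Setting
`end_tolerance_3p = Inf` emulates 5'-anchored merging for 5'-enriched
(dRNA-Seq-like) libraries. Units longer than 310 nt — above the expected
small-RNA size range — are flagged `oversize` but kept, since physical size
selection already happened before sequencing.

## Classification

`classify_units()` assigns one category per unit by the first matching rule:

1. overlaps rRNA (either strand) — structural contamination dominates;
2. overlaps tRNA (either strand);
3. same-strand ORF overlap covering at least half the unit — `ORF`;
4. opposite-strand ORF overlap of at least 1 nt — `AS`, associated with the
   maximal-overlap ORF (ties: leftmost);
5. intersects the 300 nt window immediately 5' of a same-strand gene start
   — `LR5`, associated with that gene;
6. otherwise `IGR`.

The priority order is a design choice: structural RNA must win so that
rRNA/tRNA background can be stripped, and antisense must outrank intergenic
so asRNAs that only partially overlap an ORF are not lost. The 50% sense
threshold prevents short leaders that brush a start codon from being
swallowed by rule 3; antisense deliberately needs only 1 nt. The leader
window is measured from the annotated gene start because bacterial
annotations carry no UTRs; any intersection with the window counts
(`lr5_strict = TRUE` switches to full containment). All three knobs are
exposed in `classify_params()`.

`filter_candidates()` then keeps AS/IGR/LR5 units with at least 10 uniquely
aligned reads (inclusive), the usual false-positive guard for sRNA
candidate sets.

## Differential calling

`diff_calls()` implements a three-threshold filter, not a statistical test
— the method deliberately has no dispersion model, and none is added.
Candidates from the two libraries are matched greedily one-to-one on the
same replicon and strand when the interval intersection covers at least 10%
of the shorter unit (a symmetric, jitter-tolerant denominator; reciprocal
overlap is available as an option). For a matched pair the ratio is
HL/NL of uniquely aligned read counts: `up` at ratio ≥ 2, `down` at ≤ 0.5,
`unchanged` between; pairs where neither side reaches 10 reads are dropped.
Unmatched units with ≥ 10 reads are library-unique calls. A matched unit
with zero reads on one side is treated as unique to the other library
rather than as an infinite ratio. Raw counts are the default because the
filter's thresholds are read counts; per-million normalization
(`normalize = TRUE`) is available when library depths differ materially.
Swapping the two libraries maps `up` to `down` and `unique_NL` to
`unique_HL` exactly, which the tests assert.

Differential statuses are computed after the sRNA-class filter (on
candidates, not on all units); the class filter and the call thresholds are
independent, so the order only affects which units are considered at all.

## Descriptive statistics

`fit_length_distribution()` fits the candidate length distribution by
sample moments (mean, and sd with the n−1 denominator). Moments were chosen
over least-squares on the histogram because they are bin-width independent;
the 10 nt histogram emitted alongside is purely descriptive.
`replicon_breakdown()` tabulates candidates per replicon with a
chromosome-versus-plasmids rollup.

## asRNA target analysis

`antisense_map()` re-expresses an asRNA/target overlap in CDS-relative
coordinates (position 1 = first base of the start codon, counted along the
target's strand). Overhangs clamp to the CDS with `fully_contained = FALSE`
rather than erroring, and mapping the overlap back to genomic coordinates
recovers the original interval exactly. `fragment_length()` is the RACE
arithmetic: inclusive distance |3' end − TSS| + 1; the inclusive convention
is the one under which both printed fragment lengths of a two-ended
transcript reproduce from their genomic positions. `scan_motif()` scans for
degenerate IUPAC motifs such as the RNase E cleavage consensus RAUUW
(R = A/G, W = A/U), reporting *all* overlapping hits — completeness is the
safer library contract even though a biological report typically highlights
one site. DNA and RNA inputs are equivalent (T ≡ U).

## The simulator and what passing tests mean

`generate_scenario()` builds a complete experiment: i.i.d. uniform DNA
replicons (default one 200 kb chromosome and four 10 kb plasmids), annotated
ORF/tRNA/rRNA features placed at least 400 nt apart, and planted sRNA units
whose geometry guarantees an unambiguous class — asRNAs strictly inside ORF
bodies on the opposite strand, leaders strictly inside the 300 nt upstream
window, intergenic units at least 301 nt from any feature. Planted lengths
are Gaussian (mean 146, sd 55 nt; HL-exclusive units 167/67, reflecting the
longer-length regime of the stress condition) truncated to 18–310 nt.
Default per-unit depth is Poisson with mean 50; the differential subset is
scaled 4-fold up or down in HL, and unique units are zeroed in the other
library. Status fractions default to up 0.15 / down 0.45 / unique-NL 0.2 /
unique-HL 0.1 (the remainder unchanged), mirroring at reduced scale the
strong down-regulation excess reported for high-light stress. Background
reads are drawn from rRNA/tRNA/ORF bodies at 27/25/22% of the library, the
observed composition of such libraries after imperfect rRNA depletion, and
11% of planted candidates sit on plasmids. 64/18/8 planted
asRNA/IGR/5'-leader units are placed over 80 ORFs; each planted unit gets
its own host feature so truth labels never collide.

Reads are exact substrings of their unit's interval with the adapter
appended and flat Phred 35 qualities; a 30% subset has ends jittered by up
to 2 nt (inside the 5 nt unification tolerance) so the exact interval stays
modal. The default read length is the full insert: with units defined by
their boundaries, full-length inserts are what make those boundaries
observable, and the small-RNA size selection (≤ 310 nt) makes this
realistic for modern read lengths; a `read_length` cap exists for
shorter-read emulation, in which case boundary recovery is necessarily
partial. Junk reads (2% too short, 2% low quality) exercise the
preprocessing report. A `deterministic_counts` switch replaces Poisson
draws by their rounded means for exact-recovery tests. Identical seed and
configuration reproduce every output file byte for byte.

What passing against this simulator does *not* show: tolerance of
sequencing errors or quality gradients (reads are error-free by default;
the `read_error_rate` knob exists but the exact-match mapper will simply
drop mutated reads), GC or ligation bias, repeat-induced multi-mapping
(random genomes are essentially repeat-free), operon structure, or any
property of real expression level distributions beyond the planted
Gaussian/Poisson model.

## Numerical choices and degenerate inputs

Thresholds are inclusive everywhere (≥ 18 nt, mean Phred ≥ 20, ≥ 10 reads,
overlap ≥ 10%, ratio ≥ 2 and ≤ 0.5). Ties in unification seeding are broken
leftmost-then-shortest; ties in feature association by maximal overlap then
leftmost feature. Empty inputs yield empty outputs rather than errors,
except where a result is undefined (a Gaussian fit needs n ≥ 2; an
asRNA/target map needs opposite strands and a non-empty overlap).
Palindromic reads legitimately match both strands at one locus and are
counted as two placements. Multi-record FASTA with duplicate ids, features
beyond replicon bounds, and malformed SAM are hard errors.

## Problem sizes

The default simulated scenario (two libraries of roughly 16,000 reads each,
90 planted units, 89 features over 240 kb) runs through the complete
pipeline in well under a minute on one core; the test suite uses this
scenario once and smaller fixtures elsewhere. These sizes were chosen as
the smallest at which every stage still sees realistic structure
(multi-replicon placement, background dominance, boundary jitter), not as a
limit of the implementation — the mapper and unifier scale linearly and
near-linearly in reads.

## Known limitations

The exact-match mapper is a validation device, not an aligner. The
differential filter inherits the original method's lack of replication and
significance testing. Classification depends entirely on the annotation's
gene calls; unannotated genes masquerade as IGR/AS candidates. The 5'
leader window is a fixed 300 nt heuristic. TSS calling from 5'-enrichment
differentials, transcript assembly across gaps, and RNA secondary-structure
prediction are out of scope.
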