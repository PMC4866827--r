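---
title: "Calling and quantifying young L1 insertions from junction sequencing"
author: "L1atlas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and quantifying young L1 insertions from junction sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
    library(L1atlas)
    library(GenomicRanges)
})
```

## The problem

LINE-1 (L1) is the only autonomously active family of mobile DNA in the
human genome. Virtually all ongoing activity comes from its youngest
subfamily, L1HS-Ta, distinguished from older subfamilies by an ACA
trinucleotide in the 3' UTR (ACG in the immediate predecessor, GAG in
older families). Because recent insertions are polymorphic between
individuals and cell lines, mapping where L1HS-Ta copies sit in a given
genome — and which of them are transcribed — requires targeted data rather
than a reference annotation.

ATLAS-seq provides that data: genomic DNA is randomly sheared, ligated to
a suppression-PCR linker, and junctions between L1HS-Ta ends and their
flanking genomic DNA are amplified with subfamily-specific primers and
sequenced. A 3' library captures the downstream flank of every element; a
5' library captures the upstream flank of full-length elements (those
retaining the 5' UTR with its sense and antisense promoters — the only
copies that can be transcriptionally active on their own). This package
implements the computational half of that design: turning junction reads
into insertion calls, filtering artifacts, tracing element descent, and
measuring per-copy expression from stranded RNA-seq — plus a synthetic
data generator that stands in for sequencing data in all tests.

## Read grammar and trimming

A raw 3' read is a concatenation: sample barcode, linker, genomic flank,
poly(A) tract, L1 3'-end sequence, and the 3' PCR primer — later elements
present only when the read reaches the junction. Trimming inverts this
grammar. Barcodes are matched exactly (a single mismatch leaves the read
unassigned). The linker is then located at the 5' end with an
error-tolerant semi-global aligner and removed; reads without a linker
are discarded, as are flanks shorter than 25 nt. After 3'-end quality
trimming (running-sum rule at Q12), the primer, the L1 3'-end sequence
and a poly(A) stretch are iteratively searched and removed from the 3'
end, each recorded as a feature flag. Reads with no 3' feature are kept:
they usually represent fragments that did not reach the junction and
still support the flank cluster. 5' reads are first size-selected
(&lt; 133 nt raw means the read cannot span primer, L1 5' end and a
usable flank), stripped of primer and L1 5'-end sequence from the 5' end
and the linker from the 3' end — all three features are mandatory here —
and finally reverse-complemented so both libraries read from the linker
position toward the element.

The aligner (`findAdapter`) follows cutadapt semantics: substitutions and
indels both count as errors, the budget is `floor(error_rate * L)` where
`L` is the matched adapter length, occurrences may be internal (full
adapter) or terminal (an adapter prefix at the read 3' end of at least
`min_adapter_overlap = 8` nt), and ties go to fewest errors, then longest
match, then the terminal-most start. Poly(A) detection reuses the same
machinery with a long `A` homopolymer as the pattern and a permissive
3-nt minimum, anchored so only the most 3'-distal run is trimmed; the
permissive minimum is deliberate, since the poly(A) flag feeds the
support filter where false negatives are costlier than false positives.
Iterative trimming repeats the primer/L1/poly(A) pass until a full pass
removes nothing; termination is guaranteed because each removal shortens
the read.

## From alignments to calls

The caller consumes coordinate-sorted alignments of trimmed flanks
(GRanges with MAPQ, secondary flags and, for split reads, the clipped
segment's location). Secondary alignments and reads with MAPQ &le; 20 are
removed. PCR duplicates are collapsed by their linker position — the
genomic coordinate of the original sonication break, i.e. the
flank-distal end of the mapped read (leftmost base on the plus strand,
rightmost on minus) — keeping the longest read per position, with ties
broken by the smallest read id so outputs are reproducible. Same-strand
reads overlapping or separated by at most 100 bp merge into clusters;
the boundary is inclusive (a separation of exactly 100 merges, 101 does
not), matching the `-d` distance semantics of the interval-merging tools
this step is conventionally run with.

Orientation and insertion point derive from cluster strand and side: 3'
flank reads map antisense to their element, so a minus-strand 3' cluster
supports a sense (+) element whose insertion point is the most upstream
cluster coordinate, a plus-strand 3' cluster an antisense element with
the point at the most downstream coordinate, and 5' clusters mirror this.
Each 3' call is then matched to the nearest orientation-compatible 5'
cluster whose junction lies within 7 kb upstream in the element's sense
direction; a successful pairing marks the call full-length. The recorded
pairing distance is the genomic span strictly between the two junction
points, which makes the expected bimodality explicit: about the element
length (~6 kb) when the element body is present in the reference
assembly, 0 when it is absent. Each 5' cluster pairs with at most one 3'
call; when several calls compete the nearest wins (assignment is greedy
by increasing distance), a conservative choice given the observed
bimodal distance distribution. Calls are annotated against reference L1
annotations, known polymorphic insertions (200-bp matching window on
both), overlapping genes (sense/antisense/both relative to the element)
and copy-number segments.

Internally all coordinates live in 1-based, closed GRanges — the Bioconductor
convention — and conversion to and from 0-based, half-open BED happens
exactly once, at the file boundary (`writeCalls`/`readCalls` and the
rtracklayer importers), so no coordinate arithmetic ever mixes the two
conventions.

## The filtering tier

Three independent boolean verdicts gate a call:

* **Support.** At least 3 non-redundant 3' reads of which at least one
  ends in a poly(A) tract and/or L1 sequence, *or* at least one 5' and
  one 3' non-redundant read.
* **Spurious priming.** The 3' primer can prime at genomic sites that
  resemble its 3' end, producing clusters with no element behind them.
  A genome-wide site map is built once: every exact occurrence of every
  primer suffix from 8 nt up, plus full-primer occurrences with up to 2
  substitutions (mismatches only — the suffix forms are exact by
  construction), keeping the longest form per priming position and
  strand. A call is an artifact when it is not a reference insertion,
  a mapped site falls within its 3' cluster span (extended by the 100-bp
  cluster gap, because poly(A) trimming can shave a genomic A-run sitting
  between flank and site), and at least one supporting read shows flank
  immediately followed by primer with no poly(A)/L1 in between.
* **Older-subfamily carry-over.** The primer occasionally amplifies
  close relatives of the target subfamily. Flagging is catalog-driven
  (insertion point within 200 bp of an annotated older-subfamily 3'
  end); the roughly ten-fold lower read support such clusters show is
  surfaced as a diagnostic ratio rather than used as a threshold, since
  no principled cutoff exists for it.

A call is retained when it passes support and triggers neither artifact
flag. `discoveryRate` measures sensitivity as the fraction of a fixed
(population-invariant) insertion set recovered within 200 bp, computable
before or after filtering.

## Descent: transductions and lineages

Transcriptional readthrough past the weak L1 poly(A) signal co-mobilizes
downstream genomic sequence, so a daughter insertion carries a sequence
tag pointing back at its progenitor. Two tracers are implemented.
`detectTransductions` screens split 3' reads: both segments must map
with MAPQ &gt; 15 (the clipped tail is often low-complexity, making this
gate essential), the primary segment must sit within 500 bp of a call's
3' cluster and the clipped segment within 500 bp downstream — on the
strand implied by the element's orientation — of a *different*
full-length call; progenies matching several progenitors are dropped
entirely. The 500-bp adjacency window is a configuration value
(`transduction_window`); the anatomy it encodes (transduced sequence
flanked by two poly(A) tracts directly downstream of the source) fixes
only its order of magnitude. `assignLineages` searches junction reads
for the three published lineage tags (AC002980, RP, LRE3) at 10\% error
and 16-nt minimum overlap, detection-only. Two robustness choices are
deliberate: tags are searched in barcode/linker-clipped reads that still
contain poly(A) and L1 sequence, because the RP tag is homopolymer-rich
and aggressive trimming can destroy its context; and both the read and
its reverse complement are searched, making the result independent of
read orientation conventions. Tagged reads are attributed via their
mapped flank (primary, MAPQ &gt; 15) to intersecting full-length calls;
matches at annotated older-subfamily elements are discarded, and
conflicting lineages on one call are all reported with read counts
rather than silently resolved.

## Locus-level expression

For each full-length element the sense signal is the number of stranded
RNA-seq first mates (MAPQ &ge; 20) whose 5' position falls in the 1-kb
window immediately downstream of the 3' junction on the element's sense
strand — readthrough transcripts from the element's own promoter — and
the antisense signal mirrors it upstream of the 5' junction on the
opposite strand, capturing antisense-promoter activity. Fragments
overlapping annotated exons are masked (a window may overlap an
expressed gene); the FPKM denominator keeps the nominal 1-kb window
without rescaling for masked bases, so values stay comparable across
loci at the cost of a slight downward bias in heavily masked windows.
Counting the single 5' position avoids double-counting fragments at
window boundaries. FPKM = count / (total first mates / 10^6) / 1 kb.

A present locus is *expressed* when its sense FPKM strictly exceeds
0.05 (a locus exactly at the threshold is non-expressed). Polymorphic
loci absent from a sample's genome are a third state, held as `NA` in
the `LocusExpression` container — never 0, which would conflate "no
transcription" with "no locus"; absent loci are excluded from both the
expressed and non-expressed groups. `halfTotalContributors` reports how
many loci account for half of the summed FPKM, the headline summary of
how concentrated L1 transcription is.

Two clusterings complement the matrix. Samples are clustered by
Euclidean distance between their sense-FPKM vectors with Ward linkage
(`hclust` method `"ward.D"`, the algorithm historically named `ward`);
absent loci contribute 0 to the sample vectors, since a distance over a
ragged matrix is otherwise undefined. Loci are clustered with the
reciprocal of the mean product of FPKMs across shared-presence samples:
loci never expressed anywhere (at the 0.05 threshold, in any sample
where they are present) are excluded first; pairs present in no common
sample get a neutral distance equal to the mean of computable distances;
pairs whose products are all zero would be infinitely distant and are
capped at the maximum finite distance before linkage.

Global subfamily activity is measured independently of genomic mapping:
reads aligned end-to-end to the L1 consensus vote by the trinucleotide
their alignment spells at consensus positions 5927–5929 (1-based, as
positions on the consensus are conventionally printed; they are
converted at input). Only reads spanning all three positions count;
partial spans are tallied separately. Counts are normalized per million
genome-mapped reads. Flank metaprofiles average an arbitrary per-base
signal (RNA-seq coverage, chromatin marks) in 50-bp bins across ±1 kb of
each element extremity, oriented in the element's sense direction,
split by expressed status, with bins inside annotated element bodies
excluded so only flanks — the uniquely mappable part — are aggregated.

## The synthetic-data generator

`makeGenomeAndTruth` plants insertions in a random genome: reference
insertions splice in the element body (a synthetic 6019-nt consensus for
full-length copies, its 3' portion — 0.5 to 5.5 kb, below the pairing
threshold by construction — for truncated ones), non-reference
insertions leave only a junction point, and the generator also plants
spurious primer sites (exact genomic copies of the primer, alternating
strands), low-support older-subfamily loci, and lineage-tagged
transduced segments downstream of designated full-length reference
elements. `makeAtlasReads` inverts the read grammar, emits PCR
duplicates sharing their template's linker position (geometric copy
numbers, so a duplicate rate of 0.5 roughly doubles the raw read
count), applies substitution errors, and — because it knows the truth —
emits each read's correct flank alignment, so the test suite never
invokes an external aligner. `simulateRnaSeq` places Poisson fragment
counts in the flanking windows plus uniform background;
`simulateConsensusReads` plants diagnostic trinucleotides in stated
proportions. Everything is deterministic given the seed, and every read
id traces to a planted feature or decoy class.

Two deliberate idealizations keep the ground truth exact and should be
kept in mind when reading test results. First, the three genomic bases
adjacent to each junction are set to a fixed non-A pattern, and
non-junction reads avoid ends that would spuriously match a trimmable
feature: a genomic A-run at a junction is inherently ambiguous to any
trimmer (the real pipeline has the same blind spot), and these tests
probe the grammar, not that ambiguity. Second, read errors are
substitutions only — no indels and no homopolymer-length noise of the
kind single-molecule or semiconductor sequencing produces — and
alignments are by construction correct, so mapping errors, mappability
and repeat structure are outside what a passing suite demonstrates
about real data. The simulator's defaults (10 non-redundant 3' reads
and 5 five-prime reads per insertion, 60–250 nt flanks, 30\% duplicate
rate, 60\% reference fraction, 30\% full-length) are fixed study-like
conditions, not tuning knobs.

## Numerical and scale choices

Benchmarks in the tests and the acceptance script use a 123-insertion
fixed-set simulation on a ~2.2-Mb genome (1\% substitution errors, 30\%
duplicates, 20 primer decoys) for sensitivity and a 58-insertion
simulation (8 lineage-tagged among 50 untagged, error-free) for lineage
recovery; unit tests run on a shared 10-insertion experiment. These
sizes exercise every code path — both orientations, reference and
non-reference, all decoy classes — while keeping a full run in tens of
seconds on one core. Degenerate inputs are handled explicitly: empty
read sets and empty catalogs flow through; zero normalization totals,
an all-zero FPKM vector, an empty fixed set, unsorted cluster input and
fewer than two clusterable samples/loci are errors, not silent zeros.

## Known limitations

Zygosity and target-site duplications are not modeled; insertion calls
are presence/absence. Transduction tracing reports pairwise
progeny–progenitor links only, not multi-generation pedigrees, and the
manual review the RP lineage needs in practice is replaced by exposing
per-read diagnostics. Differential-expression testing of the flanking
windows and gene-level association statistics are out of scope: the
expression matrix exports are designed to feed standard tools for those
steps.
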