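---
title: "Curation and error profiling of CCS 16S rRNA amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and error profiling of CCS 16S rRNA amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccs16s)
```

## The problem

Circular consensus sequencing (CCS) on single-molecule platforms can read a
full-length 16S rRNA gene in one molecule: the polymerase traverses a
circularised amplicon several times and the passes are collapsed into one
consensus read. Consensus reads still carry errors — on the order of a few
tenths of a percent per base — and, unlike short-read platforms, the errors
are spread roughly uniformly along the read, so quality trimming of read ends
does not help. Curation instead works at the level of whole reads: discard
reads whose characteristics correlate with error (mismatched barcodes or
primers, low pass counts, a poor predicted error rate from the base caller),
then absorb residual error variants into their abundant parent sequences by
pre-clustering, and only then cluster OTUs.

`ccs16s` implements that workflow end to end and pairs it with a mock
community read simulator, so every stage can be validated against a known
truth without any external data.

## Read representation and the quality-zero convention

Reads are tibbles (`id`, `bases`, `quals`, `passes`, `predicted_error`,
`orientation_flipped`). The consensus base caller encodes an ambiguous call
as a Phred score of zero, so `read_fastq(pacbio_mode = TRUE)` rewrites every
quality-0 base to `N`; `write_records()` applies the inverse rule. Quality
values are required to lie in `[0, 93]`, 93 being the encoder's maximum.
Plain FASTQ has no per-read tag fields, so the pass count and predicted error
ride in the header as `@id;np=<int>;pe=<float>`; a sidecar table
(`read_id`, `passes`, `predicted_error`) takes precedence when supplied.

## Amplified regions

Six primer pairs spanning nested windows of the gene ship with the package:

```{r}
ccs_regions()
```

Coordinates are 1-based inclusive on the *E. coli* 16S reference, and the
amplicon length is the insert between (excluding) the primers, so
`amplicon_length == ref_end - ref_start + 1 - nchar(fwd) - nchar(rev)` holds
exactly for every row; `load_region_table()` enforces the identity on any
user-supplied table.

## Demultiplexing, orientation and trimming

Libraries carry paired 16-nt symmetric barcodes on both ends.
`find_and_trim()` searches for `fwd_barcode + fwd_primer` at the 5' end and
the reverse complement of `rev_primer + rev_barcode` at the 3' end, each
within `max_shift` (default 2) leading or trailing positions. Barcodes are
compared exactly; primers are compared IUPAC-aware so degenerate positions
(e.g. `M` = A/C) match their expansions. Consensus reads are emitted in
either strand orientation, so if the forward orientation fails the mismatch
thresholds the reverse complement is tried and flagged. Mismatch counts are
reported as the maximum over the two barcodes and over the two primers — the
stricter reading of an "at most one mismatch" rule; a combined budget across
all four elements is available as `combined_mismatch_budget` for the laxer
reading. Indels inside a barcode are absorbed by the shift search rather than
scored separately.

## The screen

`screen()` keeps a read iff it passes every enabled filter:

| filter            | default   | rationale                                            |
|-------------------|-----------|------------------------------------------------------|
| homopolymer       | ≤ 8 nt    | long runs are error-prone                            |
| insert length     | ±10% of the region's expected insert | proxy for "starts and ends at the expected alignment coordinates" without an external reference alignment |
| barcode/primer mismatches | ≤ 1 each | error rate rises with mismatches              |
| coverage          | ≥ 10 passes | error rate stops improving beyond 10-fold coverage |
| predicted error   | ≤ 0.01%   | strongly correlated with the observed error rate     |

The kept set is a pure conjunction, so it does not depend on the order the
filters run; the attrition report tallies failures in the order
homopolymer → length → mismatch → coverage → predicted error, mirroring the
narrative order of the curation procedure (basic screen first, then the three
error-correlated filters). When no predicted error accompanies a read the
fallback `predicted_error_from_quals()` is used: the mean of `10^(-Q/10)`
with ambiguous (quality-0) positions costed at 0.75. That fallback is a
package convention — the base caller's own estimate is proprietary — which is
why sidecar values always win.

## Measuring the true error rate

With mock community references the error rate is measured, not guessed.
`align_to_best_reference()` aligns each read against every reference by
Needleman–Wunsch with affine gaps (match +1, mismatch −1, gap open −2, gap
extend −1) and free terminal gaps on the read, and picks the reference with
the fewest differences (`n_sub + n_ins + n_del`), ties going to the first
reference in input order. Terminal gap columns are excluded from every
count, and the error rate is
`(n_sub + n_ins + n_del) / (n_match + n_sub + n_ins + n_del)` over the
remaining columns. The scoring values are conventional; the quantities the
package reports are count-based and unambiguous on near-identical sequences.
`tally_errors()` aggregates the error-type mixture, the substitution matrix,
the composition of inserted and deleted bases, and the fraction of calls at
the maximum quality value among correct calls, substitutions and insertions.

Two numerical caveats are deliberate. First, the difference-count functions
used for pre-clustering, chimera margins and OTU distances force an
end-to-end alignment (`free_ends = FALSE`): with free terminal gaps two
unrelated sequences can pair up a trivially small overlap and appear almost
identical. Free ends are reserved for read-versus-reference alignment, where
the read genuinely sits inside (or slightly beyond) its template. Second,
because terminal columns are excluded, an error in the last base or two of a
read can escape counting; at the package's default simulation scales this
shaves a few tenths of a percent off the tallied error count, well inside the
statistical tolerance of the recovery tests.

An optional diagonal band (`band`) accelerates alignment of near-identical
sequences; `band = NULL` runs the exact full dynamic program, and the banded
and exact paths are cross-checked against an independent plain-R
implementation in the test suite.

## Chimeras

PCR produces single-breakpoint hybrids (bimeras) of community members, which
would inflate the apparent error rate. Because the mock community references
are known, all possible bimeras can be enumerated:
`enumerate_in_silico_chimeras()` aligns every ordered pair of parents and
emits one product per internal alignment column, degapped and de-duplicated,
discarding products identical to a parent. A read is called chimeric when it
is at least `delta = 3` differences closer to some enumerated chimera than to
any genuine reference (`d_ref - d_chimera >= 3`). Single-breakpoint products
are the standard reading of "all possible chimeras": multi-breakpoint
enumeration is combinatorially unbounded. De novo, abundance-based chimera
detection is out of scope here — the reference-based rule is the one used for
error assessment.

## Pre-clustering

`precluster()` implements the greedy abundance-sorted denoiser: sequences are
visited in decreasing abundance (ties broken lexicographically, an arbitrary
but deterministic choice the source procedure leaves open), and each sequence
merges into the first more-abundant retained sequence within the threshold.
The threshold scales with fragment length at one difference per 100 nt,
truncated — `precluster_threshold(250)` is 2 and
`precluster_threshold(1458)` is 14 — and "within" is inclusive (`<=`): with a
strict inequality a 250-nt fragment's threshold of 2 would barely denoise at
all. Merging into the first (most abundant) match follows the greedy
description; `merge = "closest"` is available as an alternative. Total
abundance is conserved exactly, and raising the threshold can only shrink the
number of retained sequences. The cost is resolution: full-length fragments
within 14 nt of a more abundant neighbour cannot be distinguished after
denoising.

## OTUs and rarefaction

`pairwise_distance()` counts substitutions plus gap-run events (a contiguous
indel counts once, the common 16S convention; per-base counting is a switch)
over non-terminal columns. `average_neighbor()` is UPGMA — the distance
between clusters is the unweighted mean of all cross-pair distances — cut at
the 3% threshold; it is computed via `stats::hclust(method = "average")` and
verified against a naive O(n³) agglomeration in the tests.
`rarefied_otu_count()` uses the closed-form expectation
`sum_i 1 - C(N - n_i, d) / C(N, d)` on the log scale for determinism, with a
seeded Monte-Carlo mode as a cross-check; sampling deeper than the sample
size is refused (reported as not determined).

## The simulator

`simulate_ccs_reads()` is first-class, tested code: it generates the fixtures
for every recovery test and defines the conditions under which the package's
claims are checked. Its defaults encode the measured CCS error structure:

* per-base error rate 0.0065 (the observed 0.65% average);
* error-type mixture: insertions 31.2%, deletions 17.9%, substitutions 50.9%;
* deleted-base weights G 39.4%, A 24.3%, C 18.3%, T 18.0% — deletions are
  drawn by first picking the base class from these weights, then a uniform
  position among sites holding that base, so the deleted-base composition
  matches the weights irrespective of small composition fluctuations in the
  templates;
* substitution targets and inserted bases uniform;
* qualities: the maximum value 93 with probability 0.805 / 0.800 / 0.804 for
  correct calls, substitutions and insertions respectively — the striking
  observation that quality values barely separate errors from correct calls —
  with the remainder uniform on 2..92;
* pass counts uniform on 3..25 (consensus reads require at least 3 passes;
  the true distribution is not published, so a flat placeholder is used);
* 50% of reads emitted reverse-complemented, exercising orientation recovery.

Error positions are i.i.d. along the read (consensus errors are thought to be
uniformly distributed); collisions keep the first-drawn event. A
`systematic_error_rate` mode injects one fixed recurrent 1-nt substitution to
reproduce the heavy tail of the 1-nt variant spectrum, where a single variant
can recur hundreds of times.

Two read-level dials are package extensions, needed to make the
predicted-error filter meaningful in simulation:

* `rate_dispersion_sdlog` (default 2.5): each read's latent error rate is the
  base rate times a lognormal multiplier with mean 1. With a single constant
  rate essentially no full-length read is error-free, and a 0.01%
  predicted-error threshold would retain nothing; real runs retain roughly
  half their reads at that threshold. The default makes the rate distribution
  strongly right-skewed — most reads nearly perfect, a poor minority carrying
  most errors — which reproduces coverage-dependent consensus accuracy and a
  realistic retention at the default threshold.
* `predicted_error_sdlog` (default 0.5): the reported predicted error is the
  latent rate (floored at 1e-6) under lognormal noise. The prediction tracks
  the read's underlying quality rather than the realised error count, as a
  base caller's estimate would, producing a predicted-versus-observed
  association of roughly the observed strength without pinning any number to
  it.

What the generator does **not** emulate: pass-by-pass polymerase kinetics,
chemistry-specific error profiles, context-dependent (e.g. homopolymer-
length) error rates beyond the deleted-base weights, abundance skew across a
real community, or reagent contamination. Tests passing on simulated data
therefore validate the algorithms and their statistical behaviour under the
stated error structure, not performance on any particular instrument run.

## The pipeline report

`run_pipeline()` chains simulate → trim → chimera removal (perfect, from the
truth table) → basic screen → error-correlated filters → pre-cluster →
cluster, and reports per-stage read counts plus the observed error rate after
the basic screen, after the filters, and after pre-clustering — the three
columns in which a curation procedure is conventionally summarised. Stage
error rates are abundance-weighted pooled counts over unique sequences, each
aligned once to its best reference, so the columns can be reproduced
independently by running `tally_errors()` on any stage's retained reads.
Every removed read is attributed to exactly one stage; pre-clustering
reassigns reads but drops none.

## Problem sizes and determinism

All randomness flows through explicit seeds (`withr::with_seed`), so
identical seeds give byte-identical reads, truth tables and reports. The test
suite checks parameter recovery at around 10⁵ injected errors (error-type
mixture) and 5×10⁴ injected deletions (deleted-base composition), tolerating
three binomial standard errors; oracle-equivalence checks run 100 random
small instances per operation against independent plain-R brute-force
implementations; the end-to-end monotonicity check simulates a few hundred
full-length (V1–V9) reads at the default error rate. These sizes were chosen
so the statistical tolerances are tight enough to be meaningful while the
whole suite stays comfortably runnable on a laptop.

## Known limitations

* The coordinate screen is an insert-length window, not a profile-alignment
  coordinate check; severely mis-primed reads of coincidentally correct
  length pass the basic screen (and are then caught by the error filters).
* The predicted-error fallback from qualities is a convention, not the base
  caller's algorithm; supply sidecar values when you have them.
* Chimera classification against the full enumerated set is quadratic in
  references and linear in read count; for large reference sets enumerate
  once and reuse the table.
* Distances and error counts exclude terminal alignment columns, so errors in
  the outermost base or two of a read are under-counted slightly.
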