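---
title: "Estimating telomere length from paired-end whole-genome sequencing"
author: "telotape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating telomere length from paired-end WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telotape)
```

## The problem

Telomeres are the tandem TTAGGG tracts capping chromosome ends; their
mean length is a widely used marker of replicative ageing and a
phenotype of interest in cancer genomes.  Approaches that convert the
*amount* of telomeric sequence in a WGS library into a length must
divide by the number of telomeres, which is unknown and variable in
aneuploid tumours.  `telotape` instead estimates the number of
telomeres *from the data itself*: read pairs that straddle the
telomere–subtelomere boundary count telomere ends, while read pairs
wholly inside the tract count telomeric sequence.  The ratio of the two
depends on tract length and insert size but not on how many
chromosomes the sample has, so the estimate is ploidy-agnostic.

The pipeline has three stages:

1. **TELBAM extraction** — subset the BAM to read pairs where one mate
   carries at least two copies of the telomeric hexamer
   (`extractTelbam()`).
2. **Error profiling and classification** — decide, for every read,
   whether it is a *complete* telomere read despite sequencing error,
   and classify each pair as F1 (both mates complete), F2 (exactly one
   complete, reading CCCTAA), F3 (neither) or F4 (exactly one
   complete, reading TTAGGG) (`buildErrorMask()`, `countPairs()`).
3. **Length inversion** — find the telomere length whose simulated
   F1:F2a ratio reproduces the observed one (`estimateLength()`).

## Identifying divergence from the repeat

Every TELBAM read is compared against the repeat lattice
`...TTAGGGTTAGGG...` (or its reverse complement, whichever dominates
the read) by fragmentary local alignment, implemented in compiled code
(`findMismatchingLoci()`):

* maximal runs that continue the repeat at one of its six phase
  offsets (minimum run length 4) are matched wholly — this absorbs
  partial flanking repeats around each complete hexamer;
* two runs that abut mark a single indel event: one mismatch at the
  junction locus with the lower Phred score;
* the segments between runs are Hamming-aligned against all six phase
  offsets when at least 4 bp long (ties broken by the lower mean Phred
  at the mismatches); shorter segments are marked in full;
* reads shorter than one hexamer are marked in full; N bases never
  match.

The per-read outcome is a 0/1 divergence vector `m`, its total `z`,
and `lambda`, the floored mean Phred at the diverging loci offset by
the lowest observed Phred.  On random (non-telomeric) sequence this
reconstruction marks about 64% of loci: each intervening segment is
aligned at its own best phase, so slightly fewer loci diverge than
under a single whole-read alignment; what matters downstream is the
wide gap between this value and the 10% divergence a complete telomere
read may carry.

## The error profile

Sequencing error concentrates at low-Phred cycles, so complete
telomere reads suffering error populate the low-`lambda`, low-`z`
corner of the joint (`lambda`, `z`) histogram **X**.  A matched
histogram **Y** uses the mean Phred at `z` *random* loci of the same
read, and cells where `D = X - Y` exceeds `k` — the maximum of `D`
over the high-Phred/high-`z` quadrant, where no error signal can live
— form the initial mask.  Two refinements follow; their exact rules are
this package's own design, chosen to keep the contiguous low-Phred
signal while discarding scattered threshold noise:

* **noise removal** keeps only 4-connected components of two or more
  cells that touch the low-Phred rows (values up to a quarter of the
  Phred range);
* **low-Phred capture** then sets every positive-`D` cell in those
  rows up to the rightmost column already anchored there, closing the
  gaps thresholding leaves.

A read is *complete* when at least 90% of its loci match the repeat,
or when its (`lambda`, `z`) cell is set in the mask.  The 90% cut-off
is exposed (`completeness=`) because stricter values measurably reduce
accuracy: genuinely complete reads with clustered error would
otherwise be lost.

Reads with `z = 0` carry no information about error and are excluded
from both histograms; reads where *every* locus diverges are excluded
as well (the column range runs to L−1) and counted separately — they
are effectively unalignable and vanishingly rare outside degenerate
inputs.

## Interstitial repeats and the boundary count

Telomere-repeat runs also occur inside chromosome arms (interstitial
telomeric repeats, ITRs).  An ITR has two boundaries: pairs spanning
one side read CCCTAA on their complete mate — indistinguishable from
true boundary pairs (F2) — while pairs spanning the other side read
TTAGGG (F4), which *cannot* occur at a real telomere because the
chromosome ends there.  Since both sides of an ITR are sampled at the
same rate, `F2a = F2 - F4` cancels the interstitial contamination in
expectation and leaves the count of true boundary pairs.  A negative
difference can only be sampling noise and is clamped to zero with a
warning.

Orientation is recovered before any of this: reads stored
reference-forward by the aligner are reverse-complemented back to
sequenced orientation on load, because the F2/F4 distinction is
defined by what the instrument read, not by how the aligner stored it.

## Cohort correction

The boundary fraction `theta = F2a / (F2 + F4)` is noisy in
low-coverage samples.  When several samples are processed together,
each sample's `theta` is shrunk towards the cohort mean with weight
`psi / (psi + w)`, where `psi` is the variance-to-mean ratio of the
sample's **X** cells in the low-Phred band (row values 1 to 2/5 of the
Phred range) and `w = 3`.  A concentrated band (high `psi`) indicates
strong sample-specific signal and little shrinkage; an empty band
defers entirely to the cohort.  An alternative formulation of this
correction divides by `psi * w` instead; that form is not a weighted
average — a cohort of identical samples is not a fixed point under it
— so this package normalises by `psi + w` and keeps the non-normalised
variant behind `strictDenominator = TRUE` for comparison with
implementations that use it.

## From counts to base pairs

`simulateExpectedRatio()` models one telomere: inserts are drawn from
`Normal(mean, sd)` truncated below at twice the read length, fragments
are placed uniformly over a construct whose first `tl` bases are
telomere, and each fragment scores F1 (both reads wholly inside the
tract) or F2a (the boundary-crossing configurations).  With a fixed
insert `I` and read length `L` the expected ratio has the closed form
`(tl - I + 1) / (I - L)`, which the Monte-Carlo model reproduces and
the tests check by exhaustive enumeration.  `estimateLength()` inverts
the model by bracket expansion and bisection on `tl`; every evaluation
reuses the same random-number stream (common random numbers), which
makes the simulated ratio monotone in `tl` and the whole estimate
deterministic for a fixed seed.  Defaults: 10,000 fragments per
evaluation, 1 bp bisection tolerance, at most 60 iterations.

Degenerate inputs are explicit: `F2a = 0` is an error ("no boundary
reads"), because without boundary pairs the telomere count is unknown
and no length can be normalised; `F1 = 0` yields a warning and a
degenerate short-tract estimate bounded by the mean insert.

The insert model itself comes from the template-length fields of
properly paired reads (one observation per pair), winsorised at the
1st/99th percentiles when at least 100 observations are available so
chimeric pairs cannot distort the moments; an explicit
`--insert-mean/--insert-sd` override bypasses estimation.

Estimates from different platforms can differ by an additive offset
(lower-quality runs depress the boundary signal); `batchCorrect()`
shifts each platform group so group means coincide with the reference
group, preserving within-group contrasts exactly.

## The synthetic-data generator

`generateSample()` builds what the method needs to be tested against,
with full ground truth:

* **telomere constructs** — random subtelomere (1.5 kb) followed by a
  TTAGGG tract of known length; twelve constructs by default, a
  tractable stand-in for the dozens of telomere ends of a real genome.
  The estimator sees only the F1:F2a ratio, so the construct count
  does not move the expected estimate — but it sets the number of
  boundary pairs per sample and hence the sampling noise, and a
  single-digit count would let fixture noise dominate any measurement
  of the method itself;
* **ITR constructs** — a repeat run embedded in 2 kb random flanks.
  ITR fragments are drawn in mirrored twins (reflected about the
  construct midpoint) so the two boundaries contribute exactly matched
  pair counts: the truth-level F2b/F4 cancellation is exact, and what
  remains measurable is how well classification preserves it;
* **decoy** — random sequence exercising the capture filter's
  rejection path;
* **errors and Phred** — a two-level Phred model (39/11, with 10% of
  loci low by default) and substitution/indel errors at a configurable
  per-base rate, a configurable fraction of them forced onto low-Phred
  loci.  This reproduces the low-Phred error hotspot the profiling
  stage must detect.  Note an arithmetic constraint when designing
  fixtures: a read can only *fail* the 90% rule with genuinely
  low-Phred errors if it has more low-Phred loci than the failure
  threshold, so high-error fixtures should raise `lowPhredFrac`
  accordingly (the validation suite uses 0.3).

Reads are emitted as proper SAM pairs with correct flags, mate
positions and template lengths, the reverse mate stored
reference-forward, so the whole pipeline — including insert-size
estimation and orientation recovery — runs unmodified.

What the generator does **not** emulate: real subtelomeres are
repeat-rich rather than random, telomere variant repeats (TTGGGG,
TCAGGG, ...) are absent, Phred values are two-level rather than
continuous, and coverage is uniform with no GC bias.  Passing tests
therefore demonstrate the internal consistency of the method and its
robustness to the modelled artefacts, not its calibration on any real
platform.

## Validation conditions and problem sizes

The validation suite runs the full pipeline at 100 bp reads,
350 ± 30 bp inserts, 50× coverage, 1% error with 90% low-Phred bias:
ten replicate samples at each true length of 2, 5 and 10 kb (recovery
within ±10%), an ITR twin pair where interstitial loci contribute
about half of the apparently telomeric pairs (estimate shift below
5%), a 12-point closed-form grid for the placement simulation, and an
error-profile fixture at 6% error.  These sizes were chosen so the
whole suite completes on a laptop in minutes while keeping
count-statistics noise well inside the asserted bands.

## Known limitations

* The method yields a single mean length; per-chromosome or per-allele
  distributions are out of reach by design, as alignment positions are
  deliberately ignored.
* Samples with telomeres much shorter than the insert size sit in a
  degenerate regime (few or no F1 pairs) where only an upper bound is
  meaningful.
* The refinement rules of the error mask are reconstructions; on data
  whose error profile differs strongly from the low-Phred-hotspot
  shape they were built for, the mask may under-capture and the 90%
  rule then dominates.
* Batch correction requires both platforms in one run (or an explicit
  offset); it aligns means and cannot correct platform effects that
  scale with length.
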