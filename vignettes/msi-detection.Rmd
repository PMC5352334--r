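---
title: "Detecting microsatellite instability from matched tumor-normal pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microsatellite instability from matched tumor-normal pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msipair)
```

## The problem and the model

Microsatellites are short tandem repeats of 1-6 bp motifs scattered
throughout the genome. When DNA mismatch repair is deficient, replication
slippage at these loci goes uncorrected and the tumor accumulates somatic
changes in repeat length — microsatellite instability (MSI). MSI status
matters clinically (MSI-high tumors respond differently to
immune-checkpoint therapy), and sequencing data collected for other
purposes can be reused to call it.

`msipair` calls MSI from a matched tumor-normal pair of alignment files.
The matched normal acts as an error-correcting baseline: systematic
artifacts of library preparation, sequencing chemistry, and alignment
appear in both samples and cancel, so no pooled-normal baseline or
cohort-level calibration is needed.

For each microsatellite locus the package builds, per sample, the
*repeat-length distribution*: how many reads support each observed motif
copy number. After quality control both distributions are normalized to
fractions and compared with a stepwise difference

$$d \;=\; \sum_{r \in R_T \cup R_N} \lvert T_r - N_r \rvert,$$

where $T_r$ and $N_r$ are the normalized fractions of tumor and normal
reads supporting repeat count $r$, and the sum runs over the union of
repeat counts observed in either sample. This is an L1 distance on the
two length histograms: $d = 0$ when the distributions are identical and
$d = 2$ when they share no repeat length. The pair's *aggregate
instability score* is the arithmetic mean of $d$ over all loci that pass
quality control, and a pair is called **MSI-positive when the score
strictly exceeds 0.4** (a score of exactly 0.4 is negative). Averaging
over hundreds to thousands of loci lets the score benefit from the law of
large numbers: individual noisy loci perturb the aggregate only slightly.

Note what the model does *not* do: it never calls individual loci stable
or unstable, and it has no MSI-low category. The per-locus distances are
treated as a continuous instability signal and pooled.

## Pipeline stages and their assumptions

1. **Locus realignment.** Input BED files disagree about 0- versus
   1-based starts, so each locus is re-anchored by searching offsets
   $\{0, -1, +1\}$ for the motif and then extended to the maximal run of
   whole motif copies. Displacements beyond one base are treated as data
   errors and the locus is excluded, rather than silently repaired:
   a ±1 window fixes indexing-convention mismatches but cannot turn a
   wrong annotation into a plausible one. Re-maximizing the run after
   anchoring makes the truncation test below well defined.
2. **Read extraction.** Only reads whose aligned span fully contains the
   locus plus one anchor base on each side are used; unmapped, secondary,
   supplementary and duplicate-flagged reads are excluded. A read that
   does not span the whole run cannot yield a complete repeat count.
3. **Stage-1 read QC.** Reads shorter than `min_read_length` or with
   mean base quality below `min_read_quality` are dropped (strict `<`;
   a read exactly at a threshold passes).
4. **Repeat counting.** The locus start is projected through the
   alignment (CIGAR) into read coordinates, the first motif copy is
   located by exact match within ±2 bases, and maximal consecutive whole
   copies are counted; partial trailing copies are floored. Matching is
   deliberately exact, with no CIGAR-guided repair inside the run:
   insertions and deletions in the run *are* the signal. Reads whose run
   abuts either read end are rejected (`truncated_run` — the run may
   continue past the read), as are reads whose mean base quality over
   the run falls below `min_locus_quality`.
5. **Distribution QC.** Within each sample's distribution, repeat
   lengths more than `outlier_sd` (default 3) support-weighted standard
   deviations from the support-weighted mean are discarded as outliers —
   once, not iterated to convergence, because iterative trimming changes
   the statistic being computed. The weights are read counts and the
   variance uses the population ($n$) denominator: the distribution
   itself is the object of interest, not a sample from it. Coverage is
   then checked *after* outlier removal — both samples must retain
   `min_locus_coverage` reads — so outlier stripping can disqualify a
   locus. Loci with an empty post-QC distribution in either sample are
   discarded as `no_support`, since the distance is undefined there.
6. **Scoring.** Normalize, compute $d$ per locus, average over passing
   loci only (discarded loci leave both numerator and denominator),
   classify. Per-locus computations are independent, so locus order can
   never change a result.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_read_length` | 35 | bases | drop short reads that carry little flank context |
| `min_read_quality` | 20 | mean Phred | whole-read quality gate |
| `min_locus_quality` | 25 | mean Phred | quality gate over the repeat run itself |
| `min_locus_coverage` | 20 | reads/sample | minimum post-QC support per sample |
| `outlier_sd` | 3.0 | SD multiplier | repeat-length outlier rule |
| `flank` | 1 | bases | anchor bases required around the locus |
| `search_window` | 2 | bases | motif-start search around the projected position |
| `threshold` | 0.4 | score | MSI-positive decision boundary (strict `>`) |

The read-level defaults follow whole-exome practice; the outlier rule
and threshold are the method's own constants. All are overridable via
`msi_config()`, but the threshold interacts with panel composition:
moving it should be justified with a labeled cohort and
`threshold_sweep()`.

## The microsatellite scanner

`scan_reference()` catalogs every maximal run of a primitive 1-6 bp
motif in a reference genome. Defaults require 6 copies for homopolymers
and 3 for units of 2-6 bp: homopolymer runs shorter than ~6 bases are
ubiquitous and carry little instability signal, while multi-base repeats
are rare enough to catalog from 3 copies. A run is reported exactly once,
under its primitive motif — `ACACAC` is `(AC)3`, never `(ACAC)1` — with
left-anchored start and whole-copy count; ambiguous bases terminate runs.
Only the forward strand is scanned, because reads are reference-aligned
and both strands observe the forward-strand motif. Compound and
interrupted microsatellites are out of scope.

## Locus ranking across a labeled cohort

With per-pair results and gold-standard labels, each locus gets a
*difference of averages*

$$a \;=\; \frac{\sum_{i \in H} d_i}{|H|} - \frac{\sum_{i \in S} d_i}{|S|},$$

the mean distance among MSI-H pairs covering the locus minus the mean
among MSS pairs covering it, and a *locus score* $l = a\,c^2$, where
$c$ is the proportion of pairs in which the locus passed the same
coverage QC used in scoring. Squaring $c$ demotes rarely evaluable loci.
Pairs in which a locus failed QC are excluded from the means rather than
imputed as zero — absence of coverage is not evidence of stability. Ties
in $l$ break by higher $c$, then genomic order, so rankings are
deterministic; loci with undefined $a$ (no covering pair of one label)
rank last.

## Evaluation statistics

`confusion()` / `metrics()` compute sensitivity, specificity, error rate
(incorrect calls / total calls) and accuracy (1 − error rate) against
gold labels, reporting any metric with a zero denominator as undefined
rather than zero. Confidence intervals use the Wilson score interval
with continuity correction, clipped to $[0,1]$; the continuity-corrected
form stays sensible at the small cohort sizes and extreme proportions
typical of MSI panels (e.g. 38/38 correct). `threshold_sweep()` scans a
threshold grid (the conventional sweep is 600 thresholds from 0.001 to
0.6) and reports the accuracy-maximizing threshold, ties resolved to the
smallest for determinism.

## What the simulator emulates — and what it does not

`make_reference()` plants known microsatellites in seeded random
background. Flanking bases are constrained so a planted run can neither
extend nor re-phase into background (the base before the run never
equals the motif's last base, the base after never its first), and any
background run that the scanner would report is broken by point
substitution — so the planted BED is provably the exact scan result.
`simulate_pair()` then draws per-read repeat counts from configurable
per-locus distributions and writes coordinate-sorted indexed BAMs whose
reads embed the drawn run between real reference flanks, with CIGARs
encoding the indel relative to the reference run. Reads are written
pre-aligned rather than run through an external aligner: the caller
consumes alignments and the method is aligner-agnostic, so this removes
a heavy dependency while keeping the ground truth exact. By default base
errors are never injected inside the run, so the drawn distributions are
exactly recoverable (`errors_in_run = TRUE` enables a robustness mode).

The simulator deliberately omits: PCR stutter (the dominant real-world
noise process at microsatellites, which blurs normal-sample
distributions), alignment ambiguity and soft-clipping near runs, GC and
fragment-size biases, capture efficiency differences, and contamination.
Passing tests on simulated data therefore demonstrate the *algorithmic*
contract — exact score endpoints, QC behavior, recovery of planted
truth — not robustness to every artifact of real exomes. On real data
the normal-vs-tumor design absorbs much of the shared noise, but that
property is exactly what cannot be proven on idealized reads.

Default simulation conditions are fixed once: depth 50 reads per sample
per locus, read length 100, base quality ~35, point-mass normal
distributions at the reference repeat count; divergent tumors move half
their mass two repeat units down, giving an expected per-locus distance
of 1.0 — far above the 0.4 threshold but well short of the ceiling.

## Numerical choices and degenerate inputs

- A score exactly at the threshold is MSI-negative (strict `>`).
- A single observed repeat length has $\sigma = 0$; nothing is removed.
- Empty distributions cannot be normalized; such loci are discarded
  upstream with reason `no_support`, and a pair with *zero* passing loci
  is a hard error ("no evaluable loci"), not a score of 0.
- File outputs round to 6 decimals; all internal arithmetic is double
  precision. Depth invariance (scaling either sample's counts by any
  positive integer) holds to 1e-12 by construction of the
  normalization.
- Motif-start search examines offsets ordered by absolute value
  (0, −1, +1, −2, +2) and takes the first exact match, then left-anchors
  by whole copies, so the counted run is reproducible regardless of
  projection jitter from nearby indels.

## Problem sizes in the test suite

The packaged tests run entirely on simulated data: genomes of 4000 bp
chromosomes with 3-50 planted loci, depths of 12-50 reads per sample per
locus, and cohorts up to 20 pairs x 50 loci. These sizes keep the whole
suite in the low minutes on a single core while still exercising every
stage end to end; all statistical checks (score endpoints, oracle
equivalence, perfect cohort classification, ranking recovery) are exact
or near-exact at these depths, so larger simulations would add runtime,
not information.

## Known limitations

- Score quality depends on coverage in *both* samples; shallow normals
  silently shrink the evaluable locus set (watch `n_discarded`).
- Exact motif matching inside the run means a sequencing mismatch within
  the run truncates the count at the error; with error-free flanks this
  biases counts down slightly at high error rates. The effect is shared
  by tumor and normal and largely cancels in $d$.
- Homopolymer-adjacent errors can extend a run by one unit; the outlier
  rule catches gross cases only.
- No MSI-low category and no per-locus calls, by design.
- The ranking statistic assumes the cohort's labels are correct and
  benefits from balanced label counts; with very few labeled pairs of
  either class, $a$ is noisy and $c^2$ weighting dominates.
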