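---
title: "Methods: rearrangement concordance between paired tumor genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rearrangement concordance between paired tumor genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svconcord)
options(svconcord.quiet = TRUE)
```

## The problem

Two tumors from the same patient — a primary and a distant metastasis, or
two metastases — descend from a common clone. Chromosomal rearrangements
acquired before their divergence are carried by both; events acquired after
are sample-specific. Because a rearrangement is identified by two breakpoint
coordinates, the shared fraction can be estimated directly from two
per-sample structural-variant catalogues, without matched normal DNA and at
low sequencing coverage. This package implements that estimation and the
analyses built on it.

The central difficulty at low coverage is asymmetric detection: an event
clonal in one tumor but subclonal in the other may fall below the caller's
support threshold in the second sample and be misread as sample-specific.
The classification therefore has three passes of decreasing stringency:

1. **Direct matching.** Two catalogue events match when their chromosome
   pairs are identical and both breakpoints agree within a ±500 bp window.
2. **Rescue.** A still-specific event is searched for in the partner
   sample's *raw* (unfiltered) call list; one sub-threshold call (support
   ≥ 1 read pair) at matching coordinates reclassifies it as shared.
3. **Look-up.** Finally the partner's discordant read-pair evidence is
   queried; a single read pair whose mates fall within the window of both
   breakpoints suffices.

An event recovered by rescue or look-up is, by that evidence, present in
both samples; it therefore counts toward both samples' totals even though it
appears in only one catalogue. With that accounting each sample's total
equals `shared + specific`, directional similarity is
`100 · shared / total`, and the combined similarity is
`100 · shared / (total_a + total_b − shared)`.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| matching window `w` | 500 | bp | read-pair callers localize breakpoints to within a few hundred bp at typical insert sizes; the boundary is inclusive (`|Δ| ≤ 500`) so the rule is deterministic |
| support threshold | `max(2, ⌈coverage/3⌉)` | read pairs | one third of the sequence coverage (3 read pairs at 9×); the floor of 2 avoids single-read calls at very low coverage |
| minimum intrachromosomal span | 7000 | bp | deletions/inversions/intra-chromosomal events smaller than 7 kb are dominated by library-insert artifacts; the rule is strict (`span < 7000` removed, 7000 retained) and exempts interchromosomal events |
| CN ploidy | 2 | copies | states are compared categorically (loss/normal/gain against ploidy) rather than as exact CN levels, which is robust to caller level noise; exact-level comparison is available via the `ploidy` argument and window tables |
| density bandwidth | 10 000 | bp | the Gaussian kernel σ of the breakpoint density; matched by a 10 kb evaluation grid |
| hotspot threshold | 3·10⁻⁶ | per bp | applied to the genome-wide normalized track |
| enrichment simulations | 10 000 | draws | empirical two-sided p values are reported as `2·tail/n`; a zero tail is a bound (`< 2/n`), never 0 |

## Numerical and design choices

**Coordinates.** 0-based breakpoint positions and half-open intervals
everywhere inside the package (BED/BEDPE native); 1-based caller dialects
are converted at the I/O boundary only. Events are canonicalized so the left
breakpoint precedes the right under (chromosome order, position); SV type
labels are corrected from coordinates (interchromosomal ⇒ CTX) because
caller labels are unstable between samples, and type labels are deliberately
*not* required to agree during matching.

**Greedy one-to-one matching.** Candidate pairs are taken in ascending
summed two-side distance, ties broken by the lower partner coordinates, each
event used at most once. Greedy matching is not guaranteed maximal, but at
realistic event densities (hundreds of events over tens of Mb, window
500 bp) collisions are rare: the test suite checks 1000 random fixtures
against an exhaustive maximum bipartite matching and allows a total
shortfall of at most a handful of events; in practice the greedy solution
attains the optimum.

**Percent rounding.** Reported percentages round half away from zero
(94.5 → 95) at reporting time only; unrounded values stay available. A
similarity with a zero denominator is `NA` with a warning — undefined, not
0%. Note one consequence for cohort medians of count columns: the median of
the 13 per-comparison primary-specific ("lost") counts in the bundled
example cohort is 9, while the median of the specific column over all 30
directional rows is 9.5 and prints as 10 in a rounded summary row; the
summary emits both.

**Conditional likelihood.** The probability that a primary-tumor
rearrangement is found in the metastasis is emitted in two aggregations that
do not coincide: pooled (`Σ shared / Σ primary totals`, 0.900 on the example
cohort) and per-comparison mean (0.859). Neither is privileged.

**Non-redundant catalogue.** Events across samples are single-linkage
clustered under the windowed match: chains can join members farther apart
than one window; this is accepted (and logged) because transitive identity
is what "the same rearrangement seen in several samples" means here. The
cluster representative is the member with the (lower) median left
coordinate.

**Clustering.** The presence/absence matrix is compared with the asymmetric
binary (Jaccard) distance — rows with an empty union are at distance 0 — and
clustered with classic Ward linkage (`hclust`, `ward.D`) applied directly to
that distance matrix. Ward's method formally assumes squared Euclidean
input; it is used here on the binary distance for fidelity to the standard
practice for barcode matrices, and the pairing property it must deliver
(true pairs merge before any cross-patient merge) is what the tests assert.

**Density track.** The kernel density is computed per chromosome (so no
kernel mass leaks across chromosome boundaries), each chromosome weighted by
its share of breakpoints, and the concatenated track is renormalized to a
genome-wide trapezoid integral of exactly 1; both ends of every
rearrangement contribute a breakpoint. Hotspots are maximal grid runs
strictly above the threshold, snapped to the grid, and two runs separated by
one sub-threshold point are not merged.

**Genic areas.** A gene's area extends from 2 kb upstream of its
transcription start (strand-aware, inclusive at exactly 2000 bp) through its
3′ end. Random breakpoints for the genic null avoid the genome masks,
mirroring the catalogue filters (configurable off).

**Cancer-gene null.** Draws of `|affected|` genes are made without
replacement from the annotated universe, so the null is hypergeometric; the
tests verify the simulated null against the closed-form pmf by chi-square
goodness of fit, and that the two-sided empirical p is super-uniform under a
true null.

## What the generator emulates — and what it does not

`simulatePatient()` + `renderObserved()` produce what a read-pair caller
would report for a clonally related pair under the study-like defaults:
100 somatic events in the primary, 89% retained by the metastasis, 14
metastasis-private events, 10 germline events shared with a normal pool,
physical coverage 22.3× / sequence coverage 9.3×, on a 5 × 50 Mb genome.
Per-event read support is Poisson with mean physical coverage × clonal
fraction, clonal fractions are Beta(5, 2) (a right-skewed choice: most
events are clonal, a tail is subclonal; exposed in the config), and observed
coordinates get independent Gaussian jitter per sample per breakpoint
(σ = 100 bp by default, a read-pair caller's typical localization spread).
A configurable 10% of shared events are forced sub-threshold in the
metastasis (exercising rescue) and 5% are observable only in its read-pair
evidence (exercising look-up). Germline events are fully clonal in every
sample, so their support is maximal and their breakpoint estimates
effectively deterministic; they are reported un-jittered, which is what
makes the pool filter remove them reliably.

CN profiles are piecewise constant with a common segmentation for the pair;
a configured fraction of aberrant segments is shared (same state), the rest
alternate between the two samples, so the event-based CN similarity of a
generated pair equals the configured sharing up to rounding — a direct
recovery oracle. The synthetic annotation lays non-overlapping genes whose
extended footprints cover exactly the configured genome fraction (0.433 by
default), with log-normal lengths and random strands.

Not emulated: read-level data (no FASTQ/BAM), microhomology or
replication-mechanism signatures at breakpoints, chromothripsis-like spatial
clustering of events (placement is uniform), CN-correlated breakpoint
positions, and tumor purity/contamination. Passing tests therefore
demonstrate the correctness of the classification and statistics under the
stated generative model, not caller performance on real reads.

## Problem sizes in the test suite

The suite runs entirely on synthetic or bundled plain-text data: matcher
oracle equivalence on 1000 fixtures of ≤ 30 events; end-to-end
shared-fraction recovery over 20 seeds × 100 events (the average estimate
must fall within ±3 points of the configured 89%); genic-null calibration
with 2000 simulations of 1000 breakpoints; hypergeometric goodness of fit
with 10 000 draws; p-value super-uniformity over 200 replicate analyses;
and a 6-patient cohort for the clustering property. These sizes keep the
whole suite under a minute on a single core while leaving the statistical
checks well-powered.

## Limitations

Orientation/strand of rearrangement ends is not modelled, so a deletion and
a tandem duplication with coincident breakpoints are not distinguished;
matching is purely coordinate-based. The greedy matcher can in principle
fall one pair short of the maximum matching in adversarial collision
configurations. CN similarity compares categorical states at a fixed ploidy
and does not model subclonal mixtures or purity. The pipeline assumes
catalogues from a single caller dialect per run; cross-caller harmonization
is out of scope, as is breakpoint refinement from split reads.
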