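---
title: "Classifying autonomous super-enhancers from multi-factor occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying autonomous super-enhancers from multi-factor occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asescope)
```

## The procedure

asescope classifies regulatory elements in four stages.

**1. Active enhancers.** DNase-seq peaks are kept when they overlap (≥ 1 bp)
an H3K27ac ChIP-seq peak and dropped when any base of the peak lies within
±2.5 kb of a transcription start site. The retained DNase peaks — accessible,
acetylation-supported, promoter-distal — are the enhancer universe for all
downstream stages. `call_active_enhancers()` records the count surviving
each filter as provenance.

**2. Occupancy score.** For every enhancer and every TF/cofactor ChIP-seq
dataset, the peak signal value at the enhancer is recorded (0 when the
factor has no overlapping peak) and min–max normalized per factor. The
occupancy score multiplies the number of bound factors by the sum of
normalized signals, `OS(E) = N_E × Σ_f Signal_E(f)`, so an enhancer is
rewarded both for binding breadth and for binding strength. Histone marks
are excluded from the matrix by construction — the score measures factor
occupancy, not chromatin state. Enhancers are ranked by OS and cut at the
ranked curve's inflection point; everything strictly above the cutoff is
"super-high occupancy".

**3. Classic SE comparison.** Independently, `rose_classic_se()`
re-implements the ROSE procedure on the H3K27ac peaks alone: stitch peaks
within 12.5 kb (no TSS exclusion inside the stitching step, matching ROSE's
`tss_exclusion_zone_size = 0` default), rank stitched regions by total
signal, cut at the same inflection criterion. Crossing the two binary calls
(high occupancy × inside a classic SE region) yields the four-way partition
aSE / dSE / cSE / rEh.

**4. Characterization and prediction.** Footprint statistics, anchoring-TF
calls, loop clustering and the signal-ranking predictor all operate on the
classified enhancer table; they are described below where their parameters
matter.

## The inflection cutoff

The cutoff rule is the piece most open to interpretation, so it is worth
stating precisely. Sort the n values ascending as y(1..n) and define the
reference slope `s* = (max − min)/n` — the slope of a line spanning the
whole ranked curve, as in ROSE's tangent construction. Discrete slopes are
central differences over a half-window of ranks (default 1, exposed as
`half_window`). Scanning from the low end, the cutoff sits at the last rank
before the discrete slope first exceeds `s*` — the point where the curve
takes off from its own chord. Two degenerate cases follow from the rule: a
constant curve has reference slope 0 and never takes off, so the cutoff is
the constant and nothing lies above it; a curve at least as steep as its
chord from the very first rank (e.g. strictly linear) has no elbow, so the
cutoff is the top value and nothing is called.

We considered the alternative reading "the greatest rank anywhere on the
curve whose slope is ≤ s*". Both readings agree on clean two-regime curves,
but the global variant is fragile on noisy data: three near-tied values high
in the super tail produce a local slope below `s*` and would drag the cutoff
into the super cluster. The first-crossing scan never does this, which makes
the classification stable across seeds; it errs, when it errs, toward
calling more enhancers super rather than fewer.

The predictor's **two-step cutoff** applies the same rule twice: once
globally, then again restricted to the scores at or below the global cutoff,
re-using the global cutoff value as the new maximum in the reference slope.
The local cutoff is the prediction threshold and can never exceed the global
one (the restricted curve's values are bounded by it).

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `tss_exclusion_bp` | 2500 | bp | promoter exclusion half-width; any bp overlap between peak and the closed TSS window removes the peak (edge-to-point distance; a `center` mode is available) |
| `stitch_distance` | 12500 | bp | ROSE default stitching distance |
| overlap window (loops) | 1000 | bp | `bedtools window` default gap used when intersecting loop arms with enhancers/TSSs; all other overlaps use window 0 |
| `aggregate` | `max` | — | several peaks of one factor on one enhancer collapse to the maximum signal; max is robust to peak fragmentation (sum/mean available) |
| `half_window` | 1 | ranks | central-difference width for discrete slopes |
| `fpkm_min` | 2 | FPKM | strict threshold defining expressed target genes |
| anchoring thresholds | 50 / 50 | % | a TF anchors a class when it binds > 50 % of the class's peaks and > 50 % of bound peaks carry a matching-DBD footprint; both strict |

Numerical conventions worth knowing: min–max normalization maps a constant
factor column (including all-zero) to all-zero rather than all-one, so a
ubiquitously equal factor adds no weight; `N_E` counts raw > 0, so the
factor whose minimum bound signal becomes 0 after normalization still counts
as bound; predicted positives and super calls always use strict `>` against
the cutoff; DBD bitscore ties break to the lexicographically smallest family
name so the pipeline is deterministic; inter-footprint gaps are edge-to-edge
distances floored at 0 (a midpoint mode exists); footprints straddling an
enhancer boundary count fully in every enhancer they touch, with unclipped
widths. Loop "contacts" are read from BEDPE column 8 and consumed as given.
Trans-chromosomal loops are accepted into clusters, but a cluster spanning
several chromosomes reports `NA` span. Cluster labels are non-exclusive: one
cluster can simultaneously be aSE-, dSE-, cSE- and rEh-containing.

Where a convention was genuinely open — multi-peak aggregation, the
combination rule for two predictor signals (default: sum of min–max
normalized signals; minimum and product available), TSS distance measured
from the peak edge rather than its center — the default is the reading we
judged most robust, and the alternatives sit behind flags so the choice is
auditable.

## What the synthetic generator emulates

`simulate_bundle()` produces every input the pipeline consumes, with planted
truth. Its defaults are the study conditions for all recovery tests:

- class fractions 5 % aSE-like, 2 % dSE-like, 13 % cSE-like, 80 % rEh over
  400 enhancers on two 50 Mb chromosomes;
- factor binding probabilities 0.85 for the high classes, 0.45 for cSE,
  0.25 for rEh across 12 factors; log-normal signals with a +1.5 log-scale
  location shift for high classes;
- cSE/dSE-like enhancers placed in stitchable runs of 4 (gaps of 2–8 kb,
  well under 12.5 kb) with strong H3K27ac, so the classic-SE caller can
  recover them; aSE-like enhancers isolated, more than 1 Mb from any run;
- promoter-proximal decoy peaks (5 %) planted inside the TSS exclusion zone
  and DNase-only background peaks (10 %) without H3K27ac support, so both
  filters have something to catch;
- footprint counts Poisson(6) versus Poisson(2) with widths 18 ± 3 versus
  12 ± 3 bp; loop degree 5 versus 1 with contacts 1 + Poisson(8) versus
  1 + Poisson(2); expression log-normal with a +1.0 shift for genes looped
  to high-class enhancers.

The genome is tiled into 2 Mb blocks: each run and each isolated aSE claims
one block, and the remaining enhancers spread over the other blocks on a
coarse grid (≥ 14 kb spacing) that prevents accidental stitching into
run-sized regions. All randomness flows from one seed; the same seed
reproduces the bundle byte-for-byte, and the generator restores the caller's
RNG state.

The generator's claim is structural, not distributional: it plants the
*separations* the analysis assumes (class-dependent binding breadth and
strength, stitchable versus isolated placement, loop preference, expression
shift). It does not model read-level noise, peak-caller artifacts,
copy-number bias, chromosome-scale covariates, or realistic genome sequence
— so passing recovery tests demonstrates that the pipeline's machinery is
correct and well-calibrated for separable input, not that real datasets are
this separable. On real data the class boundary depends on how many factor
datasets are available, and classifications built from few factors are
correspondingly less definitive.

## Test problem sizes

Unit tests run on a 120-enhancer / 6-factor bundle; recovery tests use the
default 400-enhancer configuration over five fixed seeds; engine-equivalence
tests compare each core operation (overlap, stitching, cluster components,
occupancy scores, inflection cutoffs, AUC) against literal brute-force
re-implementations on 1 000 random small instances apiece. These sizes give
each property enough replication to be meaningful while keeping the whole
suite comfortably fast on one CPU.

## Known limitations

- Region signal in the classic-SE caller is the sum of member-peak
  signalValues; the original ROSE integrates read density from alignments,
  which is out of scope here (peak files are the package's input substrate).
  Rankings are internal, so the comparison is self-consistent.
- The rank-sum test uses exact enumeration only for tie-free samples of at
  most 8 per group, and the tie-corrected normal approximation otherwise.
- Motif annotations on footprints are consumed as given; no motif scanning
  or footprint re-calling is performed.
- GC/CpG composition requires user-supplied sequences; conservation scoring
  (external genome tracks) is not implemented.
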