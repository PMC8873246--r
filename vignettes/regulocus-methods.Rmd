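---
title: "Methods: locus-scale regulatory analysis with regulocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-scale regulatory analysis with regulocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulocus)
```

## Scope and model

regulocus implements the locus-scale analyses used to dissect a clustered
gene locus controlled by a super-enhancer (SE): the fast-myosin paradigm,
in which a single distal SE contacts the promoter of exactly one *Myh*
gene per myonucleus. Four analyses are covered, each usable alone:

1. **Fragment maps** — in-silico digestion of a contig by a first cutter
   (DpnII-style `^GATC`), with blind-fragment annotation from a second
   cutter (NlaIII-style `CATG`), as in double-digest 4C designs.
2. **4C tracks** — viewpoint masking, reference-region normalization,
   running-mean smoothing and between-condition log-ratios of
   per-fragment contact profiles.
3. **Differential contact** — a fragment-sign G-test comparing the SE
   region against the remainder of its TAD between two conditions.
4. **SE calling and nucleus classification** — ROSE-style stitching and
   hockey-stick cutoff on peak signal, and QC plus promoter-accessibility
   fiber-type assignment of single nuclei.

A synthetic-locus generator stands in for deposited sequencing data, so
every pipeline stage is exercised end to end with no download.

## Coordinates

All internal computation is zero-based half-open (BED). Publication-style
region strings (`"chr11: 67,103,534–67,145,377"`) are one-based inclusive
and are converted exactly once by `parse_region()`; that SE region has
width `r interval_width(parse_region("chr11: 67,103,534–67,145,377"))` bp,
the "42-kb" element. BED input is never shifted.

## 4C track construction

Counts are assigned to the unique fragment containing each position
(half-open rule). The stages are enforced in order:

* **Masking** (`mask_viewpoint`, margin 2,000 bp): the viewpoint fragment
  and every fragment overlapping the ±margin window become missing, not
  zero — undigested/self-ligation signal near the viewpoint is
  uninformative about looping.
* **Normalization** (`normalize_to_region`, scale 10⁶): one multiplicative
  factor per profile makes the summed unmasked signal over the reference
  region (typically the TADs surrounding the locus) equal the scale
  constant. The reference membership of a fragment is decided by its
  midpoint, which is unambiguous for boundary-straddling fragments. A
  single scale factor is the simplest reading of "normalization to" a
  region and makes conditions comparable; it is exactly equivariant under
  uniform rescaling of the raw counts.
* **Smoothing** (`running_mean`, 11 fragments): the window is defined in
  fragment-index space. At contig edges the half-width shrinks
  symmetrically to the available fragments, so constants and linear ramps
  pass through unchanged and no data are invented beyond the contig;
  masked fragments stay masked and never enter a neighbour's mean.
* **Ratios** (`ratio_track`): log2 with pseudocount 1 (in per-million
  units). The pseudocount choice is a display decision only; the
  statistical test never consumes ratios.

The differential test deliberately consumes *normalized, unsmoothed*
values: smoothing correlates neighbouring fragments and would invalidate
the fragment-level contingency counts. The stage field makes this a hard
error rather than a convention.

## Differential contact: fragment signs and the G-test

For two normalized profiles, each fragment is classified as increased,
decreased or tied (ties carry no directional evidence and are excluded;
the default tie tolerance is 0, i.e. exact equality only, appropriate for
continuous normalized values). Masked fragments are excluded from the
test as well as from display; re-run `mask_viewpoint` with `margin_bp =
0` to keep margin fragments in the test. The 2×2 table counts directions
for fragments with midpoints in the SE region versus the remainder of the
TAD, and

$$G = 2 \sum_{ij:\,O_{ij}>0} O_{ij}\,\ln(O_{ij}/E_{ij}),\qquad
E_{ij} = \frac{r_i c_j}{N},$$

is referred to the upper tail of $\chi^2_1$. A zero row or column margin
is reported as a degenerate (uninformative) comparison, not as a
p-value. The Williams correction ($G/q$ with
$q = 1 + (N/r_1 + N/r_2 - 1)(N/c_1 + N/c_2 - 1)/(6N)$) is available but
off by default. Under the generator's null (no loop), the test's type-I
error at $\alpha = 0.05$ is 3–7% over 1,000 simulated pairs; with the
default planted loop it rejects essentially always at depth 10⁵
(both measured by the acceptance suite).

## Super-enhancer calling

Peaks are stitched by transitive closure of "gap ≤ 12.5 kb", signals
summed (conserved exactly), and regions ranked. For the cutoff, signals
are sorted ascending and scaled with their ranks to the unit square; the
cutoff sits after the **last** forward-difference slope ≤ 1, i.e. the
point past which the curve's slope stays above 1, and regions strictly
above the signal there are super-enhancers. On a convex hockey-stick
curve this is exactly the classic slope-1 tangent rule; on noisy finite
landscapes the "stays above" refinement is essential — taking the *first*
slope > 1 on ~30 i.i.d. background regions calls most of them super
(order-statistic gaps fluctuate around the mean slope of 1), while the
sustained-slope rule calls ~2. Ties in ranking break toward the earlier
genomic coordinate; the cutoff is invariant to uniform signal rescaling.
No promoter-proximal exclusion is applied before stitching (none is part
of the modelled analysis); callers may pre-filter their peak set.

## Nucleus QC and fiber-type classification

QC keeps a nucleus iff all six strict inequalities hold:
`peak_region_fragments` > 3,000 and < 100,000, `pct_reads_in_peaks` > 15,
`blacklist_ratio` < 0.025, `nucleosome_signal` < 10 and
`tss_enrichment` > 2 — a literal reading of the printed thresholds, so a
value sitting exactly on a threshold fails. Promoter accessibility scores
are per-nucleus proportions of window counts (invariant to sequencing
depth); classification assigns the top gene when it dominates the
runner-up by the margin (default 2.0), labels `hybrid` otherwise and
`unassigned` when no window has signal. The margin and the promoter
window definition (2 kb upstream + 500 bp downstream of the TSS, with the
gene body included in the synthetic windows) are package decisions — the
modelled study reports single-gene myonucleus classes without printing a
rule. Clustering/embedding pipelines are deliberately not reimplemented;
classification is rule-based and auditable.

## The synthetic world

`sim_config()` fixes one stated world; its defaults are not tuned per
test:

* **Genome**: one 500 kb contig, five 100 kb TADs, cutter sites planted
  with gamma(shape 4) spacings of mean 500 bp (typical 4-cutter fragment
  size). The background is scrubbed of accidental cutter motifs so
  digestion tests are exact; secondary-cutter sites are left random, so
  roughly 20% of fragments are blind at these defaults.
* **Locus**: a cluster of 4 genes at the focal TAD start (TSS every
  8 kb), SE of width 41,844 bp (mirroring the printed 42-kb element)
  within the same TAD, viewpoint at the promoter of the most distal gene
  (resolved to its full fragment, so it always overlaps exactly one
  fragment).
* **4C**: expected counts follow $(|d|+d_0)^{-\alpha}$ with $\alpha = 1$,
  $d_0 = 1$ kb, total depth $N = 10^5$; negative-binomial noise with size
  $\theta = 10$ (Poisson in the $\theta \to \infty$ limit, which the
  tests exercise); the loop multiplies SE-fragment weights by
  $1 + \beta$ ($\beta = 1$ by default) in the active condition only. The
  power-law decay is an emulation choice — no decay model is asserted
  about any real dataset.
* **Enhancer landscape**: 30 isolated background peaks (kept > 12.5 kb
  apart so they never stitch) with gamma(shape 20, mean 50) signal — a
  moderately homogeneous typical-enhancer landscape — plus 7 planted
  peaks inside the SE at 10–20× the background mean with gaps well under
  12.5 kb.
* **Nuclei**: classes of 64/59/249/495 nuclei (the reported myonucleus
  class sizes); multinomial promoter counts with 10-fold mass on the own
  class promoter (1 = uninformative); ~300 window fragments per nucleus;
  10% of nuclei planted as QC violators, each violating one random rule,
  so the failing fraction equals the planted fraction.

What a green test does **not** establish: real 4C libraries have
self-ligation artifacts, blind-fragment dropout, mappability gaps and
condition-dependent decay that the generator does not emulate; real
H3K27ac landscapes are heavier-tailed than the background used here; real
snATAC nuclei include doublets and ambient contamination. Green means the
algorithms are correct on data satisfying their assumptions, not that any
biological claim is reproduced.

## Numerical choices and degenerate inputs

* Zero-length fragments from a cut at position 0 are dropped; `N` bases
  never match a motif.
* `sum(lambda) = N` is exact to 1e−9 relative before sampling.
* G is clamped at 0 against rounding on proportional tables; cells with
  zero observed count contribute nothing.
* All-equal signal landscapes yield zero super-enhancers with a warning;
  fewer than 3 regions is an error.
* Out-of-bounds count records are dropped with a warning; totals of
  retained records are conserved in exact integer arithmetic.
* Determinism: every generator takes a seed (defaulting to the config
  seed), and a fixed seed gives bit-identical FASTA/BED/TSV output.

## Known limitations

Single-contig simulation only; no multi-viewpoint joint modeling; no
FDR across loci (the test is a single-locus comparison by design); the
sign test treats fragments as exchangeable units and inherits the usual
caveats of dichotomizing paired signal.
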