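---
title: "Delineating 4C interaction domains: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating 4C interaction domains: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourcdomains)
```

This vignette is the package's account of its methods: what each stage
computes, which assumptions it makes, which parameters matter and why their
defaults are what they are, and where the design was genuinely open.

## Coordinates

Everything internal is 0-based, half-open (`[start, end)`), the BED
convention, which makes interval arithmetic (splitting at breakpoints,
adjacency of restriction fragments) free of ±1 bookkeeping. Published locus
coordinates are 1-based inclusive; `from_1based()`/`to_1based()` convert at
the boundary, and the YAML rearrangement-config reader applies the conversion
itself so that config files can be written in the publication convention.

## From reads to a profile

A 4C library measures, for one *viewpoint* restriction fragment, how often
every other fragment was ligated to it. The pipeline is deliberately plain:

1. **Demultiplexing** is an exact 5′-prefix match of 3–6 nt inline tags, no
   mismatch tolerance. Exactness keeps assignment deterministic and
   order-independent; the cost (a small fraction of unassigned reads in real
   data) does not bias fragment counts. Tag sets must be mutually
   prefix-free, which is validated when the viewpoint table is built, not
   per-read.
2. **Counting** assigns each aligned position (its 5′-most coordinate,
   regardless of strand) to the fragment whose half-open interval contains
   it, by binary search. Counts are per fragment, not per fragment end — the
   coarser of the two conventions; fragment-end counting would be a
   refinement, not a correction.
3. **RPM normalization** divides by the total count on the viewpoint
   chromosome and multiplies by 10⁶, so the normalized track on that
   chromosome sums to exactly one million and libraries of different depth
   are comparable. The viewpoint-proximal reads are included in the
   denominator (the subsequent mask changes summaries, not the scale), a
   choice that keeps the normalization a pure per-library constant.
4. **Masking.** Fragments whose midpoints lie within 10 kb of the viewpoint
   fragment's midpoint are excluded: signal there is dominated by
   self-ligation and undigested templates, not genuine contacts. Fragments
   overlapping user-supplied low-mappability intervals are also masked —
   their zeros are artifacts of alignability, not of chromatin structure.
   Masking is monotone: enlarging the radius or the exclusion set never
   unmasks a fragment.
5. **Smoothing** is an 11-fragment centered running mean, applied *after*
   normalization, truncated at chromosome ends (no padding — padding invents
   signal), and computed over unmasked fragments only, in both numerator and
   denominator. Zero-filling masked fragments would drag the smoothed level
   down exactly where the data are least trustworthy and bias domain calls
   toward excluding low-mappability gaps.

Fragment maps come from in-silico digestion: NlaIII (`CATG`) cuts placed
after the last motif base, DpnII (`GATC`) sites annotated per fragment;
fragments without an internal secondary site are flagged *blind* (they cannot
circularize in the protocol) but are not removed by default — removal is a
filter the user applies knowingly. Both motifs are palindromic, so scanning
the forward strand is complete; `N` bases never match.

## Segmentation and the primary interaction domain

The smoothed profile of a viewpoint shows a plateau of elevated contacts —
the primary interaction domain — falling off to a power-law decay tail. To
delineate it we segment the log₂(smoothed + 1) transformed signal (4C signal
spans orders of magnitude; least-squares segmentation assumes roughly
constant variance, and the log transform is the standard stabilizer) into
piecewise-constant segments.

`fit_piecewise_constant()` is exact: dynamic programming over all changepoint
placements returns the global minimum of the within-segment sum of squares
for a given number of segments `k`, with ties broken deterministically toward
the leftmost changepoints. Cost is O(n²k), trivial at fragment-track sizes
(hundreds of points). Exactness is the module's contract — the test suite
checks it against exhaustive enumeration of all placements for small inputs —
because heuristic segmenters fail exactly where domain edges are subtle.

`select_segments()` picks `k ≤ k_max` (default 12) minimizing
`n·log(SSE(k)/n + ε) + λ·k·log(n)` with `λ = 2` (a BIC-type penalty for
Gaussian residuals) and `ε = 10⁻⁸` guarding the noiseless SSE = 0 case, where
the criterion then prefers the smallest adequate `k`.

`call_primary_domain()` then works in three steps:

* **Background.** The median smoothed signal over unmasked fragments farther
  than `background_distance` (default 1 Mb — beyond the scale of a single
  locus) from the viewpoint. On chromosomes too short to have any such
  fragments, the most distant quartile of unmasked fragments is used instead;
  the median makes this robust even when that quartile clips a domain edge.
* **Segment run.** The maximal run of contiguous segments containing the
  viewpoint whose means (on the original smoothed scale) exceed a threshold.
  The threshold is `threshold_factor × background` (default 3×) guarded from
  below by `sqrt(background × viewpoint-segment mean)` — the geometric
  midpoint between background and the domain's own level. The guard matters
  because a power-law decay tail just outside a domain edge sits near 3× the
  distal background for typical decay exponents, so a fixed multiple alone
  occasionally admits a tail segment and overshoots the edge by tens of
  fragments; the geometric midpoint is scale-free, sits far above any tail
  segment when the domain is strong, and reduces to the plain
  `threshold_factor` rule for weak domains (viewpoint level below
  `threshold_factor² ×` background), where it is inert.
* **Edge refinement.** An 11-fragment running mean turns a sharp domain edge
  into an 11-fragment ramp, and ramp segments always pass the threshold, so
  the raw segment run overreaches each edge by up to half a window. Each
  boundary is therefore re-located by an exact two-segment fit on the
  *unsmoothed* normalized signal within ±2 half-windows of the run edge,
  accepted only when the two local means are ordered like a domain edge.
  Smoothing detects; the local refit undoes the blur. In the noiseless limit
  the refit recovers a planted step exactly, and at the generator's default
  noise the recovered boundaries match the planted ones to the fragment in
  the large majority of replicates (the acceptance suite quantifies this).

If even the viewpoint's own segment fails the threshold (a flat profile),
that segment is returned with `confidence = "low"` rather than nothing: a
downstream comparison still needs an anchor. The viewpoint fragment itself is
always masked, so the run is anchored at the nearest retained fragment.
Masked fragments are dropped, not interpolated, before segmentation;
interpolation would fabricate signal inside low-mappability gaps, and the
reported interval simply spans the retained fragments' genomic coordinates.

Segmentation settings of the original analyses of this kind are typically
not reported in full, so published domain tables are qualitative references
rather than bit-reproducible targets; all settings here are explicit
arguments with the defaults above.

## Transition zones and topology statistics

Two adjacent viewpoints' domains are compared as plain intervals.
`detect_transition_zone()` reports *overlap* (the intersection — the
transition zone, typically a few tens of kb) when the Jaccard index is below
`merge_fraction`, *gap* when disjoint, and *merged* at or above
`merge_fraction` (default 0.5). The cutoff separates a localized overlap from
wholesale fusion of the two domains, as produced by deleting the TZ; the
published observations distinguish a 10–30 kb overlap from a fused domain but
fix no numeric boundary, so 0.5 — far from both regimes — is our choice.

`cumulative_asymmetry()` accumulates normalized signal left and right of the
viewpoint beyond the 10-kb exclusion radius; `region_fraction()` reports
percentages of normalized signal over named non-overlapping regions
(midpoint membership, masked fragments excluded), summing to 100 by
construction; `flanking_regions()` builds the standard three-region set — a
rearranged span and 400-kb flanks. Fragment membership is midpoint-based
everywhere, one rule across modules. Asymmetry ratios are reported as
`log2((right + 1)/(left + 1))` in normalized units, guarding one-sided
profiles against division by zero.

`compare_alleles()` lifts reference domains into allele coordinates and
reports signed boundary shifts, per-allele inter-viewpoint Jaccard, and the
TZ relation; a domain edge that falls in a deleted interval is snapped to the
nearest surviving position and flagged rather than dropped.

## Rearrangement maps

`build_allele_map()` accepts pairwise non-overlapping events only. All
engineered alleles modelled here are single-event; silently composing
overlapping or nested events is a classic source of coordinate bugs, so
composition is the caller's explicit job (the test suite shows joint
application of disjoint events equals sequential application). Duplications
are tandem — the copy sits immediately after the original — and lifts into a
duplication return one image per copy, labelled by `copy_index`.
`reorder_track()` defaults to *split and flag* for track elements spanning a
breakpoint (such fragments are chimeric in a real library and unreliable;
how the original analyses treated them is unstated, so the flag preserves
the information); `strict = TRUE` rejects them instead.

## The synthetic locus

The generator is the package's own model — the published work fits no
generative model — and its mandate is to reproduce the *qualitative* profile
features that motivate the methods: high in-domain contact frequency
stopping abruptly at the TZ, a TZ that contacts both flanking regions,
tissue-specific enhancer peaks, and overdispersed counts at fixed depth.

Expected intensity of a fragment at distance `d` kb from the viewpoint:

```
mu = (1 + d)^(-alpha) * D * E
D  = beta                      same domain as the viewpoint
   = gamma                     across the domain limit
   = tau * (beta + gamma) / 2  either end in the TZ
E  = 1 + sum of active enhancer peaks (Gaussian kernels)
```

Defaults: a 1-Mb chromosome, ~3-kb mean fragment length (the NlaIII genomic
average is close to this), domains `[200, 510)` and `[490, 810)` kb
overlapping in a 20-kb TZ, viewpoints at 350 and 650 kb (two promoters 300 kb
apart straddling the TZ), `alpha = 1`, `beta = 5`, `gamma = 0.2`, `tau = 2`,
dispersion `phi = 0.1`, library size 10⁶, and one enhancer peak per tissue
(amplitude 2, 5-kb kernel width) — a geometry and signal contrast chosen once
to echo a two-gene developmental locus of ~0.6 Mb with a 10–30 kb transition
zone. Counts are drawn multinomially at fixed library size with per-fragment
gamma multipliers of variance `phi` (so depth is interpretable and `phi = 0`
recovers the pure multinomial); independent negative binomials would let
depth float. Simulation is single-chromosome: the analyses being modelled are
all in *cis*, and RPM normalization is well-defined without trans background.

`simulate_fragment_map(with_sequence = TRUE)` realizes an actual nucleotide
sequence whose digestion reproduces the simulated map bit-exactly (primary
motifs planted only at boundaries, secondary motifs only inside non-blind
fragments, strays scrubbed), which is what lets the suite test the digestion
module against the generator rather than against itself. A 15% blind-fragment
rate approximates genome-wide NlaIII/DpnII statistics.

`simulate_allele()` lifts the structural elements (TZ, peaks, viewpoints)
through a rearrangement and *re-derives* the domains from the lifted TZ
position — everything between the locus outer limits on one side of the TZ is
one domain — rather than lifting domain intervals wholesale. That is the
model's central causal assumption: the TZ organizes the partition, so moving
or deleting it moves or removes the partition. Deleting the TZ yields a
single merged domain; an inversion carrying an enhancer across the TZ places
it in the other viewpoint's domain.

What the generator does *not* emulate: polymer-physics contact statistics,
trans contacts, PCR duplicates, mappability structure, undigested/self-
ligated template artifacts beyond the viewpoint mask, or the read-depth
profile of any particular real library. Passing the simulation-based tests
therefore shows the pipeline recovers the structures this model plants, under
this model's noise — evidence of correctness of the algorithms, not a
validation against real chromatin.

## Problem sizes and determinism

The test and acceptance workloads use the default 1-Mb locus (~330
fragments), 100 seeded replicates for boundary recovery, 200 random vectors
(length ≤ 30, k ≤ 4) for the DP-vs-enumeration check, and 10⁴ positions per
allele type for liftover round-trips — sizes at which the exhaustive oracles
are still exact and the whole suite runs in about two minutes. Every
stochastic step takes an explicit integer seed and restores the caller's RNG
state, so identical seeds give identical fragment maps, counts, reads and
calls.

## Known limitations

* Single-chromosome analysis; trans contacts and multi-chromosome maps are
  out of scope.
* No confidence intervals on domain boundaries; the segmentation is a point
  estimate.
* Translocations and nested/overlapping rearrangements are rejected, not
  modelled.
* Demultiplexing tolerates no tag mismatches; heavily error-prone barcodes
  would need an upstream correction step.
* The domain caller assumes one dominant contact domain per viewpoint;
  multi-modal profiles (two separate plateaus) return the viewpoint's own
  plateau only.
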