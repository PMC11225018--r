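---
title: "Strand-specific R-loop quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-specific R-loop quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopkit)
```

## The problem

An R-loop is a three-stranded chromatin structure: an RNA:DNA hybrid plus
the displaced single-stranded DNA. Strand-specific DRIP-style sequencing
(S9.6 immunoprecipitation of hybrids followed by single-stranded-DNA
library construction) reads out R-loops with strand identity: a *wR-loop*
leaves the Watson strand unpaired, a *cR-loop* the Crick strand. Two
experimental refinements shape everything this package computes:

* **Fragmentation chemistry.** Restriction-enzyme digestion forces R-loop
  fragment boundaries onto cut sites of the enzyme cocktail, so peak
  boundaries are artifacts of the digest. A single-strand-specific
  nuclease (mung bean nuclease, MBN) instead removes the ssDNA and cleaves
  at the hybrid/duplex junctions, giving boundaries near single-nucleotide
  resolution. The package provides diagnostics for both regimes.
* **Spike-in quantification.** Coverage normalization alone cannot compare
  *global* R-loop levels between samples. Adding a fixed amount of a
  foreign genome to every sample anchors an absolute scale: the
  quantitative-factor chain below converts relative coverage into relative
  total R-loop content.

All coordinates are 0-based half-open throughout; conversion to the
1-based SAM/Bioconductor convention happens only at format boundaries.
Counts are *fragments* (read pairs), not reads: the library molecule, not
the sequencing read, is the R-loop evidence unit.

## Strand partitioning and coverage

Properly paired primary alignments are loaded into fragments spanning the
two mates' outermost aligned bases; pairs with more than three mismatches
(`NM` tag) on either mate are dropped and counted, and pairs without an
`NM` tag pass (their count is reported rather than silently guessed).
Under the `mate1-forward` convention the fragment strand is mate 1's
strand: `+` fragments are wR-loops, `-` fragments cR-loops; the
`mate1-reverse` convention swaps the sets exactly.

Coverage tracks are binned fragment-base densities: bin value = overlapped
fragment bases / bin size x scale, so track mass is conserved under any
binning. The RPGC ("reads per genomic content") factor is
`L_eff / B` with `L_eff` the summed non-ignored target chromosome lengths
and `B` the summed fragment span lengths on those chromosomes; applying it
makes genome-wide mean coverage exactly 1. Mitochondrial DNA (`chrM`) is
excluded from both sides of the normalization by default because its copy
number varies strongly between samples; it re-enters only in compartment
accounting.

## Spike-in quantitative factors

For sample *n* with fragment counts `T_Rloop`, `T_input` (target genome)
and `S_Rloop`, `S_input` (spike-in genome):

```
QF(n)  = [T_Rloop(n) x S_input(n)] / [S_Rloop(n) x T_input(n)]
FNF(n) = QF(n) x NF(ref) / QF(ref)
```

`NF(ref)` is the RPGC factor of a user-chosen reference sample (default:
the first sample; the choice is recorded on the `QuantTable` and printed).
`QF` is invariant under independent rescaling of the R-loop library depth
and of the input library depth — the property that makes it a
between-sample quantity rather than a sequencing-depth readout. The
relative total R-loop level is `QF(n)/QF(ref)`, which equals
`T_Rloop/T_input x S_input/S_Rloop` normalized to the reference. Counts
here are fragments on non-ignored chromosomes; whether coverage or
fragment counts are used is a genuine design fork, and this package uses
fragment counts, documented by the formula above.

## GC/AT skew

`gc_skew = (G - C)/(G + C)` and `at_skew = (A - T)/(A + T)`, always
counted on the Watson strand of the reference, in 200 bp windows sliding
by 50 bp (both configurable). Three numerical conventions matter and are
deliberate:

* A window with zero informative bases has *undefined* skew, reported as
  `NA`, never as 0 — zero is a meaningful "balanced" value.
* Window values anchor at the window midpoint (symmetric, strand-free).
* Orientation is applied only at metaprofile aggregation: `-` (cR-loop)
  regions are reverse-complement-oriented (bin order reversed, sign
  flipped), so wR and cR peaks with mirrored composition reinforce rather
  than cancel. The antisymmetry `skew(revcomp(s)) = -skew(s)` is the
  invariant that makes this exact.

## Peak calling and its size filter

The caller is deliberately minimal (it replaces a general-purpose caller
only for this package's internal needs): background `lambda` is a trimmed
mean of all bin values (top 1% excluded so enriched regions do not inflate
it); candidate bins need both `value >= min_fold x lambda` (default 5x)
and a Poisson upper-tail probability below 0.01; candidate runs separated
by at most one bin merge; merged peaks shorter than 200 bp are discarded
— the minimum-size filter is part of the method, not a cosmetic step.
Calling is per-strand on wR and cR tracks separately, with unstranded
calling available. Local-background machinery of full-featured callers is
intentionally not reproduced; on the synthetic libraries this package
targets, the global trimmed mean is the correct null.

## Boundary and junction diagnostics

Two simulators and two diagnostics probe fragmentation chemistry:

* **Boundary-to-cut-site distances.** For every peak start/end, the
  distance to the nearest cut site of the enzyme set (built-ins: DdeI
  C^TNAG, MseI T^TAA, NlaIII CATG^, MboI ^GATC, scanned IUPAC-aware on
  the Watson strand). Distances `<= 5 bp` fall in bin 0 ("overlapping");
  further bins are 1–10, 11–50, 51–200, >200 bp. The bin edges beyond 0
  are this package's documented defaults. Restriction-model libraries
  put essentially all boundaries in bin 0; MBN-model libraries are
  statistically indistinguishable from length-matched random regions —
  that contrast is the diagnostic.
* **Substrate first-base readout.** A synthetic half-R-loop substrate (a
  203 nt RNA:DNA hybrid behind a primer/oligo duplex; component sequences
  ship with the package) is digested in silico; the modal 5' read end per
  strand is compared with the designed hybrid/duplex junction. Exact MBN
  digestion puts the Watson mode at the junction with deviation 0; a
  noisy nuclease (Gaussian end jitter) shifts the mode by at most a
  couple of bases because the jitter is symmetric around the junction.

## Compartments, annotation, and overlap enrichment

Fragments are assigned to compartments (e.g. mitochondrial genome, rDNA
arrays, everything else) by *midpoint*, highest priority first, so the
fractions are a true partition summing to 1. Peak annotation likewise
uses the peak midpoint with priority promoter (default 1 kb upstream of
the TSS, strand-aware) > gene body > intergenic.

Overlap enrichment uses a permutation null: each query region is
re-placed uniformly at random on its own chromosome preserving its
length, overlaps among placed regions allowed — the simplest valid
randomization, matching common practice for region-permutation tests.
`p = (1 + #{permuted >= observed}) / (n_perm + 1)`, so p can never be
smaller than `1/(n_perm+1)`; the z-score is computed against the permuted
mean and sd. Under an independent null the p-values are uniform to the
resolution the discrete statistic allows.

## Stage dynamics: fuzzy c-means

Per-stage peaks are union-merged into a total peak set; each region's
mean FNF-scaled coverage per stage fills the stage matrix; rows are
standardized to mean 0, *population* sd 1 (zero-variance rows dropped and
counted). Clustering uses the standard fuzzy c-means updates on Euclidean
distance:

```
v_k  = sum_i U_ik^m x_i / sum_i U_ik^m
U_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))
```

with membership rows summing to 1 and the objective
`J = sum_ik U_ik^m d_ik^2` non-increasing by construction. Defaults
`c = 6` clusters and fuzzifier `m = 2` reflect common practice for
developmental time courses; both are plain arguments. Initialization is a
seeded random membership matrix with 5 restarts keeping the lowest
objective, because soft-clustering fits are sensitive to
initialization and neither the initialization nor a model-selection index
is part of this package's scope. A point coinciding with a center gets
membership 1 to the first such center (the limit of the update). The
implementation is validated in the test suite against an independent
nested-loop implementation of the same updates (agreement to 1e-8 after
identical initialization).

## What the synthetic generator does and does not emulate

The generator exists so every downstream stage is testable without any
external sequencing data. It emulates:

* i.i.d. background genomes at a chosen GC content (default 0.41, a
  typical vertebrate value) with planted, non-overlapping R-loop regions
  whose Watson strand is skew-biased by `skew_strength` (so a planted `+`
  region's expected GC and AT skew equal `skew_strength`; `-` regions are
  mirrored);
* fragment libraries where a fragment is signal with probability
  `enrichment x W / (enrichment x W + B)` (`W` planted bases, `B`
  background bases), with fragment lengths truncated-normal around 250 bp
  (sd 50), the sonication target of the protocol this emulates;
* the two boundary chemistries: MBN (fragment ends = region boundaries
  plus Gaussian jitter, default sd 2 bp — "near single-nucleotide", not
  asserted perfect, and settable to 0 for exactness tests) and
  restriction digestion (every fragment end snapped to the nearest cut
  site);
* spike-in pairs where target fragments are drawn proportional to the
  sample's global R-loop level and spike fragments to a fixed spike
  level, with uniform input libraries — the planted level ratio is the
  recovery target for the quantification chain;
* RNase-H-style null libraries (background-only sampling);
* already-aligned synthetic proper pairs (perfect alignment, NM=0)
  emitted as coordinate-sorted BAM, because alignment itself is out of
  scope and alignment-free fixtures keep tests hermetic.

It does **not** model sequencing errors, PCR duplicates, mappability,
GC-amplification bias, chromatin-accessibility confounders, or repeat
structure. Passing tests therefore demonstrate correctness of the
*computations* under the stated sampling model, not robustness to every
artifact of real libraries.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at desk scale by design:
chromosomes of 0.3–1 Mb, 10–60 planted regions, libraries of 1e5
fragments, 999 permutations, 200-run null calibrations. At these sizes
the spike-in recovery lands within a few percent of truth and the peak
caller is essentially exact against the planted truth. Key tolerances:
RPGC mean coverage is exact to 1e-9; fuzzy c-means membership rows sum to
1 within 1e-9 and agree with the reference implementation to 1e-8;
binomial-sampling checks use confidence intervals derived from the
generative probabilities rather than hard-coded margins.

## Known limitations

* The peak caller's Poisson tail is computed on the normalized-coverage
  scale, which is conservative; it is a plumbing component, not a rival
  to dedicated callers on real data.
* Degenerate IUPAC motif matching is exercised with `N` (enough for the
  built-in enzymes); other ambiguity codes pass through the matcher but
  are untested.
* The scale-regions metaprofile uses `ceiling(n_bins/2)` fixed-width
  flank bins per side; other layouts are not offered.
* Replicate variance modeling, differential R-loop testing, and
  cluster-number selection indices are out of scope.
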