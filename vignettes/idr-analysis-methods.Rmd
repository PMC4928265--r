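---
title: "Methods: disorder profiling, motif enrichment and conserved binding regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disorder profiling, motif enrichment and conserved binding regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrpipe)
```

`idrpipe` analyses intrinsic disorder in multidomain protein families such
as the histone lysine methyltransferases, whose long inter-domain linkers
are largely disordered and concentrate linear motifs, binding regions and
disease variants. This vignette documents the models and procedures, the
parameters that matter, the numerical choices, and what the synthetic
benchmark does and does not demonstrate.

## Disorder model

A disorder profile is a per-residue score in [0, 1]; a residue counts as
disordered at score ≥ 0.5 and a protein's *disorder rate* is the fraction
of such residues. Proteins with disorder rate above 50% are "mostly
disordered" and are the ones scanned for motifs. IDRs are maximal runs of
disordered residues — no merging across sub-threshold residues, so the
segmentation is exactly the run-length decomposition of the threshold
mask.

Real analyses of this kind use a dedicated predictor (IUPred-class);
`idrpipe` ingests any such per-residue track from TSV. The built-in
stand-in, used when no external track is supplied, is deliberately simple
and fully documented: the TOP-IDP composition scale is averaged over a
centered window (default 21 residues, truncated at the termini) and mapped
through a logistic `1/(1 + exp(-slope (x - midpoint)))` with slope 4 and
midpoint at the scale mean, so an average-composition window scores 0.5.
Window 21 matches the long-disorder smoothing scale of standard
predictors; slope 4 makes the transition region (≈ ±0.25 scale units)
comparable to the spread between typical ordered and disordered
compositions. `X` residues are scored at the midpoint (neutral) and are
excluded from all composition statistics (entropy, shuffling, JSD).

Family summaries read "an IDR longer than 80 aa" strictly (> 80). Length
comparisons between families use Welch's t-test by default — the
equal-variance assumption is not defensible for protein-length data —
with the pooled-variance test available by flag; both report raw p values
at α = 0.05 and optional Bonferroni correction, flagged as such, since
the multiple-comparison treatment is an analyst's choice. Degenerate
zero-variance cells report `t = Inf` with p recorded below 1e-12 (or
t = 0, p = 1 when the constant means agree) rather than dividing by zero;
cells with n < 2 are reported untestable instead of being dropped.

## Low-complexity regions

The detector is a two-threshold entropy scheme in the spirit of SEG:
Shannon entropy `H = -Σ f_a log2 f_a` over each window of 12 residues;
windows with H ≤ 2.2 bits seed a region, the seed extends over contiguous
windows with H ≤ 2.5 bits, and the union of the window footprints is
reported, overlaps merged. SEG's full two-pass probability refinement is
not reproduced: in this analysis LCRs feed only a qualitative
overrepresentation/overlap statement, for which the trigger/extend scheme
with configurable thresholds suffices. The defaults translate SEG's
conventional parameter set into bits; they are configuration, not fitted
values. Homorepeats are maximal single-residue runs of at least 5 —
the polyQ length range seen in this protein family starts at 5 — and any
run at least as long as the entropy window necessarily lies inside an LCR
(a homopolymeric window has zero entropy), which the tests assert.

## Motif enrichment and the shuffled null

Motif classes are regular expressions with functional tags (e.g. `PPI`).
Scanning reports *all* occurrences, including overlapping matches at
distinct start positions, in deterministic (protein, start, motif) order.
The protein-level filter — only proteins with disorder rate > 50% are
scanned — mirrors the analysis design this pipeline reimplements; a
per-hit disordered-fraction filter exists but defaults to off, because
the original filter applied to proteins, not hits. Densities are
expressed per 1000 residues with the scanned proteins' full length as
denominator.

The null emulates the shuffled-sequence control: constructs with the
amino-acid composition of the pooled disordered residues, by default 20
constructs of 10,000 residues. When the requested total equals the pool
size the null is an exact permutation (residue multiset conserved
exactly); at any higher coverage — the default geometry is ~10x for a
20,000-residue pool — a permutation cannot exist, so constructs are drawn
i.i.d. from the pool composition. Both modes are seeded and bit-stable.

Enrichment offers two t-tests plus an always-reported empirical p,
`(1 + #{null ≥ obs}) / (1 + #null)`. The one-sample mode tests the 20
per-construct densities against the observed density as a fixed value;
the two-sample mode is a Welch test of per-protein densities against
per-construct densities. The two-sample mode is the calibrated choice
when the observed set is comparable in size to a few constructs: the
observed density then carries sampling variance of its own, which the
one-sample test ignores. The package's calibration experiment (200
replicates in which sequences are drawn i.i.d. from the pool composition,
so motifs occur at exactly the null's expected rate) rejects at 2–5% at
α = 0.05, and planting motifs at three times the null expectation over
20,000 disordered residues is detected in essentially every replicate.

## Conservation and constrained versus flexible disorder

Sequence conservation of an alignment column is the base-2
Jensen–Shannon divergence between the column's residue distribution and a
background (uniform by default), normalized by the largest JSD any fully
conserved column can achieve against that background. The normalization
matters: the raw base-2 JSD of a point-mass column against a uniform
background is 0.855, so without it the conventional 0.9 conservation
threshold would be unreachable; after normalization a fully conserved
column scores exactly 1, matching the convention of standard conservation
scorers. Columns with more than 50% gaps are scored 0 (uninformative) and
columns where the reference is gapped are dropped — both our decisions,
as gap handling is rarely specified. Scores are smoothed with a centered
window of 3 and projected onto reference residue numbering. Disorder
conservation is the fraction of non-gap orthologs whose residue is
disordered at the column, smoothed identically.

Reference-disordered residues are *constrained disorder* when both
disorder conservation (≥ 0.75) and sequence conservation (≥ 0.9) hold,
*flexible disorder* when only disorder is conserved, else not-conserved;
ordered residues are labelled separately. The 0.9 sequence threshold is
the published operating point of this analysis; 0.75 for disorder
conservation is our default (the reference tool's internal default is not
published) and is exposed in configuration. `constrained_percent()` is
monotone non-increasing in both thresholds, which the tests verify.

## Conserved binding regions and variants

Binding-region calling is two-step: maximal runs of binding propensity
≥ 0.5 at least 8 residues long become candidates; each candidate is then
intersected residue-wise with the conservation track at 0.9 and the
surviving sub-runs are kept if they still reach 8 residues. Whether the
8-residue floor re-applies after intersection is ambiguous in the source
analysis; we re-apply it by default (`min_conserved_run = 8`,
configurable), and a `whole_region` mode instead keeps or drops entire
candidates by mean conservation. The built-in binding stand-in is a
logistic of windowed interface-residue enrichment (window 9) multiplied
by the disorder score — a documented heuristic for "disordered yet
interaction-prone"; real ANCHOR-class tracks are ingested via the same
TSV path as disorder tracks. Variants (protein, 1-based position) map to
a region by closed-interval membership; positions are assumed to be on
the same sequence version as the FASTA (no isoform mapping).

## Ensemble helicity

For multi-model structures, φ/ψ are computed from N/CA/C coordinates with
a standard four-point dihedral (cross-checked in the tests against an
independent implementation); DSSP is not reimplemented, since the
counting rule needs only torsions. A residue is helical in a frame when
(φ, ψ) falls in the α basin, default φ ∈ [-90°, -30°], ψ ∈ [-77°, -17°]
— a generous box around the canonical (-57°, -47°), configurable because
the precise basin is a convention. Occupancy is helical frames divided by
usable frames per residue; chain-terminal torsions are undefined and
excluded from both numerator and denominator. The package also builds
backbones from given torsions (NeRF with ideal geometry), which yields
exact round-trip tests and lets the generator emit structure ensembles
with known helix fractions.

## The synthetic benchmark

`generate_family()` emulates the study conditions: by default 12 proteins
of ≈ 860 residues, two ordered domains (120 and 140 aa, order-promoting
composition) separated by disordered linkers (350 and 250 aa,
disorder-promoting composition — enriched P/E/S/Q/K, depleted
W/C/F/I/Y/V), giving a disorder rate near 70%, i.e. mostly disordered
proteins with IDRs far longer than 80 aa. Into the linkers it plants:
motif instances (two classes, two copies each per protein by default, or
at a requested per-1000-aa density), binding regions of ≥ 8 residues
(two conserved 16-mers and one unconserved 10-mer per protein), and
variants (three clustered inside each conserved binding region —
mimicking the clustering of cancer-associated variants in conserved
binding sites — plus two background positions). Ortholog alignments use a
star topology with 23 rows (the 22–24 range typical of vertebrate
ortholog sets): per-column substitution probability 0 in planted/conserved
columns, 0.05 in ordered background, 0.5 in disordered background, with
replacement residues drawn from the block's composition so disordered
columns stay disordered; short deletions and reference-gap insertion
columns occur only outside planted regions, so planted coordinates stay
exact. Oracle score tracks (0.9 inside planted regions, 0.1 outside,
optional clipped Gaussian jitter ≤ 0.05) decouple downstream stages from
the stand-in predictors.

What passing these tests shows: the segmentations, intersections, null
construction, statistics and classifications implement their definitions
exactly, are calibrated, and recover planted features at per-region
Jaccard ≥ 0.8 under realistic alignment divergence. What it does not
show: performance of the *stand-in predictors* on real proteins — they
are composition heuristics, not trained predictors — nor anything about
real phylogenies (the generator uses a star topology, no rate variation
across lineages, no alignment error). Real analyses should plug in real
predictor tracks and curated alignments; the pipeline surface is
identical.

## Numerical choices and problem sizes

All run-length operations are exact integer scans; entropy and JSD use
base-2 logs with `0 log 0 = 0`; moving averages truncate at the ends
rather than pad. Ties at thresholds are inclusive (≥) everywhere, so
boundary cases like a run of exactly 8 or an IDR of exactly 80 behave as
documented (kept, and not "longer than 80", respectively). The test and
acceptance workloads use a 12-protein family, 200-replicate calibration
and power experiments at 20,000 observed residues per replicate, and a
20 × 10,000-residue null — sizes chosen to match the study geometry
while keeping the full validation run in well under a minute per
component.
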