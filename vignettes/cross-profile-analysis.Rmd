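---
title: "Cross profile analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross profile analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossprofiler)
```

## The problem

Protein local structure is redundant: short backbone conformations recur
across proteins that share neither sequence nor fold. If a recurring
conformation imposes a recognizable amino-acid preference, that preference
should surface twice — once in the *structure-based profile* computed from
the residues observed in segments adopting the conformation, and once in
the *sequence-based profiles* (PSSMs) of the families that contain such
segments. `crossprofiler` detects this coincidence directly by aligning the
two kinds of profile against each other, and then asks an evolutionary
question: given an ancestral sequence for a family, did the family evolve
toward or away from compatibility with the structural motif?

## From structures to profiles

Backbone chains are reduced to per-residue (φ, ψ) dihedrals. φ of residue
k is the torsion C(k−1)–N(k)–CA(k)–C(k), ψ is N(k)–CA(k)–C(k)–N(k+1), both
in the IUPAC sign convention on (−180°, 180°]. An angle is undefined at
chain termini, at residues missing any backbone atom, and across chain
breaks (consecutive CA–CA distance above 4.5 Å, a bound implied by peptide
geometry). ω torsions are not used for classification; only (φ, ψ) enter
the segments.

A sliding window of L residues (9 and 15 are the conventional lengths)
yields maximally overlapping segments; a window is kept only if all 2L of
its angles are defined, the terminal φ/ψ of the window being taken from the
flanking residues. Whether the original procedure imputed terminal window
angles or restricted windows is not decidable from the published
description; requiring flanking residues is the stricter reading and makes
every kept window fully comparable.

Segments are clustered by single-pass (leader) clustering: the first
segment founds a cluster; each next segment joins the nearest existing
centroid if within `d_th`, else founds a new cluster. Two quantities had to
be fixed that the published description delegates elsewhere:

* **the distance**: the wrapped root-mean-square over all 2L angle
  differences, `sqrt(mean(Δ²))` with Δ wrapped into [−180°, 180°]. It is
  symmetric, bounded by 180°, and reduces to the familiar per-angle RMS.
  It is isolated in `dihedral_distance()` so it can be swapped.
* **the centroid**: the per-coordinate circular mean (atan2 of summed
  sines/cosines), updated incrementally after every join. This is
  wrap-correct and makes the procedure a deterministic function of the
  input order. Input order is therefore part of a run's provenance and is
  recorded in the manifest.

`d_th` defaults to 30°; on well-separated planted fixtures the cluster
count is flat over the 30–40° band (this is asserted by a test). The
80-member floor (`min_members`) applies to profile building and search
only — small clusters are retained in clustering output, they just do not
produce profiles, since propensities from a handful of members are
dominated by sampling noise.

For a cluster, the propensity of amino acid j at window position i is
`pro_i(j) = p_i(j)/p(j)`: observed positional frequency over the member
sequences divided by the background composition of all segments. Counts
are raw — no sequence weights, no pseudo-counts. `'X'` (nonstandard)
residues are excluded from both numerator and denominator; segments
containing `'X'` still cluster (their structure is valid) but are dropped
from profile counts. A residue absent from the background gets propensity
0 by convention; zeros are handled downstream by the log floor, never by
pseudo-counts.

## The search

Profile–profile column similarity is the Pearson correlation of two
20-vectors, with zero-variance columns defined to score 0. Correlation is
affine-invariant but not log-invariant, so the space in which columns are
compared matters. Structure-profile columns enter as `ln(pro)` floored at
`ln(1e-4)` (the same constant the compatibility score uses), which makes
them commensurate with PSSM log-odds; the raw-propensity mode is kept as a
config option.

The alignment is global with free terminal gaps: unaligned runs at either
end of either profile cost nothing, internal gaps of length k cost
`gap_open + k·gap_extend`. The dynamic program is the affine-gap (Gotoh)
recursion in the aligned-pair formulation, including the transition that
lets an internal gap in one profile follow an internal gap in the other
between two aligned pairs — without it the recursion would not agree with
exhaustive enumeration over monotone pair sets, which is how the aligner is
tested (200 random instances up to 6×6 columns, exact agreement). Traceback
ties prefer the diagonal, then a gap in the query, then a gap in the
target, making alignments deterministic.

Gap penalties are not published for the original search engine; the
defaults (0.6 open, 0.06 extend) price a single internal gap above the
best possible column gain (a perfect correlation, 1.0) minus a typical
decoy column (≈0), so gaps are used only when they buy genuine signal.
They were fixed on the planted-motif fixture and are exposed in
`search_config()`.

Significance is a library statistic: raw scores are regressed on
log(target length) (longer targets offer more alignment opportunity), and
the residuals are standardized. The resulting Z-scores have mean 0 and
standard deviation 1 by construction; `z_threshold = 8` is the working
point for calling a hit significant. The exact length correction of the
original engine is unpublished; regression-on-log-length followed by
standardization is the simplest recipe with the stated shape and is
isolated in one function. Libraries below 10 profiles get raw scores only
(flagged), and an all-equal-score library yields all-zero Z with a warning
rather than dividing by zero.

## Compatibility scores and ΔS

Threading an L-symbol region onto a profile scores
`S = Σ_i ln pro_i(j_i)`, with `ln(0.0001) ≈ −9.21` for gaps, for `'X'`,
and for residues never observed at their position. The constant is stored
at full precision and reported rounded to two decimals. Every per-position
term is floored at that constant, so `S ≥ L·ln(1e-4)` holds for any input
with equality exactly on all-gap/zero regions; with realistic cluster
sizes a nonzero propensity never falls below 1e-4, so the floor coincides
with the gap/zero rule in practice.

Because the terms are independent, the per-position argmax sequence (ties
broken alphabetically) attains the global maximum of S over gapless
sequences — this is the "deduced" consensus peptide of a profile.

`family_delta_scores()` scores every member of a gapped family alignment
over a designated L-column window and reports `ΔS = S_member −
S_ancestral`. Members whose window contains no amino acids at all are
excluded (reason `"empty region"`) rather than scored as pure gap runs; an
ancestral sequence that is empty in the window is an error, prompting the
caller to designate an alternative (e.g. next-root) ancestor. Ancestral
sequences are inputs: reconstructing them is out of scope. How alignment
columns map onto the L profile positions is genuinely a modelling choice;
the window specification (`"start-end"` in alignment columns) externalizes
it rather than guessing.

## The evolutionary landscape

"PCA with Hamming dissimilarity" is implemented as classical (Torgerson)
multidimensional scaling — the standard identity when only dissimilarities
are available, and equal to PCA of the implied one-hot encoding up to
scaling. Hamming distance counts gap-vs-residue as a difference and
gap-vs-gap as equal. The top-2 eigenpairs of the double-centred Gram
matrix give PC1/PC2, each scaled by the square root of its eigenvalue;
axis signs follow the first nonzero loading. Two-point and equilateral
three-point configurations embed exactly, and the embedding matches
`stats::cmdscale` (an independent oracle in the tests).

The published landscape surface was drawn by a proprietary interpolation
routine; here the default is linear interpolation on the Delaunay
triangulation with inverse-distance-weighted (power 2) extrapolation
outside the convex hull, recorded in the surface's metadata. The surface
is exact at data nodes and, in triangulation mode, bounded by the data
range. "Virtual" sequences for densifying sparse maps are seeded single-
and double-point mutants of the data sequences (`virtual_sequences()`).

## The synthetic-data generators

The generators define the study conditions for all tests:

* **Backbones from dihedrals** use sequential internal-coordinate (NeRF)
  construction with ideal geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N
  1.329 Å; angles 111.2°, 116.2°, 121.7°; ω = 180°). Recomputing dihedrals
  recovers the inputs to ~1e-13 degrees, which anchors the dihedral
  conventions end to end.
* **Planted segment populations** scatter members (wrapped Gaussian noise,
  default σ = 3°) around k centroids. Centroids are drawn per angle
  coordinate as equally spaced values (spacing 360/k) with a random
  rotation and assignment, giving exact pairwise separation 360/k = 120°
  for k = 3. A blanket "5 × d_th" separation is not achievable in this
  metric — its diameter is 180°, and uniform rejection sampling
  essentially never reaches 150° for 2L ≥ 18 coordinates — so the
  structured construction with `min_separation = min(4·d_th, 360/k)` is
  used instead; it exceeds any plausible joining radius (d_th + noise) by
  a comfortable factor and guarantees single-pass recovery. Sequences
  follow a per-cluster positional bias (preferred residue with probability
  0.7) so cluster profiles are informative.
* **Family libraries** mutate a consensus at a per-site rate (or accept an
  explicit family, e.g. a cluster's member sequences), build a log-odds
  PSSM with a uniform background and one pseudo-count, embed it between
  decoy columns at a recorded offset, and surround it with
  symmetric-Dirichlet(0.5) decoy profiles. The pseudo-count exists only
  here, as a stand-in for the machinery of iterative profile builders; it
  never enters structure-profile propensities.

What the generators do *not* emulate: real secondary-structure geometry
(centroids are uniform in angle space, not Ramachandran-weighted), real
residue covariation (sites are independent), database redundancy, and the
composition of real PSSM libraries. Passing tests therefore demonstrate
the correctness and power of the machinery under controlled conditions,
not the biological hit rates of any particular structure library.

## Problem sizes and determinism

The test and acceptance workloads use 3 planted clusters × 50–80 members
(L = 15), libraries of 200 decoys plus one planted target, 20 replicate
seeds for clustering recovery and detection power, 200 random instances
for the aligner oracle, and 1,000 angle pairs for the dihedral round
trip — sizes at which every check runs in seconds while keeping the
statistics meaningful. All generators are pure functions of their seed;
pipeline runs write a manifest with the config hash, seed, input order and
stage counts, and identical configurations produce byte-identical outputs.

## Known limitations

* Single-pass clustering is order-dependent by construction; the package
  treats input order as provenance rather than hiding it.
* The Z-score recipe and gap penalties are reasoned stand-ins for
  unpublished choices of the original search engine; both are isolated
  behind `search_config()` / one function each.
* The compatibility score treats positions independently; no attempt is
  made to model covariation or indel placement within the window.
* `read_pssm()` ingests the ASCII PSSM layout (with or without the
  percentage block); binary checkpoint formats are not supported.
* Real-structure validation (e.g. the published 2.49 Å cross-fold
  superposition) requires the corresponding PDB entries, which are not
  redistributed with the package.
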