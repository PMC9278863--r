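---
title: "Methods: rigid-body domain motion analysis of membrane transporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigid-body domain motion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlemotion)
```

## The problem and the model

Elevator-type secondary transporters alternate access to their substrate
by sliding a mobile *transport domain* — a bundle of transmembrane (TM)
helices carrying the substrate site — along a static *scaffold domain*
that also mediates oligomerization. For the ZIP family of zinc
transporters the two bundles are TM1/TM4/TM5/TM6 (transport) and
TM2/TM3/TM7/TM8 (scaffold). This package takes two conformations of the
same protein and (i) detects the rigid bodies without assuming them,
(ii) quantifies the inter-domain motion, (iii) tests which coevolved
residue pairs each conformation satisfies, and (iv) builds a geometric
model of a state that satisfies the remainder.

All analyses operate on C-alpha coordinates in author residue numbering.
Heteroatoms are parsed and available for site definitions but never enter
C-alpha selections; alternate locations resolve to the highest-occupancy
conformer (ties toward altloc `A`); only the first model of a multi-model
file is read.

## Rigid-body detection by distance differences

For each conformation the intramolecular C-alpha distance matrix is
computed; their element-wise difference (the DDM) is invariant under any
rigid transform of either structure, so no superposition — and no choice
of reference frame — is involved. Residue pairs inside one rigid body
have (noise-level) zero entries; pairs straddling two bodies do not. The
residue-level matrix is aggregated per helix pair as the root mean square
of its signed entries (RMS rather than mean absolute difference, so
occasional large entries are not washed out; the signed residue level is
retained in the exported matrix). Average-linkage hierarchical clustering
of the aggregate, treated as a dissimilarity, cut at *k* = 2, gives the
partition. Segments are sorted lexicographically before clustering so the
result is invariant to input order, and the *separation score* (mean
cross-cluster minus mean within-cluster entry) quantifies the split; below
0.1 A the partition is flagged as "no rigid-body substructure", the
expected outcome when the two structures differ by an overall rigid
transform only. An extra N-terminal helix resolved in only one
conformation (labeled `TMa` in the default tables) is excluded from the
DDM by default, since its entries exist in only one structure's frame.

## Motion decomposition

Structure *b* is superposed onto *a* by a Kabsch least-squares fit (base
`svd()`, with the determinant correction that forbids reflections) over
the scaffold C-alphas, pairing residues by the intersection of
`(chain, residue number, insertion code)` labels; unpaired residues are
reported, not silently dropped. In this scaffold frame the residual rigid
transform of the transport domain is fit the same way, and is reported
as:

* **tilt**: the rotation angle from `tr(R) = 1 + 2 cos θ` (equal to the
  axis–angle magnitude);
* **translation**: displacement of the transport-domain C-alpha centroid,
  decomposed along and perpendicular to the membrane normal. The reported
  sign is positive toward the extracellular side; printed output shows
  magnitude plus direction word.

The membrane normal is the normalized mean of the per-helix axes after
flipping each to the hemisphere of the first (an antiparallel bundle
alternates direction); a mean resultant length below 0.5 aborts with "no
consensus normal". Each helix axis is the first principal component of
the C-alpha trace smoothed by a 4-residue running average — one helical
turn, which cancels the periodic wobble of the helix — with its sign fixed
along the N→C direction. The normal's global sign (which side is
extracellular) is not decidable from coordinates alone; callers fix it
with the `orient` argument or by passing the normal explicitly, as the
analysis scripts do.

Per-segment angle changes compare axis directions before/after in the
scaffold frame. The "cytoplasmic half" angle of a chosen helix uses the
residues of that helix lying below the membrane mid-plane (the scaffold
centroid's height along the normal) *in structure a*, and compares the
same residues in both structures: defining the subset once makes a pure
translation give a zero angle change, as it should. Site displacements
are distances between site centroids (C-alpha or all-heavy policy) in the
scaffold frame.

## Coupling satisfaction

Coupling tables are read from delimited text with `i`, `j`, `score`
columns (header auto-detected), normalized to `i < j`, deduplicated
keeping the maximum score. Significance uses a score cutoff of 0.9, the
convention for probability-scaled coupling scores. Geometric satisfaction
uses a 10 A C-alpha–C-alpha cutoff by default — a common contact
convention for coevolution analysis; it is a declared parameter, reported
in every output, with a heavy-atom minimum-distance option. Pairs with
`|i − j| < 5` are near-diagonal trivia and are excluded by default.
Satisfaction is monotone in the cutoff, and classification is invariant
under rigid transforms of the structure (both properties are tested).
In a two-protomer assembly the per-pair distance is the minimum over
within-A, within-B and the two cross-protomer combinations, so the dimer
fraction can only exceed the monomer fraction; identical protomer
coordinates are rejected as degenerate.

## State modeling by translation scan

The transport domain is translated rigidly along the membrane normal over
a 0–15 A grid in 1 A steps (both configurable); the 15 A range brackets
the translations reported for elevator transporters with margin, and a
minimum at the range boundary is flagged rather than trusted. The
objective is the sum of C-alpha distances over the constraint pairs
(side-chain atoms are deliberately not used: the model is geometric and
unminimized). Exactly one residue of each pair should move; pairs whose
distance is translation-invariant trigger a warning but are retained.
Ties break toward the smallest translation. The emitted model records the
applied transform in PDB REMARK records and counts (but does not relieve)
heavy-atom clashes across the domain boundary.

## The synthetic generator and what it does (not) show

`make_bundle()` builds ideal alpha-helical C-alpha traces (rise 1.5
A/residue, twist 100°/residue, helix radius 2.3 A), placed on a circle of
radius 12.5 A — about 9.6 A between adjacent axes of an 8-helix bundle,
typical helix packing — alternating up/down as in an antiparallel TM
topology, with 25 residues per helix and the TM1/4/5/6 vs TM2/3/7/8
domain split. Isotropic Gaussian coordinate noise (seeded) emulates
coordinate uncertainty.

Noise semantics: the noise is drawn once, at bundle generation, and
`apply_motion()` by default moves those noisy coordinates rigidly, so the
recorded ground truth is *exactly* retrievable from the generated pair —
closed-loop tests then validate the algebra of the pipeline, not its
statistical robustness. Setting `renoise = TRUE` instead applies the
motion to the noise-free coordinates and draws independent noise for the
moved copy, emulating two independently refined structures; with
independent noise of sd σ the recovered translation error scales as
σ/√N, and the noise-robustness tests (partition recovery under sd 0.2 A,
error scaling with σ) use this mode. What the generator does **not**
emulate: side chains, loops connecting the helices, helix kinks and
irregularity, correlated refinement error, or sequence-level coevolution
(coupling scores are assigned by planted class — true contacts and
"interface" pairs score 0.9–1.0, decoys 0.3–0.9 — not inferred from
sequences). Passing closed-loop tests therefore demonstrates correctness
of the computations, not performance on real crystallographic error
structure.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear paired points (collinearity:
  second singular value < 1e-8 of the first).
* Rotations are validated orthonormal with det +1 at 1e-8; angle formulas
  clamp cosines into [−1, 1] against round-off.
* The DDM restricts to the label intersection and reports its size;
  an empty intersection is an error, as is a segment with no resolved
  residues.
* PDB output refuses residue numbers outside the fixed-width field and
  structures beyond 99,999 atoms rather than silently truncating.
* Scan ties break toward the smallest translation; halving the step can
  only improve the minimum (tested).

## Problem sizes

The test suite and the acceptance script use 8-helix bundles of 200
residues, 50-replicate recovery studies, 20 rigid-invariance trials and
10 planted-optimum scans — sizes at which every closed-loop property is
exercised while the whole study runs in seconds on one CPU.

## Known limitations

* The rigid-body partition assumes the aggregate dissimilarity is
  informative; motions below the coordinate-noise floor (separation
  < 0.1 A) are declared unresolvable rather than partitioned.
* The motion decomposition reports the transform between *two* states; it
  says nothing about the path between them.
* The translation scan explores pure translation (an optional tilt can be
  added to `build_model()`); it cannot discover motions outside that
  family, and its model is unminimized geometry with clashes counted, not
  relieved.
* Mapping coupling-table indices to author numbering is an identity plus
  constant offset; alignments with indels relative to the structure's
  numbering need external renumbering.
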