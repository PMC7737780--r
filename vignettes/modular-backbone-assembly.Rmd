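---
title: "Modular backbone assembly: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular backbone assembly: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragstitch)
```

## The design model

`fragstitch` treats a protein family as a set of interchangeable backbone
modules. A *template* structure is segmented at user-chosen *anchors* —
residue positions of maximal structural conservation, such as the
disulfide-linked framework cysteines of antibody variable domains or the
easily alignable β-strands of TIM-barrel enzymes. Between consecutive
anchors lies a *segment*; each homolog contributes its own conformation of
that segment (a *fragment*). New backbones are generated by choosing one
fragment per segment and grafting the choices onto the template.

Three assumptions underlie the model:

1. **Anchors are geometrically conserved.** Every family member presents
   (approximately) the same local backbone frame at each anchor, so a
   fragment extracted between two anchors of one structure can be re-seated
   between the same anchors of another.
2. **Torsion space is sufficient.** Backbone diversity is captured by
   (φ, ψ, ω) alone; bond lengths and angles are fixed at ideal values
   (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å; N–CA–C 111.2°, CA–C–N 116.2°,
   C–N–CA 121.7°). Experimental deviations from ideality are treated as
   noise, and every model the package emits is rebuilt from torsions by
   NeRF reconstruction, so stereochemistry is ideal by construction.
   Reconstruction is exactly invertible: `extract_torsions()` after
   `rebuild_backbone()` reproduces its input to well below 0.01°.
3. **Conformational redundancy.** Fragments of one segment cluster into a
   modest number of conformational groups, so a clustered database loses
   little diversity while shrinking the combinatorial space.

## Graft-and-close

Grafting replaces a template segment's torsions with a fragment's and must
then reconcile two rigid boundary conditions: the upstream anchor frame
(where the fragment is built on) and the downstream anchor frame (where the
rest of the template continues). The package closes this gap geometrically,
in two stages, with the chain cut at the fragment's **middle residue**:

* the N-terminal part is built forward from the upstream frame and the
  C-terminal part backward from the downstream frame, both with the
  fragment's own torsions (reversed-chain NeRF uses the same ideal internal
  coordinates, since a dihedral is invariant under atom-order reversal);
* if the cut mismatch exceeds 3 Å, a coarse cyclic-coordinate-descent stage
  (at most 50 sweeps) brings it into range;
* a damped least-squares (Levenberg–Marquardt) stage then updates the
  adjustable φ/ψ angles by the **minimum-norm** torsion change that moves
  the three cut atoms (N, CA, C of the residue after the cut) onto their
  target positions, iterating to a tolerance of 0.05 Å within a budget of
  200 iterations. ω is held planar throughout.

The minimal-norm property matters scientifically: it distributes small
corrections evenly over the fragment's torsions, so the closed conformation
stays as near as possible to the conformation observed in the source
structure. The *closure RMSD* — backbone N, CA, C, O RMSD between the closed
fragment and its idealized source conformation after optimal superposition,
excluding the final carbonyl O whose direction belongs to the next residue's
context — is the gated quantity: a fragment enters the database only when it
is strictly below the **0.2 Å** gate. Terminal tails are constrained at a
single anchor, need no closure, and therefore gate at ~0. A cut that cannot
be closed below 0.5 Å marks the record unclosable (rejected outright), which
also fails candidates during assembly, together with any graft whose closure
RMSD reaches the gate.

The deterministic middle cut replaces a randomized cut choice; determinism
makes database builds byte-reproducible, and the closure result is
insensitive to the cut position because the least-squares stage spreads the
correction over all adjustable torsions anyway.

## Alignment and segmentation

Homologs are aligned to the template by a sequence-guided structural
alignment: a global Needleman–Wunsch alignment (BLOSUM62, gap open 10,
extend 0.5, via Biostrings) seeds residue pairs; runs of at least three
consecutive identical residues — in practice the conserved anchor
neighborhoods — seed the first Kabsch superposition, and the correspondence
is then re-derived as the maximum-weight sequence-order-preserving matching
of CA atoms within 3.5 Å, iterated to stability with refits restricted to
pairs within 1.5 Å. Restricting the refit to tight pairs prevents
structurally diverged loops from dragging the superposition off register, a
real failure mode when loops outnumber framework residues. A homolog that
leaves any anchor unmapped is rejected by name.

Segments are anchor-inclusive at both ends. The shared boundary anchor
belongs to both adjacent fragments for frame purposes but to the left
segment for sequence/PSSM composition, so composed PSSMs have exactly one
row per designed position. All indices are 1-based, the native R convention
used by every structural package in the ecosystem.

## Sequence constraints

Homolog sequences are filtered at ≥35 % pairwise identity (matches over
aligned columns excluding terminal gap blocks) and ≥75 % coverage of the
query, ranked by identity (descending — the retained-set ordering is this
package's documented choice) and truncated to 3,000. The PSSM scheme is
fixed so results are reproducible without external profile tools:
position-based (Henikoff–Henikoff) sequence weights, BLOSUM62 marginal
background frequencies, a pseudocount mixture
p = (N·f_obs + B·q)/(N + B) with B = 50 effective counts by default, and
half-bit integer scores round(2·log₂(p/q)) capped at ±13 (the cap also
guards log 0 when B = 0). PSSMs serialize in a PSI-BLAST-style ASCII
dialect and can be imported from it for parity with externally generated
matrices. `allowed_residues()` never returns an empty set: if no residue
reaches the threshold, the single best scorer is returned with a warning,
because a designable position must always have at least one identity.

## Ranking

Per-criterion fitness is the logistic f = 1/(1 + e^((x−μ)/σ)) with μ, σ the
ensemble mean and **population** standard deviation (a documented choice;
with ensembles of thousands of designs the sample/population distinction is
immaterial, and the population form keeps f(μ) = 0.5 exactly). Undesirable
criteria are negated. The objective is the product of fitness terms, so one
poor feature collapses the score — the intended behavior for multi-criteria
triage. Constant criteria are rejected (σ = 0 is undefined); the exponential
is saturated so f stays strictly inside (0, 1) even hundreds of σ from the
mean. Ranking ties break on lexicographic recipe order, making reports
reproducible. Packing, shape complementarity, docking and preorganization
scores are user-supplied feature columns, not computed here.

## The synthetic generator

`make_toy_family()` emulates the features of a real homolog family that the
pipeline depends on: identical helical anchor stretches (anchor at the
stretch center; with `tails = FALSE` the chain termini are anchors and the
scheme has exactly `n_segments` segments); loops whose conformational groups
are planted by drawing per-position torsions from distinct Ramachandran
wells; group-specific loop lengths drawn from `loop_length_range` (default
12–16 residues, sampled without replacement within a segment so groups also
differ in length, mirroring natural loop families); and Gaussian torsion
noise (default sd 2°, clipped at 2.5 σ, i.e. ±5°) within a group. Each group
base conformation, and each noisy loop, is geometrically re-closed onto the
template's anchor frames — exactly the property real homolog loops have by
virtue of connecting the same conserved framework. Sequences are
family-invariant in the anchor stretches and group-specific with 25 %
per-homolog mutations in the loops. Everything derives from one seed;
repeated runs are byte-identical, including written PDB files.

What the generator does **not** emulate: side chains beyond an idealized CB,
packing of loops against a core (toy loops are free excursions, so assembled
toys often show steric clashes that a real, designed protein would not),
crystallographic noise in bond geometry, and insertions at anchor positions
(homologs with such insertions are rejected rather than guessed at).
Passing tests therefore demonstrate the pipeline's combinatorial, geometric
and statistical correctness — not that a particular natural family will
yield active designs, which additionally requires atomistic sequence design
and experimental validation, both out of scope.

Default test and acceptance problem sizes — families of 4–19 homologs, 2–4
segments, loops of 8–16 residues — were chosen as the smallest sizes at
which every claimed property (planted-group recovery with >3 Å inter-group
separation, 20-per-segment databases, full 125-recipe enumeration) is
actually exercised.

## Numerical choices and degenerate inputs

* Dihedrals use the IUPAC sign convention in (−180°, 180°], computed by the
  atan2 formulation and cross-checked in the tests against an independent
  acos/triple-product oracle and bio3d.
* Kabsch superposition uses the SVD with the determinant correction;
  collinear or sub-3-point inputs are errors, and the RMSD is cross-checked
  against a quaternion (Horn) eigen-decomposition oracle.
* Unequal-length fragment RMSD is the minimum over all contiguous ungapped
  placements of the shorter fragment in the longer, reported together with
  the length difference — a simple, documented stand-in for fully
  sequence-independent alignment tools.
* Complete-linkage clustering (stats::hclust) is cut at a radius of 1.0 Å by
  default; the radius is the one free parameter a user should revisit per
  family (it must sit between intra- and inter-group RMSD). Representatives
  minimize mean within-cluster RMSD; ties break on lexicographic source id.
* Alternate locations resolve to highest occupancy (ties → altloc 'A');
  residues missing any of N/CA/C are dropped with a warning and a recorded
  chain break; torsions spanning a break are undefined. Chain breaks are
  detected by the peptide C–N distance leaving [1.2, 1.5] Å.
* Recipe sampling is uniform **without replacement** over the mixed-radix
  recipe index space under one seed (the enumeration/sampling crossover is
  exact: at most `n` recipes are ever produced, in lexicographic order when
  enumerating). The choice distribution over fragments is uniform — nothing
  in the framework weights fragments by cluster size or provenance.

## Known limitations

No energy function: the steric clash count (backbone/CB pairs at sequence
separation ≥3 closer than 2.5 Å) is a feasibility screen, not a stability
estimate, and sequence design within the composed PSSM alphabet is left to
downstream tools. Single chains only; PDB format only (no mmCIF); no
automatic anchor discovery — `anchor_deviation_scan()` reports per-position
structural deviation to guide the manual choice, which remains the user's.
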