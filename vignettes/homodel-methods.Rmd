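---
title: "Models and methods behind homodel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind homodel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

homodel is a homology-modelling engine for single-chain protein targets:
from a target–template alignment and a template structure it builds a raw
model, repairs deletions, fills insertions with database loops (Monte Carlo
fallback), packs sidechains on a rotamer graph and regularizes the result.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic test world does and does not establish.

## Backbone representation

A `backbone_list` stores per residue the N, CA, C, O and CB positions plus
the φ/ψ/ω torsions; both views are kept synchronized. The internal
coordinate tree is rooted at residue 1's N and runs N→C; rebuilding from
torsions uses fixed Engh–Huber-style bond lengths and angles
(`ideal_geometry()`, overridable), which is the usual idealisation that
protein backbone flexibility is essentially torsional. ω is adjustable but
defaults to trans (180°) and is never sampled: cis peptide bonds are out of
scope. `set_torsion()` applies a rigid rotation to everything downstream of
the torsion bond, so upstream atoms are untouched bit-for-bit — this is
what makes torsion-space sampling cheap and exactly reversible.

Conventions worth knowing:

* φ(1) and ψ(n) are undefined and stored as `NA`; ω(i) is the peptide bond
  between residues i and i+1.
* The O of the last residue has no ψ to follow, so it is placed with a
  trans-like default. This is arbitrary but deterministic.
* CB reconstruction solves the two bond-angle constraints
  (N–CA–CB 110.4°, C–CA–CB 110.6°) at 1.530 Å and picks the root giving
  L-chirality (improper N–CA–C–CB ≈ −122.5°). Three backbone points carry
  no handedness, so chirality must be pinned by convention; a mirrored
  frame therefore also yields an L-configured CB in its own frame.

## CCD loop closure

`ccd_close()` pins the loop's first residue on the N-stem and sweeps
residues N→C, φ then ψ; each torsion gets the closed-form rotation
θ\* = atan2(b, a) that minimises the summed squared distance between the
loop's last-residue N/CA/C and the C-stem. Because every rotation minimises
the same objective, the anchor RMSD trace is monotone non-increasing (the
`trace` field lets you check). Defaults: tolerance 0.1 Å on the anchor
RMSD, 200 sweeps. These are not taken from any reference — they were fixed
once so that the convergence property suite (50 seeded ±10° perturbed
native loops, lengths 4–12, ≥ 90 % convergence) passes, and then left
alone.

Degenerate cases: loops shorter than 3 residues are refused; an anchor
beyond the loop's maximal extension simply returns `converged = FALSE`
with the best state (that outcome is informative, not exceptional).

## Structural and fragment databases

`structure_db` is a linear store — per chain: sequence, N/CA/C/O, φ/ψ and a
3-state secondary structure string — addressable by (chain index, 0-based
offset, length). Secondary structure is a self-contained stand-in for DSSP:
the same electrostatic hydrogen-bond energy
E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with the amide H
built from the backbone, bonds below −0.5 kcal/mol, helices from runs of
i→i+4 turns and strands from bridge-paired residues. It agrees with DSSP on
clean geometry and claims nothing more.

`frag_db` hashes every indexed fragment by the discretized geometry of its
two stem residues: l (residues between the stems), d (N-stem C to C-stem N
distance), and two polar/azimuth angle pairs describing the inter-anchor
direction in each stem's local frame (x = CA→C, z = x × (CA→N), y = z × x
— the frame construction is ours; only the six descriptors themselves are
fixed by the design). Defaults: distance bin 1.0 Å, angle bin 20°,
redundancy threshold 1.0 Å CA-RMSD after superposition on the six stem
atoms, fragment lengths 3–14. Azimuth bins do not wrap at ±180°; fragments
straddling that seam land in different buckets, which costs recall, not
correctness, and is recovered by query widening.

Queries return the union of all buckets within ± extra_bins of the key in
every dimension, exact bucket first, then by Chebyshev shell, ties by
insertion order — fully deterministic. The loop-filling pipeline widens
extra_bins from 1 up to `max_extra_bins` (default 4) until any candidate
converges, so sparse databases still propose (possibly poor) candidates.

## Scoring

All scorers are "lower is better" and normalized per segment residue so
that elongated loop candidates of different lengths compare fairly.
Statistical potentials are trained by inverse Boltzmann statistics,
E(bin | ctx) = −ln[(N_obs + p)/(N_ref + p)] with pseudo-count p = 1 and the
context-free pooled bin distribution as reference state (stored in the
table metadata). Binning: CB–CB distances 1–15 Å in 1 Å bins with sequence
separation ≥ 4 (glycine falls back to CA); CA–CA distance × 4 bins of the
angle between CA→CB directions ("reduced"); 30° × 30° φ/ψ grids per amino
acid; CB neighbour counts within 10 Å capped at 30. These forms are
self-contained stand-ins for the named scorer roles — the exact published
parameterizations live in supplementary material we deliberately do not
guess — and each is table-driven so a retrained or replacement table drops
in.

The clash score is a piecewise-linear repulsion: 0 beyond R = r_i + r_j,
a ceiling of 10 below 0.8254·R, linear in between. The per-element radii
(C 1.60, N 1.40, O 1.30, S 1.70 Å) are deliberately below van der Waals so
hydrogen-bonded backbone contacts (helix N···O ≈ 2.9 Å) score zero;
peptide-unit 1-2/1-3/1-4 contacts are excluded. The same functional form
with the same radii is the SCWRL3-style rotamer energy, which keeps
backbone and sidechain stages consistent.

`fit_weights()` estimates linear combination weights by least squares of
decoy CA-RMSD on score vectors (intercept discarded; minimum-norm fallback
with a warning on rank deficiency). The shipped default weights are all 1 —
honest ignorance, retrainable from `make_decoy_set()` output.

## Sidechain packing

Rotamer groups take the smallest probability-sorted prefix reaching
`coverage` (default 0.98) of the library mass; self energies are
−K·ln p (K = 1, i.e. reduced units) plus the frame energy. The flexible
rotamer model builds 1 + 2·n_chi sub-rotamers (central, ±1σ per chi, one
chi at a time) with Gaussian weights (central 1, perturbed e^−1/2,
normalized); pairs of flexible rotamers combine as
E = −(1/β)·ln Σ w_k w_l e^(−β E_kl) with β = 1. The sub-rotamer scheme and
weights are package choices; published flexible-rotamer formalisms differ
in detail.

Solvers, in the order the pipeline uses them: edge decomposition (remove
additively separable edges, folding row/column minima into self energies —
every assignment's energy changes by at most eps per removed edge),
Goldstein dead-end elimination (provably optimum-preserving), exact dynamic
programming over a min-fill tree decomposition (width cap 12), A\*
enumeration (admissible heuristic; the among-unassigned pairwise bound is
min(0, min E) per pair, which degenerates to the usual 0 for purely
repulsive energies but stays admissible for statistical potentials), and
Metropolis Monte Carlo with cyclic position visits, alternative-rotamer
proposals and geometric cooling. Disulfides are detected before packing:
any cysteine pair reaching SG–SG ∈ [1.8, 2.5] Å for some rotamer
combination is a candidate; greedy selection by |d − 2.05 Å|, each cysteine
used once, chosen pairs fixed. Sub-rotamer optimization re-solves the
reduced rigid graph over the winning rotamers' sub-rotamers; since the
central assignment is in that search space, the rigid energy can only go
down.

## Modelling pipeline

Deletions: the raw model copies stem coordinates from the template, leaving
a long C–N "bond" at the deletion point while both stems are already
placed. An anchor-objective CCD run would see this loop as already closed,
so the mini-loop (up to two flanking residues per side plus the stems) is
first rebuilt from its own measured torsions with ideal bond lengths —
restoring continuity, breaking the anchor — and then re-closed, with up to
10 deterministic jittered restarts (σ = 25°). A closure is accepted only if
the segment's clash score is exactly 0 and every peptide bond lies in
[1.2, 1.5] Å; otherwise the gap is kept and later treated as an insertion.

Gap elongation orders extents by total modelled length, then by how many
consumed flank residues are helix/strand in the template (coil is cheaper
to sacrifice), then N-side first. Database filling scores each
CCD-converged candidate with the six backbone scorers plus the pre-CCD
stem RMSD (the 6-stem-atom superposition residual), linearly combined;
the best candidate is committed per gap ("per-gap commit": the environment
is updated only when a gap is resolved). The Monte Carlo fallback samples
φ/ψ from the trained torsion tables, re-closes with a short CCD after each
single-residue move, applies Metropolis acceptance on the combined score
(closure entering through the stem term) under geometric cooling
(T₀ = 100 score units, cooling 0.92/sweep), and applies the elongation
scheme without the 12-residue cap when a gap persistently fails. Terminal
overhangs are modelled by best-of-N torsion sampling when ≤ 10 residues,
else trimmed with a warning.

The regularizer is a deliberate replacement for a molecular-mechanics
minimizer: restrained steepest descent on harmonic bond deviations from
ideal geometry plus the clash penalty, with backtracking line search (a
step is accepted only if the penalty decreases), a hard projection keeping
every CA within 0.5 Å of its input position, and termination when the
maximal atom shift falls below 0.01 Å. Sidechain atoms follow their CA
rigidly. It fixes stretched bonds and shallow clashes; it is not a force
field, and the extension point for one is documented in
`build_from_raw_model()`.

## The synthetic world, and what green tests mean

Every fixture is generated in code under fixed seeds: ideal helices
(φ = −57°, ψ = −47°), extended strands, a hairpin whose turn torsions were
chosen once so that cross-strand hydrogen bonds register without steric
overlap, helix-loop-helix toy proteins with rejection-sampled clash-free
sidechains, loop cases, labelled decoy sets and miniature databases. These
fixtures are geometric, not biological: they have ideal bond geometry, no
solvent, no ligands, no crystal contacts, no experimental noise, and
sequence drawn uniformly rather than from nature. A green suite therefore
establishes internal correctness — coordinate synchronization, solver
exactness against brute force, self-retrieval, determinism, the directional
effect of database content on loop accuracy — and not benchmark-level
accuracy on real proteins, which would require full-scale databases and
external test sets.

Two scaling notes, stated openly: the Monte Carlo loop-filling module test
runs 400 steps × 2 seeds (not 2000 × 5) because each step costs ~0.1 s in
pure R; and the inverse-Boltzmann recovery test pairs the Boltzmann-sampled
context with a dominant uniform context, since with a single context the
pooled-reference estimator is identically zero by construction.

## Known limitations

Single-chain targets and single-conformer models only; no cis prolines, no
hydrogens beyond the amide H implicit in the hydrogen-bond model; the
secondary-structure stand-in is not DSSP at its edge cases; azimuth bins do
not wrap; PDB writing only (mmCIF is read-only, atom_site subset); residue
numbers above 9999 are refused rather than written in hybrid-36; sequence
profiles, solvent accessibility and residue depth are intentionally absent
from the databases; and the regularizer is not a substitute for
molecular-mechanics minimization.
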