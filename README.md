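# homodel

A scriptable homology-modelling toolbox for single-chain protein targets,
written in R. Given a target–template sequence alignment and a template
structure, it transfers the conserved backbone, resolves small deletions by
local relaxation, fills insertions with loop candidates retrieved from a
stem-geometry-hashed fragment database (with a simulated-annealing fallback
in torsion space), rebuilds sidechains by combinatorial rotamer packing and
regularizes the stereochemistry of the final model.

It is aimed at structural bioinformaticians who want the individual building
blocks of a modelling engine — backbone container, loop databases, scorers,
packing solvers — as composable, testable library functions rather than a
monolithic black box. All test inputs are generated synthetically; nothing
is downloaded.

## The pieces

* **BackboneList** — per-residue N, CA, C, O, CB with synchronized Cartesian
  and internal coordinates. Setting a single φ/ψ propagates rigidly to all
  downstream atoms (`backbone_from_torsions()`, `set_torsion()`).
* **CCD loop closure** — cyclic coordinate descent onto stem anchors: per
  torsion the closed-form angle θ* = atan2(b, a) minimising
  Σₖ |Mₖ(θ) − Fₖ|² over the last residue's N, CA, C (`ccd_close()`).
* **StructureDB / FragDB** — a linear store of chain data addressable as
  (chain, offset, length), and a fragment index keyed by the discretized
  six-descriptor stem geometry (l, d, α, β, γ, δ) with CA-RMSD redundancy
  removal (`db_add_chain()`, `fragdb_add_fragments()`, `fragdb_query()`).
* **Knowledge-based scorers** — inverse-Boltzmann statistical potentials
  E(bin | ctx) = −ln[(N_obs + p)/(N_ref + p)] trained from a StructureDB
  (CB–CB distance, CA–CA distance × CB-direction, φ/ψ torsion, CB packing
  count), plus clash, hydrogen-bond and pairwise-constraint scorers, all
  evaluated against an incrementally updated scoring environment
  (`train_potentials()`, `score_segment()`, `combine_scores()`).
* **Sidechain packing** — backbone-dependent rotamer libraries (the
  Dunbrack 2010 bbdep text dialect is readable), rigid and flexible rotamer
  models, SCWRL3-style piecewise-linear repulsion, disulfide detection,
  Goldstein dead-end elimination, edge decomposition, exact
  tree-decomposition dynamic programming, A\* enumeration within an energy
  window, Monte Carlo, and sub-rotamer optimization
  (`reconstruct_sidechains()` and the `solve_*()` family).
* **Pipeline + CLI** — `build_raw_model()` → `build_from_raw_model()`, or
  `inst/cli/homodel build-model -f aln.fasta -e template.pdb -o model.pdb`.

## Worked example

Cut a 4-residue loop out of a synthetic toy protein, rebuild it from a
miniature fragment database that contains a homologous loop, and put the
sidechains back:

```r
library(homodel)

tp <- make_toy_protein(24, seed = 1)          # helix-loop-helix, packed
lc <- make_loop_case(tp, 12:15)               # remove loop residues 12-15
lc$mh
#> <modelling_handle> 24 residues, 20 built, 1 gap(s)

md <- make_mini_db(list(tp, make_toy_protein(20, 6)), lengths = 3:6)
md$fdb
#> <frag_db> 40 fragments in 40 buckets (dist_bin 1 A, angle_bin 20 deg)

pots <- train_potentials(md$sdb)
mh <- fill_loops_by_database(lc$mh, md$fdb, md$sdb, pots, pipeline_config())
mh
#> <modelling_handle> 24 residues, 24 built, 0 gap(s)

ref <- backbone_from_chain(tp, "A")
sqrt(mean(rowSums((mh$ca[12:15, ] - ref$ca[12:15, ])^2)))
#> [1] 0   # the native loop was retrieved and re-fitted exactly

model <- reconstruct_sidechains(mh_to_structure(mh),
                                fixture_rotamer_library(), mode = "FRM")
count_clashing_sidechains(model)
#> [1] 0
```

The zero RMSD is the self-retrieval case: the database holds the native
fragment, the stem-geometry query finds it, and CCD re-fits it onto the
stems. Acceptance criterion 9 (`tests/testthat/test-acceptance.R`) shows the
contrast: the same gap filled from a database of unrelated helices, strands
and hairpins ends up > 2 Å from the native loop.

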