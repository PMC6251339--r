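---
title: "Evolutionary search for porous organic cages: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary search for porous organic cages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Porous organic cages are discrete molecules with an intrinsic cavity and
multiple windows. The most common synthesis is dynamic imine condensation of
a tri-topic aldehyde with a di-topic primary amine, which on the two
topologies treated here gives `Tri4Di6` (tetrahedral; four tri-topic blocks
on vertices, six di-topic on edges) or `Tri8Di12` (cubic) assemblies. Even
modest precursor libraries span millions of (aldehyde, amine, topology)
combinations, and the property that makes a cage useful — a persistent,
symmetric cavity of the right size — emerges only after 3D assembly. evocage
couples a cheap geometric property pipeline to a generational evolutionary
algorithm (EA) so that only a small fraction of the space is ever built.

## The genome and its operators

A candidate is the fixed-length chromosome `(BB_tri, BB_di, topology)`. The
operators never modify a precursor chemically; they only swap whole genes,
which keeps every candidate a plausible one-pot synthesis from cataloged
precursors:

* **Crossover** picks one gene position uniformly and exchanges it between
  two parents, giving two complementary offspring; one of the two (chosen at
  random) enters the offspring pool. With 20 crossover operations and 5
  mutations per generation a 100-generation run explores at most
  25 + 100×25 = 2,525 individuals.
* **Random mutation** replaces one gene with a uniformly drawn alternative
  of the same role.
* **Similarity mutation** replaces a building-block gene with its n-th most
  similar database neighbor under Dice similarity of Morgan (radius 1)
  fingerprints; a per-(chromosome, gene) counter advances n on repeated
  application, so the operator walks outward through chemical space instead
  of jumping. The default schedule alternates random and similarity
  mutations, which mixes exploration with local refinement.

Selection supports truncation to the fittest, roulette wheel with and
without elitism, and stochastic universal sampling; all tie-breaks are by
ascending chromosome key so runs are reproducible. Offspring join the
population and the best `population_size` members survive; at equal fitness
incumbents are preferred, so replacement happens only for strictly better
offspring. Under this rule the best fitness is non-decreasing.

## Fitness

```
fitness = (a·ΔPore + b·ΔWindow + c·Asymmetry)^(-1)
```

* ΔPore — |pore − ideal| in Å. The pore (cavity) diameter is twice the
  distance from the mass-weighted center to the nearest atom van der Waals
  surface (Bondi radii), i.e. the largest sphere fitting in the cavity.
* ΔWindow — |mean(windows) − ideal|. A window diameter is the largest circle
  through a topology face: we maximize `min_i(|c − x_i| − R_i)` over circle
  centers `c` in the face plane, constrained to the face polygon, by a
  coarse grid followed by Nelder–Mead. The mean is used to collapse the
  per-face values because the windows of a two-component, single-topology
  cage are chemically equivalent.
* Asymmetry — the sum of absolute pairwise differences among chemically
  identical windows (one group per face class here); 0 for a perfectly
  symmetric cage and growing linearly with uniform window scaling.

Each term is divided by its population mean (over finite values; zero-mean
terms pass through) before weighting, so no single objective dominates by
its natural scale alone, and normalization is recomputed whenever offspring
join the evaluation pool so parents and offspring are comparable. The
inverse carries a floor `epsilon = 1e-9`, capping fitness at `1/epsilon`
for an exact target match. Failed assemblies or optimizations keep their
population slot with fitness 0. Three presets ship: `cc3` (a=10, b=10, c=1;
ideal 5.72 / 3.91 Å), `persistency` (5, 1, 10; 5.0 Å) and `big_pore`
(10, 0, 5; 16.0 Å).

## Assembly and geometry pipeline

Building blocks come from SMILES; the database filter keeps neutral,
metal-free molecules that classify as exactly tri-topic aldehydes
(`[CX3H1](=O)` on carbon) or di-topic primary amines (`[NX3;H2]` not
adjacent to a carbonyl — amide nitrogens cannot form imines and are
excluded). One conformer per block is embedded with RDKit's ETKDG (v3)
under a fixed seed, which makes the whole pipeline deterministic.

Assembly places the tri-topic blocks on topology vertices, oriented by the
best proper rotation (Kabsch, over all anchor/edge pairings) taking the
three carbonyl-carbon anchors toward the incident edge midpoints, and the
di-topic blocks on edges with the N–N axis along the edge and the backbone
rolled outward. Every junction is condensed: the aldehyde oxygen and two
amine hydrogens leave, a C=N double bond forms. This fixes two conservation
laws used throughout the tests: imine bonds = 2E, and mass =
V·MW(tri) + E·MW(di) − 2E·MW(H₂O). The default cage radius is 1.5× the sum
of the two blocks' end-group distances, large enough to avoid clashes
before relaxation and tunable per call.

Geometry refinement is a pluggable optimizer interface. Two backends ship:
a deterministic harmonic bond-spring optimizer (gradient descent with
backtracking on `Σ k(r − r0)²`; it only ever accepts energy decreases) and
an identity optimizer for invariance testing. Relaxation is two-stage —
junction atoms and their neighbors first, with everything else constrained,
then the whole cage. Flexibility is probed by a seeded perturbation
conformer search (`n_samples` Gaussian kicks, each re-optimized, lowest
energy kept), a deterministic stand-in honoring the same select-the-lowest
contract as high-temperature MD sampling; an MD backend can be plugged in
through the same interface. The shipped harmonic backend models bonds only
(no angles or non-bonded terms), so its geometries support protocol and
property testing, not force-field-grade structure prediction. A cage is
called shape-persistent when the conformer search retains at least half the
pore diameter and the absolute pore stays above 2.8 Å (roughly the smallest
guest-relevant cavity); both thresholds are arguments.

## Precomputed landscapes and benchmarking

To compare EA setups cheaply, `precompute_landscape()` evaluates every
chromosome of a small space once, normalizes penalties against the
full-space means (making the stored fitness population-independent), and
requires a unique argmax. `benchmark_setup()` then runs the EA repeatedly
with counter-derived seeds, succeeds when the optimum is evaluated into a
run's pool, and reports the success probability next to the analytic
baseline `1 − (1 − 1/N)^draws` at the same mean per-run evaluation budget —
the honest budget, since caching means a run evaluates far fewer
chromosomes than the nominal bound.

## The synthetic generators — what they emulate and what they do not

* `generate_bb_library()` enumerates substituted triformyl-arene and
  alkyl/aryl/ether diamine scaffolds (chain lengths 2–10, ring and branch
  variants), shuffles them by seed and runs them through the standard
  filter. It emulates the diversity structure of a curated commercial
  library — enough spread in size, rigidity and substitution for similarity
  ranking and descriptor trends to be non-trivial — but makes no attempt to
  match real property distributions.
* `generate_toy_cage()` spreads dummy atoms along polyhedron edges projected
  onto a sphere, so the pore diameter is exactly `2(shell − vdw)` and all
  windows are equal by symmetry; these closed forms are the oracles for the
  property code.
* `generate_landscape()` plants an optimum in (tri, di) index space, decays
  fitness as `exp(−4d)` in the normalized index distance and multiplies
  log-normal noise (`ruggedness`, default 0.1 — mildly rugged, as expected
  when fingerprint similarity correlates with fitness), clipped below the
  planted value so the optimum stays unique. Its stub database carries
  sliding-window fingerprints whose Dice similarity decays with index
  distance, so similarity mutation is meaningful on abstract landscapes.

Passing tests on these generators demonstrate the correctness of the
protocol — operators, bookkeeping, convergence, property oracles — not the
chemical accuracy of any particular force field or the transferability of
fitness values to laboratory cages.

## Numerical choices and degenerate inputs

* Fingerprints: OpenBabel ECFP2 (the Morgan radius-1 analog), OR-folded to
  2048 bits; Dice similarity of two empty fingerprints is defined as 1.
* Window search: 9×9 coarse grid in the face plane, Nelder–Mead refinement
  from the three best starts, centers constrained to the face polygon
  (outside positions are penalized); faces with no free path report 0.
* Convergence: a run stops once the top-5 chromosome identity set has been
  unchanged for `convergence_patience` consecutive generations (default
  20), on a generation budget, or when a designated target is evaluated.
* RNG: one master seed spawns independent named streams (init, selection,
  crossover, mutation, sampling), so changing one subsystem does not shift
  another's draws; run records from equal seeds are byte-identical.
* Degenerate cases: single-candidate mutation returns the only candidate;
  the similarity counter wraps with a warning when it exhausts the
  database; all-zero-fitness selection falls back to uniform draws with a
  warning; embedding failures drop the molecule from the database with a
  logged count.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at deliberately desk-friendly
scales chosen as the smallest sizes at which each claim is informative: a
4×8 embedded library (20 assemblies per topology for the conservation
laws), 20 random toy cages against 0.05 Å-resolution grid oracles, and a
20×50 single-topology landscape (1,000 cages) with 200 EA runs for the
rediscovery benchmark. The combinatorial and baseline quantities
(49,700-cage mock space, 5% exploration fraction and random-search
baseline, the ~6M and ~10^7 full-space counts) are exact arithmetic and are
recomputed as such.

## Known limitations

* The harmonic optimizer is intentionally minimal; energies are not
  comparable across chromosomes and shape-persistency calls with it are
  qualitative. Plug in a real force-field backend for structural claims.
* Window grouping assumes all faces of a topology are chemically
  equivalent, which holds for single-topology, two-component cages only.
* No solid-state effects: packing, solvent and crystallization are out of
  scope; properties are single-molecule.
* Synthetic accessibility is not scored; candidates are combinations of
  cataloged precursors but may still be hard to make.
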