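---
title: "Hot-spot guided screening triage and the ISE filter ensemble"
author: "dockscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hot-spot guided screening triage and the ISE filter ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockscreen)
```

## The problem

Blocking a protein--protein interaction with a small molecule starts from
knowing *where* on the interface binding energy is concentrated. For the
egg--sperm adhesion pair JUNO--IZUMO1, the receptor JUNO presents a
contiguous patch of interface residues whose individual contributions can
be estimated by virtual alanine scanning; residues whose virtual mutation
costs at least 4 kcal/mol of computed binding affinity are called *hot
spots*. Docked small molecules are then triaged by whether they engage
those hot spots (a hydrogen bond to ARG87 plus van der Waals contact with
TYR44, GLU45, LEU81, MET83 and TYR147 for the full site), ranked by three
properties (docking score, attractive contact count, buried surface area),
split into "Best" and "Worst" classes, and used to train a ligand-based
classifier -- an Iterative Stochastic Elimination (ISE) ensemble of
descriptor-range filters -- that can screen millions of molecules cheaply.

`dockscreen` implements this pipeline end to end as reusable, tested
components, with synthetic-data generators so every stage is verifiable
without external downloads.

## The frozen alanine scan

`alanine_scan()` virtually mutates one receptor residue to alanine by
deleting its side-chain atoms beyond C-beta. Both states use **identical
frozen coordinates**: no minimization, no repacking, no rotation about the
CA--CB bond, no hydrogen rebuilding. The reported *delta affinity* is

$$\Delta A = E_\mathrm{bind}(\text{wild type}) -
             E_\mathrm{bind}(\text{truncated}),$$

which under any pairwise-additive potential equals exactly the summed
interaction of the deleted atoms with the partner side. That additivity is
a tested invariant (brute-force pairwise summation agrees to 1e-9
kcal/mol), as is invariance under rigid motion of the whole complex.
Glycine and alanine are defined to score zero: there is nothing to
truncate. A scan threshold of 4 kcal/mol (the `hot_spot_threshold` of
`energy_params()`) calls hot spots; `call_hot_spots()` reports whatever the
threshold yields, with no assumption about how many hot spots a site
"should" contain.

The potential itself is a **declared stand-in**, not a validated force
field: Lennard-Jones 6-12 with Bondi radii (pair minimum at $r_i + r_j$,
well depth the geometric mean of per-element depths) plus Coulomb with a
distance-dependent dielectric $\varepsilon(r) = 4r$ and coarse
residue-template partial charges, cut off at 10 Angstrom. Absolute
kcal/mol values are therefore not comparable with commercial interface
scorers; what the package preserves -- and tests -- is the frozen-scan
*procedure* and its additivity. Free-energy-grade estimates, side-chain
repacking and protonation assignment are out of scope.

Interface residues are found by a local geometric rule (receptor residues
with any heavy atom within 4.5 Angstrom of a partner heavy atom) rather
than an external interface server, keeping the pipeline self-contained;
the cutoff is configurable.

## Pose interaction profiles

`profile_pose()` summarises one docked pose by three quantities:

* **Hydrogen bonds** (`detect_hbonds()`): polar heavy-atom pairs (N/O/S on
  both sides, donors and acceptors treated symmetrically) at
  donor--acceptor distance <= 3.5 Angstrom. When explicit hydrogens are
  present a D-H...A angle >= 120 degrees is additionally required; crystal
  structures deposited without protons fall back to the distance-only
  criterion. Both cutoffs are parameters of `geometry_params()`.
* **Attractive van der Waals contacts** (`count_attractive_vdw()`): heavy
  atom pairs whose distance over the Bondi radius sum lies in
  [0.89, 1.30] -- near-van-der-Waals packing, excluding clashes below the
  window and distant pairs above it. The window is configurable.
* **Buried surface area** (`buried_surface_area()`):
  SASA(receptor) + SASA(ligand) - SASA(complex), i.e. the *two-sided*
  convention, which for drug-sized ligands lands in the several-hundred
  square-Angstrom range of the candidate table shipped with the package.
  SASA is Shrake--Rupley with probe 1.4 Angstrom and a **deterministic
  golden-spiral lattice** of 960 points per atom. A deterministic lattice
  was chosen over random sampling so results are bit-stable across runs;
  doubling the lattice changes toy-pose BSA by under 1%, an isolated atom
  agrees with $4\pi(r+p)^2$ to under 1%, and the two-sphere case agrees
  with the closed-form spherical-cap solution to within 2% (all tested).

The docking score is deliberately *ingested, never computed*: it is the
external docking engine's pose energy and enters only as a ranking input.

## Criteria, labels, ranking

`criteria_preset()` ships three named interaction-requirement sets:
`"full_site"` (H-bond ARG87; contacts TYR44, GLU45, MET83, LEU81, TYR147)
and the two half-site presets `"subsite_a"` (MET83, LEU81, TYR147) and
`"subsite_b"` (TYR44, GLU45, TRP62), both keeping the ARG87 hydrogen bond.
LYS163 sits too far from the rest of the site to be required anywhere, and
TRP62 is required only within sub-site B, where docked poses can actually
reach it. `passes_criteria()` is monotone: adding interactions never turns
a pass into a fail.

`label_best_worst()` applies the two disjoint regions of (docking score,
BSA, contact count) space -- Best strictly below -3 kcal/mol with BSA >=
750 and contacts >= 250; Worst at score >= -1 with BSA <= 600 and contacts
<= 150 -- with strict-versus-inclusive comparisons following that
punctuation exactly, so the boundary score -3 is *neither*. Threshold
membership is the class definition used throughout; no quantile-based
definition is applied. `rank_molecules()` aggregates the three properties
by rank sum (score ascending, contacts and BSA descending, ties sharing
the minimum rank, final ties broken by score then molecule id): expert
visual inspection of poses is not reproducible, and a rank sum with
declared tie-breaks is the reproducible surrogate for it -- deterministic
and permutation-invariant by construction (tested).

```{r}
filter_and_count(docked_candidates())
rank_molecules(docked_candidates())[1:3, c("molecule_id", "rank_score")]
```

## The descriptor panel

`compute_descriptors()` produces a fixed, versioned panel of 151
two-dimensional descriptors: Open Babel physicochemical terms (molecular
weight, logP, TPSA, molar refractivity, H-bond donor/acceptor counts),
constitutional counts (elements, bonds by order, rings, degrees), classic
topological indices (Wiener, Harary, Zagreb, Randic/chi, kappa shape,
Balaban J, eccentric connectivity, Platt) and topological
autocorrelations (Moreau--Broto, Moran, Geary) of atomic mass,
electronegativity, polarizability and van der Waals radius at lags 1--8.
Every molecule is canonicalized before computation, so two spellings of
one structure yield identical rows (tested bitwise). The panel is an
*open stand-in* for the commercial 206-descriptor set used historically:
the ISE algorithm operates on any real-valued descriptor matrix, so the
algorithmic surface is unchanged, but equivalence with models trained on
the commercial panel is neither obtainable nor claimed.
`prune_descriptors()` removes zero-variance columns and, from each pair
correlated above |r| = 0.99, the later-named column; pruning is
order-stable and idempotent. A `min_mw` flag reproduces the
molecular-weight > 350 g/mol restriction applied when screening for
site-spanning ligands.

## The ISE filter ensemble

The ISE literature defines the semantics -- iteratively eliminate
descriptor-range values that keep appearing in bad filters, keep the
statistically good filters -- but not one canonical parameterisation, so
the internals here are fully declared:

1. Descriptors are cut into `n_bins` (default 10) equal-frequency bins on
   the training split only.
2. Each iteration draws `n_candidates` (default 2000) random conjunctions
   of 1--4 descriptor-bin-range clauses from the active pool and scores
   each by training MCC (positive class "Best").
3. The worst 25% of candidates are inspected: any (descriptor, bin) value
   whose usage among them is at least twice its expected share (given at
   least `min_cell_usage` = 5 total uses) is eliminated from the pool.
4. Iterate until the pool is stable or `max_iterations` (default 50).
5. Candidates with training MCC >= `mcc_floor` (default 0.7, inside the
   0.77--0.86 range reported for well-trained filter sets on this kind of
   docking-derived learning set) are deduplicated greedily, best first,
   dropping any candidate whose clause-cell Jaccard overlap with a kept
   filter reaches 0.75.

The molecular index of `score_index()` is the unweighted
$(n_\mathrm{pass} - n_\mathrm{fail}) / n_\mathrm{filters}$, matching the
stated [-1, 1] bounds and pass/fail semantics; an MCC-weighted variant
exists behind `weight_by_mcc` but is off by default, since nothing in the
source procedure indicates weighting. `cross_validate()` uses stratified
5-fold splits (fold sizes per class differing by at most one), scores
every molecule exactly once as test data, and merges the five filter sets
into a final model deduplicated by clause signature -- the union rule is a
declared decision, as is everything the dedup does. All randomness flows
from one seed; a retrained model serializes byte-identically
(`write_ise_model()` emits versioned JSON carrying the descriptor-manifest
hash, every hyperparameter and the seed).

`enrichment_curve()` reports TP/FP at every index threshold, with an
explicit `Inf` sentinel when FP reaches zero -- never silently dropped --
and `select_cutoff()` picks the smallest threshold whose ratio meets the
requested enrichment, keeping the candidate pool as large as possible at
that purity.

## What the synthetic generators emulate

* `make_toy_complex()` builds two-chain complexes in which each planted
  interaction is provably the only interaction its atoms make: residues
  sit 12 Angstrom apart with only the backbone nitrogen near the contact
  plane, planted contacts are carbons at exactly the Bondi radius sum
  (ratio 1.0, mid-window) from a C-beta, and planted hydrogen bonds are
  oxygens at 2.65 Angstrom from a backbone nitrogen. The 2.65 Angstrom
  choice is deliberate: it is a valid (short) hydrogen-bond distance whose
  N/O radius-sum ratio (0.863) sits *below* the attractive-contact window,
  so the hydrogen-bond count and the contact count stay independently
  recoverable; a 2.9 Angstrom pair would also be counted as a contact and
  the planted ledger would no longer be exact.
* `make_pose_table()` draws pose records inside the Best region, the Worst
  region or the gap, so labeling must recover the planted classes exactly.
* `make_learning_set()` plants a Best-versus-Worst separation in a
  descriptor matrix: Worst rows standard normal everywhere, Best rows
  shifted by `effect_size` pooled SDs in `n_informative` randomly chosen
  descriptors. Defaults mirror the reference learning-set geometry (68
  Best, 69 Worst, 206 descriptors); the noise is standard normal because the
  generator's job is to exercise the algorithms at a stated effect size,
  not to mimic any particular descriptor package's marginals.

Every generator returns a machine-readable truth ledger, and all recovery
tests assert against the ledger rather than re-derived values. Passing
these tests shows the algorithms recover what was planted under clean,
independent noise -- it does not show that real docking scores or real
descriptor distributions carry comparable signal: docking-derived labels
carry a substantial false-positive fraction, which can defeat the
prospective use of any classifier trained on them.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise ISE recovery at 68/69
molecules x 50 descriptors with 3 informative descriptors shifted by 2
pooled SDs, over 20 seeds, with a search of 600 candidates per iteration
and at most 15 iterations -- deep enough that the median pooled-test MCC
across seeds clears 0.5 and the selected cutoff enriches at least
threefold over the index floor, while a pure-noise control almost never
yields a model (a per-fold search can still come up empty on an unlucky
seed, which is reported honestly as NA indices for that fold). The
package defaults (2000 candidates, 50 iterations) are what a production
run would use. Other fixed choices: SASA lattice 960 points (tested
against 1920), interaction cutoff 10 Angstrom, interface cutoff 4.5
Angstrom, equal-frequency binning via type-7 quantiles with every value
mapped to exactly one bin, and clause intervals half-open
[lower, upper) so bin membership and interval membership coincide.

Degenerate inputs are defined, not accidental: empty interfaces scan to an
empty table; an all-zero confusion matrix is an error while a degenerate
margin gives MCC 0; a constant descriptor collapses to a single bin with
a warning; a learning set with one class refuses to train; and a model
with zero filters refuses to score.

## Pipeline reproducibility

`run_pipeline()` executes the enabled stages in a fixed dependency order
from one YAML config and writes a manifest with input/output MD5 hashes,
parameters and seeds. Each stage derives its seed as
`global_seed + 104729 * stage_index` (mod 2^31 - 1) with stage indices
fixed by name, so toggling unrelated stages never perturbs a stage's
randomness; identical configs reproduce byte-identical outputs (tested).

## Known limitations

* The scanning potential ranks residues plausibly but its absolute
  energies are not transferable; hot-spot sets from other scoring
  functions will differ near the threshold.
* Hydrogen-bond detection without explicit protons is distance-only and
  symmetric in donor/acceptor; protonation-state effects are ignored.
* BSA laterality conventions differ between tools (one-sided vs
  two-sided); this package is two-sided throughout and values should only
  be compared within that convention.
* The descriptor panel is 2D only; conformer-dependent descriptors are out
  of scope.
* ISE searches a combinatorial space stochastically: per-fold failure to
  find any filter above the MCC floor is possible at small search sizes
  and is surfaced as a warning plus NA test indices, not hidden.
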