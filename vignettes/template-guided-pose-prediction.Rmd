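---
title: "Template-guided ligand pose prediction: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-guided ligand pose prediction: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`templig` predicts how a small molecule binds a protein by borrowing the
pose of a co-crystallized *template* ligand of the same protein, and it
ships the statistical machinery for asking when that borrowing is
justified. This vignette explains the models, the tunable parameters and
the design decisions, in the order the pipeline runs them.

## Hybrid 3D similarity

The central quantity is a hybrid similarity between a query conformer and a
template ligand pose,

$$S \;=\; \mathrm{ShapeScore} + \mathrm{FeatureScore} \in [0,2],$$

with both components in $[0,1]$ and the value 2 attained exactly when the
same molecule sits in the same pose. The conventional cutoff $S \ge 1.2$
separates "similar" from "dissimilar" pairs and is stored in
`templig_defaults()$similar_cutoff`.

**Shape.** Every heavy atom is a spherical Gaussian of amplitude $p = 2.7$
whose integral reproduces its van der Waals volume
($\alpha_i = \pi\,(3p/(4\pi r_i^3))^{2/3}$). The shape overlap of two
molecules is the first-order (pairwise) product integral
$V_{AB} = \sum_{ij} p^2 (\pi/(\alpha_i+\alpha_j))^{3/2}
e^{-\alpha_i\alpha_j d_{ij}^2/(\alpha_i+\alpha_j)}$. Because $V_{AB}$ is an
inner product of additive densities, the Cauchy–Schwarz inequality
guarantees $V_{AB} \le \max(V_{AA}, V_{BB})$, so the normalization

$$\mathrm{ShapeScore} = V_{AB} / \max(V_{AA}, V_{BB})$$

lies in $[0,1]$ and equals 1 exactly at identity. We chose max-
normalization over a Tanimoto-style one because it makes the documented
endpoints exact rather than asymptotic.

**Pharmacophore.** Features are perceived rule-based on the heavy-atom
graph: N/O with an (explicit or implied) hydrogen are donors; N/O with
non-positive formal charge acceptors; carbons with no heteroatom neighbour
hydrophobes; each aromatic ring one feature at its centroid; charged atoms
charge centers. Matching is a Gaussian kernel of inter-feature distance
($\sigma = 1$ Å) summed over same-kind pairs, normalized like the shape
term. Aromaticity is detected from ring bond orders (Kekulé alternation or
explicit aromatic orders) on 5–7 rings of C/N/O/S; exotic heteroaromatics
outside that envelope are a known limitation.

**Alignment optimizer.** Both molecules are first expressed in canonical
principal-axes frames (axes ordered by variance, signs fixed by coordinate
skewness). Twelve deterministic starting rotations (axis flips × cyclic
permutations) are screened and the best four refined by Nelder–Mead over
six rigid parameters. Working in canonical frames makes the result exactly
invariant to the laboratory frame of the inputs — an invariance the test
suite asserts at 1e-3. Torsional flexibility is deliberately *not* part of
the alignment: it is carried by the conformer ensemble.

## Conformer ensembles

Conformers are generated from SMILES by distance-geometry embedding with a
seed-determined random state, relaxed with a standard small-molecule force
field (MMFF, falling back to UFF), deduplicated by symmetry-aware best-fit
RMSD (threshold 0.5 Å, graph automorphisms included) and capped at 200 —
the conventional ensemble size for template superimposition. The first
conformer is always the molecule's deterministic base embedding, so every
ensemble contains the ligand's canonical geometry regardless of seed; the
seeded embeds contribute the rotamer diversity. The number of additional
embedding trials scales with the rotatable-bond count (rigid molecules are
embedded once), so rigid inputs yield exactly one conformer and flexible
ones fill the cap. Identical `(smiles, seed)` inputs give bit-identical
coordinates; three embedding attempts with incremented seeds precede an
embedding-failure error. The embedding itself is delegated to RDKit through
a small Python bridge — it is standard infrastructure, not this package's
contribution — while the deduplication, symmetry handling and ensemble
bookkeeping are implemented here.

## Empirical binding score and local refinement

The protein–ligand score is the published five-term empirical form over
heavy-atom pairs within 8 Å of surface distance
$d = r - R_i - R_j$: two attractive Gaussians
($e^{-(d/0.5)^2}$, $e^{-((d-3)/2)^2}$), quadratic repulsion for $d<0$,
and piecewise-linear hydrophobic ($1 \to 0$ on $d \in [0.5, 1.5]$) and
hydrogen-bond ($1 \to 0$ on $d \in [-0.7, 0]$) terms, with weights
$(-0.035579, -0.005156, 0.840245, -0.035069, -0.587439)$. One deliberate
deviation: the rotor penalty is an *additive* $0.05846\,N_\mathrm{rot}$
term rather than the original divisive $1/(1+w\,N_\mathrm{rot})$ form, so
that the reported total is exactly the dot product of weights and terms
(an invariant the tests check). $N_\mathrm{rot}$ is constant for a given
query, so rankings across templates are unaffected.

Local refinement optimizes 3 translations (bounded by a 2 Å local-search
radius), 3 rotations and all rotatable torsions of the ligand against the
rigid receptor, with bounded quasi-Newton descent followed by simplex
polish to a 1e-6 fixpoint; the returned pose never scores worse than the
start. The search is strictly local by design — an optional deterministic
torsion-perturbed multi-start (`torsion_starts`) exists for exploration
but is off by default, because basin hopping contradicts what a local
refinement step is for. A
translation-only pre-step relieves moderate steric clash; if the weighted
repulsion still exceeds 10 after refinement the pose is declared
irrecoverable. The landscape's piecewise-linear kinks mean the optimizer's
fixpoint is sharp only on smooth regions; near kinks, re-refinement can
wander by a few thousandths of a score unit, which is why exact
stationarity is asserted only on smooth closed-form fixtures.

## Symmetry-aware RMSD

Pose quality is the *in-place* heavy-atom RMSD (no re-fitting) minimized
over all maximum-common-substructure embeddings. For identical graphs this
means all element- and bond-order-preserving automorphisms (found via VF2);
for differing molecules, maximum cliques of the modular-product
compatibility graph (elements, ring membership and bond orders respected,
minimum 3 atoms). Kekulé alternation is normalized to a uniform aromatic
order first, so a para-disubstituted ring flip correctly scores 0. When
the compatibility graph exceeds 600 vertices a greedy connected-extension
heuristic takes over with a warning — a deterministic stand-in for a
wall-clock timeout. The reported `mcs_fraction` refers to the query's
heavy atoms, which also makes the documented asymmetry concrete: swapping
query and template can change the RMSD, because the deviation is always
measured on the query's atoms. In intercomparison, both poses belong to
the same (query) molecule and the MCS machinery only contributes symmetry
handling; in cross-molecule evaluation (deposited ligands with missing
atoms) partial mappings occur and `mcs_fraction` lets users filter them.

## Dataset curation

The filter cascade tests, in order: covalent linkage (any ligand–protein
heavy-atom pair under 1.9 Å), a second ligand centered within 8 Å of the
pocket, ligand contact (< 4 Å) with two or more protein entities, fewer
than 7 heavy atoms, molecular weight outside 140–800 Da, and ligand burial
below 50%. The first failure is recorded as the discard reason. Burial is
$\Delta\mathrm{SASA}/\mathrm{SASA_{lig}}$ with solvent-accessible surface
areas from deterministic Shrake–Rupley sampling (golden-spiral points, 196
per atom, probe 1.4 Å); tests verify 2% agreement against a
quadruple-density recomputation and an analytic spherical-cap case. The
geometric thresholds (1.9, 8, 4 Å) are this package's conventions — the
curation rules are usually stated without them — and are configurable via
`curation_defaults()`. Boundary semantics are inclusive (7 heavy atoms,
140 Da, 50% burial all keep) because the discard rules are phrased
strictly. Grouping keeps, per protein, the binding site with the most
co-bound ligands (single-linkage on ligand centers, 8 Å) and resolves
duplicate ligands (identical canonical SMILES) to the lowest R-free.

## Pipeline and ranking

Per template: best superimposition → local refinement against *that
template's* receptor → empirical score. Candidates are re-ranked by
$\mathrm{Hybrid} = \mathrm{Vina} + \alpha S$ with
$\alpha = \min(\mathrm{Vina})/2$ taken over the current run's refined
candidates — the set available in every mode, and identical to "all
ligands on the target protein" when run library-wide. Since good scores
are negative, $\alpha < 0$ and higher similarity lowers (improves) the
hybrid score; the division by 2 makes the similarity contribution
commensurate with the best binding score because $S \le 2$. Ties resolve
by lower binding score, then higher similarity, then template id. Only the
single best conformer per template is refined, following the method's
written procedure; exploring several is left to callers via repeated
seeds. A 10 Å binding-site distance check (strictly larger discards) is
provided for evaluation settings where predictions may land in the wrong
pocket.

## Intercomparison and the minimum-template bootstrap

`intercompare_all()` processes every ordered pair of distinct library
members — N·(N−1) records of (similarity, RMSD), where the RMSD compares
the best-superimposed query conformer against the query's *own* crystal
pose. `min_templates_bootstrap()` estimates, within one similarity bin,
the smallest n such that n randomly drawn templates contain a good one:
inner loop of 500 draws of n records without replacement, keeping each
minimum RMSD, growing n until mean + SE ≤ 2.0 Å; outer loop of 100
replicates reporting mean and SE of N_min. SE is the standard deviation
over replicates divided by √reps (the alternative — raw SD — would widen
N_min by a factor ~√500 and is not what "standard error" means here). Bins
need at least 100 records; similarity bins are 0.1-wide on [0.8, 1.6) with
open-ended tails, reported as insufficient otherwise.

## Synthetic fixtures and what they do (not) show

`make_toy_library()` builds a concave shell pocket molded at van der Waals
contact + 0.9 Å around a seed ligand pose (162 icosphere directions, a 90°
aperture giving the seed ligand ~70% burial so the 50% rule is exercised
from both sides by widening), fills it with decorated scaffold variants,
and refines every planted "crystal" pose to a score minimum — as refined
experimental poses are. Templates are drug-like toys (140–200 Da, 7+ heavy
atoms) that pass the curation cascade by construction; the
`dissimilar-shared-mode` profile plants a saturated-ring query with 2D
similarity < 0.5 to every aromatic template yet the same binding mode, the
phenomenon the intercomparison is designed to expose. A seeded rigid
re-orientation of the whole complex makes different seeds exercise
different laboratory frames. These fixtures emulate geometry and scoring
structure, not protein chemistry: shells are poly-glycine pseudo-atoms
with no side chains, flexibility, water or electrostatics, so passing
tests demonstrate the machinery's correctness and internal consistency,
not accuracy on real crystal structures.

## Problem sizes and numerical choices

The test-suite and acceptance runs use desk-scale sizes chosen as the
smallest that still exercise every code path: 2–3 template libraries,
ensembles of 5–12 conformers for flexible toy ligands (the 200 cap is
exercised once on a long alkane), 25 fixture molecules for the endpoint
checks, bootstrap bins of 150–200 records, and 50 seeded end-to-end
prediction runs. Convergence/tie-break conventions worth knowing:
alignment ties go to the lower conformer index; refinement returns the
start pose when no improvement is found; eigen-sign conventions in the
principal-frame code are fixed by skewness so repeated runs are
bit-identical; all randomness flows through explicit integer seeds
(derived streams use small offsets, staying well below 2^31).

## Known limitations

Proteins are rigid throughout (pocket plasticity is out of scope); bond
orders for ligands read from PDB records are perceived as single bonds
(SDF connectivity is authoritative when available); aromaticity perception
covers common 5–7-membered rings; the empirical score is a functional
re-statement, not a bit-exact replica, of the published docking score; and
highly symmetric molecules with > 5000 graph automorphisms are truncated
in the symmetry search.
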