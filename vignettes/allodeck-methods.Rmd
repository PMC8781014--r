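---
title: "Methods: scoring, docking, site prediction and modulator calls in allodeck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, docking, site prediction and modulator calls in allodeck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodeck)
```

`allodeck` implements a structure-based pipeline for allosteric-site work on
GPCR-like receptors: an empirical pair potential with per-residue
decomposition, Monte-Carlo pose search, cavity detection combined with
elastic-network motion correlation, and an end-point free-energy table layer
that classifies allosteric modulators. This vignette records the models, the
parameters that matter, the numerical choices, and what the synthetic test
fixtures do and do not establish.

## The scoring model

The pair potential is the widely used five-term empirical function of
Vina-family docking engines. Every term is a function of the surface
distance $d' = d - (r_i + r_j)$, the interatomic center distance minus the
two van der Waals radii (C 1.9, N 1.8, O 1.7, S 2.0, P 2.1, F 1.5, Cl 1.8,
Br 2.0, I 2.2, metals 1.2 Å):

* `gauss1` $= e^{-(d'/0.5)^2}$ and `gauss2` $= e^{-((d'-3)/2)^2}$ — two
  attractive shells at contact and at ~3 Å beyond contact;
* `repulsion` $= d'^2$ for $d' < 0$ — a quadratic wall inside contact;
* `hydrophobic` — 1 on $d' \le 0.5$, linear to 0 at $d' = 1.5$, only when
  both atoms are hydrophobic (apolar carbon or halogen);
* `hbond` — 1 on $d' \le -0.7$, linear to 0 at $d' = 0$, only for
  donor–acceptor pairs.

The weighted sum uses the published weights (−0.035579, −0.005156,
0.840245, −0.035069, −0.587439); terms vanish beyond an 8 Å center-distance
cutoff, and the reported affinity divides the intermolecular sum by
$1 + 0.05846\,n_\mathrm{rot}$. Hydrogens never enter the pair loops; polar
hydrogens exist solely to mark donors during typing.

Assumptions worth stating plainly: the function is charge-free (partial
charges are carried through file I/O but ignored by scoring), the receptor
is rigid, and there is no desolvation or electrostatic term. One
property of the function that matters for test design: because `repulsion`
rises as $0.84\,d'^2$ while `hbond` is worth at most $-0.587$, the *net*
optimum of a hydrogen bond sits near $d' \approx -0.35$ (about 3.1–3.2 Å
N–O), not at the full-strength plateau.

### Per-residue decomposition

`score_complex()` accumulates each receptor–ligand pair into the receptor
residue's row, producing nine binding-recognition vectors per residue:
`gauss` (= gauss1+gauss2), `gauss1`, `gauss2`, `repulsion`, `steric`
(= gauss1+gauss2+repulsion), `hbond`, `hydrophobic`, `non_steric`
(= hbond+hydrophobic), and the weighted `residue_energy`. Two design
decisions are deliberate:

* decomposition is computed on the raw intermolecular score *before* the
  rotatable-bond normalization, so the conservation identity
  $\sum_\mathrm{res} E_\mathrm{res} = E_\mathrm{inter}$ holds exactly
  (tested to 1e-6 and against a brute-force pair enumeration on 500×50-atom
  random complexes);
* the eight term columns are reported unweighted while `residue_energy` is
  weighted — whether a per-residue report should weight individual terms is
  genuinely ambiguous, so both are emitted.

Intra-ligand pairs belong to no receptor residue and are excluded
throughout.

## Docking

`dock()` runs iterated Monte-Carlo: random restarts uniform in the search
box, Metropolis steps perturbing translation (σ 0.6 Å), orientation
(rotation-vector σ 0.25 rad) and one random torsion (σ 0.5 rad), then
Nelder–Mead refinement of each run's best state. The acceptance temperature
anneals geometrically from 2.5 to 0.5 kcal/mol across a run — hot enough
early to cross the repulsion walls between competing placements, cold late
so runs settle before refinement. Defaults are 16 + 4·n_rot restarts of 350
steps; both are exposed. Box containment is enforced by rejecting moves that
leave the box and by a quadratic penalty during in-box refinement; returned
poses are guaranteed inside. Pose lists are sorted by score, deduplicated at
a 2.0 Å heavy-atom RMSD diversity threshold (the conventional redocking
success radius), and capped at 999 poses. All randomness comes from one
seeded generator whose state is restored afterwards, so a fixed seed gives a
bit-identical pose list.

`local_refine()` (exported separately) is plain unconstrained descent and
returns the input pose if no improvement is found, so its score never
increases.

## Site prediction

`detect_cavities()` follows the classic grid protein–solvent–protein scan:
a cubic grid (default spacing 1.0 Å) is marked protein within the
probe-inflated (1.4 Å) van der Waals envelope; each solvent point counts
how many of seven scan directions (three axes, four body diagonals) are
blocked by protein on *both* sides; points buried in ≥ 5 of 7 directions
are pocket points; 6-connected components below 8 Å³ are discarded.
Pockets are ranked by `ligandability = volume × mean buriedness fraction`.
That score is a declared proxy: the ligandability/druggability formulas of
the commercial and web tools this stage stands in for are unpublished, and
no reproduction of their outputs is claimed. The minimum volume (8 Å³, a
water-sized void) and burial threshold were fixed when the detector was
written, sized to what the scan can resolve at 1 Å spacing.

The elastic network is a standard anisotropic network model: one node per
residue (Cα when present, else the residue centroid), uniform springs
within 15 Å, Hessian pseudo-inverted over all modes except the six
rigid-body zero modes (identified by a relative eigenvalue threshold of
1e-8; a connected structure with fewer than six near-zero modes, or extra
zero-energy mechanisms, is reported as singular). Cross-correlations are
the traces of the 3×3 covariance blocks, normalized to unit diagonal. A
candidate pocket's raw correlation is the mean correlation between its
lining residues and the orthosteric pocket's lining residues; z-scores are
taken across the candidate set with the population standard deviation
(mean 0, sd 1 by construction), and the filter keeps z strictly greater
than 0.5 — the strict inequality is deliberate.

`consensus_sites()` pools pockets tagged with (method, complex), sorts them
canonically by centroid so the greedy merge is independent of input order,
merges at ≤ 4.0 Å centroid distance, and retains a merged site only if it
appears in *every* complex and in at least two distinct methods. The 4.0 Å
default is about one pocket radius: neighbouring-but-distinct sites in real
receptors sit ~12 Å apart with boundaries a few Å apart, and stay separate
at that threshold.

## Modulator classification

MM-PBSA-WSAS component tables are read as TSV with `value ± uncertainty`
cells (either ASCII or typographic minus). Totals are reconstructed as
$E_\mathrm{VDW} + E_\mathrm{eel} + E_\mathrm{int} + G_\mathrm{pol} +
G_\mathrm{nonpol} - T S$, with $E_\mathrm{int}$ required only for complex
tables (single-trajectory binding tables cancel it). The packaged tables
reconstruct every printed total within ±0.02 kcal/mol — two-decimal
rounding of the components explains the residual.

The verdict rule: the effective agonist binding energy is the
modulator-as-receptor value when the modulator pocket is adjacent to the
orthosteric site (the `H*` convention), else the plain with-modulator
value; PAM if effective < control − tolerance, NAM if > control +
tolerance, else silent. The tolerance defaults to 0 — a 1.3 kcal/mol
deficit is already treated as a NAM call in practice, so no dead zone is
assumed — and is exposed for sensitivity analysis. Adjacency is a declared
boolean, not computed: no distance criterion for "adjacent" is established,
and guessing one would hide an assumption inside a verdict. Uncertainties
propagate in quadrature but never affect verdicts.

## The synthetic fixtures

The generator (`make_receptor()`, `make_ligand()`) produces deterministic,
seed-reproducible test systems:

* `sphere_pocket` — a solid lattice blob (~9.5 Å radius, 1.8 Å spacing,
  0.12 Å jitter) with a ligand-shaped void carved as the union of 4.0 Å
  spheres around the planted ligand atoms, a narrow (1.6 Å) perforation to
  the surface as an access channel, and two hydrogen-bond anchors — a
  serine oxygen on the ligand's donor-N ray and a zinc site on its
  acceptor-O ray, each at the net-optimal 3.15 Å. The rigid toy ligand has
  four arms of distinct lengths and angles, so no nontrivial rotation maps
  the arm set onto itself and the void fits it in exactly one orientation.
  The ligand's amine ships protonated (pKa 9.1 > pH 7.4), making the
  nitrogen a pure donor so each anchor matches exactly one arm. The
  recorded planted pose is the deepest refined optimum over a deterministic
  3×3×3 multistart — ground truth is the pose the energy landscape actually
  holds, not a drawing.
* `two_pockets` — two such blobs 32 Å apart; the gap is open in most scan
  directions and never reads as a third cavity.
* `solid_ball` — no interior void (negative control).
* `hinge_dimer` — two ~4 Å lattice lobes 28 Å apart joined by an off-axis
  jittered neck. Lobe separation exceeds the spring cutoff so coupling runs
  through the neck only; the neck is jittered off the hinge axis because a
  perfectly collinear linker leaves lobe counter-rotation as a seventh
  zero-energy mode.

What the fixtures emulate: planted geometry with known ground truth, both
polar and apolar typing branches, torsion trees, buried-pocket topology,
two-lobe collective dynamics. What they do not: real protein chemistry
(side-chain diversity, backbone connectivity, charge distributions),
crystallographic noise, receptor flexibility, or any GPCR fold. Passing the
redocking and detection suites therefore demonstrates that the algorithms
are internally correct and self-consistent on controlled landscapes — not
that they reproduce experimental poses on real receptors.

## Problem sizes and numerical choices

The test and acceptance runs use ~500-atom receptors, 6–8-atom ligands, ten
seeded docking runs for the recovery rate, 500×50-atom random complexes for
the brute-force scoring oracle, and ~100-node elastic networks — sizes at
which every stage has an exhaustible oracle (full pair enumeration, dense
eigendecomposition, hand-enumerable consensus sets). Other numerics:
tie-breaks in residue and site rankings follow input order; the z-score
denominator is the population standard deviation and a zero spread yields
z = 0 for all candidates rather than NaN; empty receptors or distant
ligands give zero-energy profiles, not errors; Nelder–Mead refinement uses
relative tolerance 1e-7–1e-8 with iteration budgets of 250–500.

## Known limitations

* The scoring engine is deliberately charge-free; systems dominated by
  electrostatics or desolvation are outside its domain.
* Cavity ligandability is a proxy score; absolute values are not comparable
  with external cavity-detection tools, only the ranking within a run.
* The Monte-Carlo search is tuned for pocket-scale boxes (~12 Å); very
  large boxes need more restarts than the default.
* `E_int` handling assumes the single-trajectory convention for binding
  tables; mixed conventions in one table are not detected automatically.
* The protonation rule acts on one designated ionizable nitrogen. The
  choice of which nitrogen is "the" basic site is the caller's; the
  amide-literal reading of the rule is selectable but chemically unusual,
  which is why the amine interpretation is the default.
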