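---
title: "Interface pharmacophores, contact occupancy, and MM-GBSA: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface pharmacophores, contact occupancy, and MM-GBSA: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscreen)
```

## The problem

Blocking a protein–protein interaction (PPI) with a small molecule is hard:
PPI interfaces are broad and shallow, and affinity concentrates in a few
hot-spot residues. The IL-6/IL-6Rα site I interface is the canonical case
this package is organised around: the cytokine contributes Phe74, Phe78,
Leu178, Arg179 and Arg182; the receptor contributes Phe229, Tyr230, Glu277,
Glu278 and Phe279. Each partner pair realises one of three interaction
classes — aromatic ring stacking, hydrophobic packing, or a salt bridge — so
a ligand that mimics one side of the interface can compete with the other
side for binding.

`ppiscreen` implements the full desk-scale workflow around that idea:

1. derive a 3D pharmacophore model from one side's hot-spot residues;
2. perceive chemical features on ligand conformers and match them
   geometrically under the model's constraint logic;
3. filter by the Lipinski Rule of Five;
4. measure stability (RMSD/RMSF) and geometric contact occupancy on
   protein–ligand trajectories;
5. decompose binding free energy with single-trajectory MM-GBSA;
6. run the candidate-selection cascade over docking scores, contacts, and
   energies.

Docking itself is consumed, not computed: pose generation and scoring belong
to external engines, and the pipeline ingests a plain score table.

## Interface pharmacophore models

A model is a set of typed feature spheres (`Aro`, `Hyd`, `Ani`, `Cat`,
`Don`, `Acc`), one per hot-spot residue, labelled `F1…Fn` in input order.
Because crystal-structure papers rarely print feature coordinates, the
centers are derived deterministically from side-chain chemistry:

* `Aro` — centroid of the six-membered ring heavy atoms (PHE/TYR; for TRP
  the six-ring);
* `Ani` — midpoint of the two carboxylate oxygens (GLU OE1/OE2,
  ASP OD1/OD2);
* `Cat` — the guanidinium carbon CZ for ARG, NZ for LYS;
* `Hyd` — centroid of side-chain carbons beyond Cβ.

Whether charged features sit on atoms or group centroids is a convention of
this package; both choices keep every center within 5 Å of its source
residue, which the tests assert.

The constraint logic is an *essential set* plus *at-least-k choice groups*.
Both interface models share one rule — F5 essential, at least one of F1/F2,
at least one of F3/F4 — so a single mechanism (`constraint_spec()`) covers
both, and `constraints_satisfied()` is monotone in the matched set by
construction. The default tolerance radius is 1.0 Å per feature,
configurable per feature and scalable at match time; 1.0 Å is the common
default of public pharmacophore screens, and the matcher's behaviour under
wider spheres can be explored with `radius_scale`.

Models serialise to a small JSON document (`write_model()` /
`read_model()`) so they can be versioned as plain-text fixtures.

## Ligand feature perception and matching

Perception is rule-based and deterministic from the bonded topology:

* **Aromatic rings** come from a fundamental-cycle ring basis (5–7-membered)
  whose members all participate in a multiple bond. This is a Hückel-free
  approximation: it types phenyl and pyridine correctly and leaves
  saturated rings (piperazine) alone, which is the chemistry the hit
  scaffolds here actually contain.
* **Cations**: quaternary or formally charged nitrogens, guanidinium
  carbons, and aliphatic (non-amide, non-aromatic) amines.
* **Anions**: carboxylate-like C with two terminal oxygens (anchor at the
  O–O midpoint), sulfonate/phosphate, and nitro, whose two oxygens give one
  anchor at their midpoint — the convention that makes a nitro group a
  single ionic partner for an arginine side chain.
* **Hydrophobic**: centroid of each maximal connected set of ≥ 3 carbons
  with no bonded heteroatom. Aromatic-ring carbons are excluded: the ring
  is already represented by its `Aro` feature, and keeping it out of `Hyd`
  means a benzene yields exactly one feature.
* **Donors/acceptors**: N/O with explicit or implicit hydrogens donate;
  all N/O except quaternary N accept. Implicit hydrogens come from
  standard valences adjusted by formal charge.

Matching enumerates every injective, type-compatible assignment of ligand
features to a model-label subset that passes the constraints and has at
least three points — one- and two-point rigid superpositions are
geometrically underdetermined, and both interface models require three
matched points anyway. Each assignment is scored by Kabsch superposition of
ligand positions onto model centers and accepted only if every assigned
feature lands inside its tolerance sphere. Accepted matches are sorted by
fit RMSD with a lexicographic tie-break for reproducibility. The tests hold
this enumeration equal to an independent exhaustive `expand.grid` oracle on
randomized models with up to 6 features.

The Lipinski filter applies the classical rule — MW < 500 Da, logP < 5,
HBA (all N+O) ≤ 10, HBD (N–H and O–H) ≤ 5 — with strict `<` on MW/logP and
`≤` on the counts, exactly as the rule is stated. A precomputed `logp`
property is preferred; otherwise a coarse element-level Wildman–Crippen-style
atom-contribution estimate (`crippen_logp()`) stands in. That estimator is
a ranking aid, not a reproduction of the full 68-type scheme, and tests that
depend on logP values supply them explicitly.

## Trajectory analysis

RMSD/RMSF use Kabsch superposition built on the SVD, with the reflection
branch excluded and collinear point sets rejected. `rmsd_series()`
separates the *fit* selection from the *measure* selection, which covers
both conventions used in MD tables: backbone-on-backbone RMSD, and ligand
heavy-atom RMSD after fitting on the protein. `rmsf()` uses the standard
two-pass average-structure reference (fit to frame 1, average, refit to the
average) so the reported fluctuation is about the time-average structure.

Contact detection is geometric:

* **Hydrogen bond**: donor–acceptor distance < 3.5 Å and D–H⋯A angle
  > 120°, donors needing an explicit bonded hydrogen (found within
  1.25 Å). Every satisfying (D, H, A) triple is one event; this
  multiplicity counting is what lets a single donor group exceed 100%
  occupancy, and it is the only convention consistent with published
  per-pair occupancies above 100%.
* **Salt bridge**: any heavy atom of a protein charged group (ARG/LYS/HIS
  positive, GLU/ASP negative, by template) within 4.0 Å of an oppositely
  charged ligand group (clusters of formally charged atoms, single-linkage
  at 2.5 Å).
* **Hydrophobic**: protein side-chain carbon within 4.5 Å of a ligand
  hydrophobic carbon cluster.
* **Aromatic**: ring-centroid distance ≤ 5.5 Å. Ring-plane angles are not
  evaluated, so π-π and π-alkyl are reported as one class; ligand rings
  must be supplied (or derived from residue templates when the "ligand" is
  itself a protein chain) because a merged topology carries no bond orders.

The 4.0/4.5/5.5 Å cutoffs are common structural-biology conventions and are
config-overridable; the contact classes themselves, not these numbers, are
the scientific content.

Occupancy is `100/N · Σ_frames (number of simultaneous bonds)`. Pair-level
rows key on (residue, class, role, protein moiety, ligand group); a
residue-level row is exactly the sum of its pair rows, which is why
per-residue values above 100% are meaningful rather than an error.
Contacts with occupancy strictly above 75% are flagged strong.

## MM-GBSA

The decomposition follows the single-trajectory end-state scheme: for each
frame the complex, receptor, and ligand geometries are all taken from the
complex frame, so intramolecular bonded terms cancel exactly and the
bonded Δ-term is identically zero. Per frame:

* ΔE_elec and ΔE_vdW are direct receptor–ligand cross sums
  (Coulomb with 332.0636 kcal·Å/(mol·e²), ε_in = 1; 12-6 LJ with
  arithmetic Rmin and geometric ε combination; no cutoffs — systems are
  desk-scale);
* ΔG_GB is generalized Born with OBC-rescaled effective radii (parameter
  set I: α = 0.8, β = 0, γ = 2.909125), ε_out = 78.5, the canonical
  `f_GB = sqrt(r² + R_iR_j e^{−r²/4R_iR_j})`, self-terms included;
* ΔG_SA is γ·SASA + β with γ = 0.0072 kcal/mol/Å², β = 0, over a
  Shrake–Rupley surface sampled with a deterministic golden-spiral point
  set (default 960 points per atom; doubling the count moves totals by
  < 0.5%).

The dielectric-boundary offset subtracted from intrinsic radii before
descreening defaults to 0 so that a single ion reproduces the Born equation
with its stated radius exactly; the conventional 0.09 Å offset is available
through `forcefield_params()`. Entropy is deliberately omitted: when
ligands are compared against the same protein the conformational-entropy
change contributes little to the ranking, which is the regime this
workflow targets. Means are reported with population SDs over frames,
matching how MD energy tables print their ± columns.

## The synthetic-data generator

The generator replaces every external input: crystal structures, compound
libraries, and MD engines.

* `make_toy_interface()` builds a two-chain interface whose residues carry
  real side-chain atom names over a minimal N/CA/C/O backbone, so feature
  derivation and the detectors run unmodified. The receptor chain carries
  Glu-Glu-Phe-Tyr-Phe side chains and the partner chain Arg-Arg-Phe-Phe-Leu,
  placed so every partner pair sits well inside its detector cutoff
  (aromatic centroids ≈ 4.5 Å, salt-bridge heavy atoms ≈ 3.3 Å,
  hydrophobic carbons ≈ 3.1 Å); base positions jitter ±0.15 Å with the
  seed. Geometry is idealized, not force-field-relaxed — the generator
  makes no claim of physical realism, only of exactly controlled truth for
  the analyses.
* `make_matching_ligand()` realises a constraint-satisfying label subset
  as chemical fragments (benzene, diprotonated piperazine, carboxylate,
  a carbon triangle, hydroxyl/ether) placed exactly at the model centers
  and linked into one scaffold; the decoy variant omits one fragment,
  typically the essential one. Linker bond lengths are not physical; the
  matcher never sees bond lengths, only perceived feature geometry.
* `make_trajectory()` realises a `contact_schedule()`: scheduled contacts
  are posed inside their criteria (bidentate for multiplicity 2) or far
  outside them (≥ 9 Å), with 0.1 Å Gaussian jitter everywhere except the
  scheduled atoms. Margins of several Å versus 0.1 Å jitter mean a
  scheduled state cannot flip, so deterministic schedules are recovered
  *exactly* — the generator's bookkeeping and the detector's measurement
  must agree to the last digit, which is the core acceptance loop.
  Deterministic mode puts the contact in the leading `round(p·N)` frames;
  Bernoulli mode draws frames independently, and recovery is asserted
  within 99% binomial bounds at N = 2,000.
* `assign_toy_forcefield()` draws charges summing exactly to each
  molecule's formal charge and LJ/Born parameters from plausible ranges
  (ε 0.05–0.2 kcal/mol, Rmin/2 1.3–1.9 Å, Born radii 1.0–2.5 Å).

All generators are bit-reproducible from their seed; 20220406 is the
documented anchor seed of the fixture suite.

What passing on synthetic data does *not* show: that feature perception
covers exotic chemotypes, that the contact cutoffs are optimal for real
interfaces, or that toy MM-GBSA magnitudes resemble force-field values.
The synthetic loop validates the *machinery* — bookkeeping, geometry,
constraint logic, closed-form limits — not chemical accuracy.

## Published tables as inputs

Three small published tables for the IL-6/IL-6Rα campaign ship under
`inst/extdata/` and are treated as *inputs*: a docking-score table for 12
candidate ligands (kJ/mol, with contacted residues), a per-pair
hydrogen-bond occupancy table from 50-ns trajectories, and a binding-energy
summary (kcal/mol). They let the selection cascade and the occupancy
aggregation run on real numbers: summing the per-pair rows reproduces the
quoted per-residue occupancies (Glu278 492.14%, Arg179 226.51%), and the
final ranking recovers the campaign's two lead compounds. One energy table
cell (a ΔG_sol printed negative while its GB + SA parts sum positive) is
internally inconsistent in the source; the package enforces the
decomposition identity instead of reproducing that cell, and the affected
column is not shipped.

## Numerical choices and degenerate inputs

* Kabsch rejects < 3 points and collinear configurations; the reflection
  correction keeps det(R) = +1 within 1e-9.
* AltLoc resolution keeps the highest occupancy, ties to the first record
  seen — structures are deterministic single conformations.
* Energies are carried in kcal/mol; docking scores stay in kJ/mol with an
  explicit 4.184 conversion (`kj_to_kcal()`), because the two unit systems
  coexist in this field's tables.
* Frame times default to 0.01 ns per frame (the usual save interval), with
  the first saved frame at one interval.
* Occupancies keep full precision internally; the 2-decimal presentation
  matches how such tables are printed.
* Selection boundaries are strict (`< −20`, `< −25` kJ/mol; `> 75%`), so
  values exactly on a boundary drop out — including a −25.00 kJ/mol score,
  which is why the shipped 12-ligand table yields 11 top hits under the
  rule as stated.
* The final ranking (strong key-residue contact count, then ascending
  ΔG_bind) formalises a qualitative multi-criteria argument; it is
  configurable because no explicit combination formula exists to
  reproduce.

## Problem sizes

The shipped analyses and tests run on deliberately small problems: a
104-atom interface, ligands of ~12 atoms, trajectories of 10–200 frames
(2,000 for the Bernoulli recovery checks), and MM-GBSA over ~40-atom
systems at a 5-frame stride with 480-point SASA quadrature. These sizes
exercise every code path while keeping the whole suite interactive; all
components scale to larger inputs with the usual O(n²) GB/SASA cost.

## Known limitations

* No docking: poses and scores are inputs.
* Aromaticity and logP use reduced deterministic schemes, not full
  electronic or 68-type models.
* Aromatic contacts ignore ring-plane geometry.
* The ligand side of an occupancy pair is identified by atom groups, not
  by a main-/side-chain split — how such a split would be defined for a
  ligand is not well specified, so atom indices are recorded instead.
* PB solvation, normal-mode entropy, and per-residue energy decomposition
  are out of scope.
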