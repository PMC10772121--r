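---
title: "Methods: epitope footprinting, footprint overlap and binding kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epitope footprinting, footprint overlap and binding kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifoot)
```

`epifoot` quantifies how an antibody engages a cell-surface receptor: the
size and chain composition of the epitope, its overlap with the receptor's
natural ligand site, conformational change upon binding, the population
variants falling inside the epitope, and the binding constants measured by
biolayer interferometry (BLI). This vignette records the models, the
parameters that matter, and the design decisions taken where the problem
was genuinely open — in enough detail that a reader can reproduce or
deliberately change any of them.

## Solvent-accessible surface area

`compute_sasa()` implements the Shrake–Rupley method. Each atom is covered
with `n_sphere_points` quasi-uniform test points at radius
`r_vdw + r_probe`; its accessible area is the exposed fraction of points
times the full sphere area `4π(r_vdw + r_probe)²`.

Choices that affect every Å² the package reports:

* **Point set.** Points come from the deterministic golden-section spiral,
  not random sampling — there is no RNG anywhere in the SASA path, so areas
  are bit-reproducible. For an isolated atom every point is exposed and the
  analytic sphere area is recovered exactly; on clusters, 960 points
  (default) track a 10,000-point computation within a few percent (asserted
  in the test suite at 3%).
* **Radii.** A single embedded heavy-atom van der Waals set: C 1.70, N 1.55,
  O 1.52, S 1.80, P 1.80, anything else 1.80 Å, overridable per element via
  `sasa_params(radii =)`. Published SASA programs differ in radii and
  sampling, and absolute areas shift by a few percent between programs;
  the table is therefore explicit rather than implicit.
* **Probe.** 1.4 Å (water) by default.
* **Hydrogens.** Dropped at parse time; all geometry in the package is
  heavy-atom based, matching what a mid-resolution crystal structure
  actually contains.
* **Neighbour search.** A uniform spatial grid with cell edge
  `2 × max(r_vdw + probe)`, giving expected linear cost without depending
  on any tree library's semantics.

## Epitope footprints

The footprint of a binder on a target is **one-sided**: per target residue,

```
ΔSASA(res) = SASA(target alone) − SASA(target in complex),
```

both states computed with identical parameters and point sets, so each
per-atom difference is non-negative by construction (occluders can only
remove exposed points). One-sidedness is a deliberate convention: it is the
only convention under which per-chain contributions can partition the total
exactly. The partition attributes each buried target atom's loss to the
binder chain owning the nearest binder atom; the attribution is exhaustive
and exclusive, so heavy-chain + light-chain area equals the total at
machine precision — an internal identity the test suite asserts, and the
natural way to decompose an antibody epitope into heavy/light
contributions. The symmetric (two-sided) interface area can be obtained by
swapping the groups and summing.

Membership in the *epitope set* uses a per-residue threshold (default
1.0 Å²); totals always use raw ΔSASA so they are threshold-independent.
Waters are always excluded; other heteroatoms (glycans, ions) are excluded
by default so the footprint describes protein–protein burial, and can be
kept with `include_hetero = TRUE`.

## Contact classification

`classify_contacts()` assigns four geometrically defined classes, all
heavy-atom based because no hydrogens are available:

| kind | criterion | default |
|---|---|---|
| hbond | donor-capable to acceptor-capable N/O/S distance; antecedent–donor–acceptor angle | ≤ 3.5 Å, ≥ 90° |
| hydrophobic | apolar-carbon pair distance | ≤ 4.5 Å |
| pi_stack | aromatic ring centroid distance; inter-plane angle | ≤ 5.5 Å, ≤ 30° |
| cation_pi | Lys NZ / Arg CZ to ring centroid | ≤ 6.0 Å |

Donor/acceptor capability comes from an embedded per-residue table
(backbone N donates except proline, backbone O accepts; Asp/Glu carboxylates
accept only, Ser/Thr/Tyr hydroxyls do both, and so on). The donor angle is
a heavy-atom proxy: for every covalently bonded heavy neighbour X of the
donor D (same residue, < 1.8 Å) the angle X–D···A must be at least the
cutoff, which rejects acceptors approaching through the donor's bonded
side. A carbon is *apolar* when no N/O/S of the same residue lies within
covalent range (1.7 Å) — a data-driven rule that needs no per-residue
enumeration. Rings are His/Phe/Tyr rings and both Trp rings; ring normals
come from the smallest singular vector of the centred ring coordinates.
All cutoffs are configuration (`contact_criteria()`), since published
practice varies and no single set is canonical; the tests therefore assert
recovery of contacts of *known, constructed* geometry rather than exact
counts on real interfaces.

## Superposition and TM-score

`kabsch_superpose()` is the standard SVD solution of the least-squares
rigid-body problem on paired CA atoms, with the reflection corrected by
negating the smallest singular axis when the determinant is negative, so
the result is always a proper rotation. Nearly collinear point sets are
rejected (second singular value test) rather than silently returning an
ill-conditioned rotation.

The TM-score is computed on a **fixed pairing** — no iterative fragment
search — because the intended use is scoring an established correspondence
(same domain, bound vs free), not finding an alignment:

```
TM = (1/L) Σ 1/(1 + (dᵢ/d₀)²),  d₀ = 1.24 (L − 15)^⅓ − 1.8
```

`L` (`l_target`) is the reference domain length and must be ≥ 16 (below
that `d₀` leaves its domain of validity; the function refuses). Because the
normalisation length is a choice, scores from different programs are only
comparable at matched `L` — the function exposes it rather than guessing.
Residue pairing is either by author numbering or through a global pairwise
alignment (Needleman–Wunsch via Biostrings, BLOSUM62, gap open 10 /
extend 0.5 — a deterministic, near-identity setting for homologous
domains). For domain-level comparisons of two-domain KIR receptors, the
membrane-distal domain 1 is taken as residues 1–101 of the ectodomain by
default; the boundary is an argument (`select_structure(residues =)`), not
a constant, because deposited numbering conventions differ.

## Footprint overlap across homologous receptors

Two footprints measured on different (homologous) receptors are compared at
**residue level**: each footprint is transferred into a common reference
numbering through the pairwise alignment (positions facing a gap are
dropped and reported, their area excluded), and

```
overlap = Σ_pos min(areaA(pos), areaB(pos)).
```

This convention was chosen over an atom-level post-superposition
intersection because atom correspondence between non-identical receptors is
undefined; the residue-level min-sum is symmetric, monotone in either
footprint, and bounded by the smaller total — properties the test suite
asserts. An atom-level alternative would be sensitive to the superposition
used and is not implemented. Occlusion of an epitope by another structural
element (e.g. an additional receptor domain) is reported as
`overlap(epitope, occluder) / area(epitope)` ∈ [0, 1].

## Variants

Variant records carry each receptor's **own mature-protein numbering** (the
numbering used in residue labels like D47 or H50); signal-peptide offsets
are the caller's responsibility. Mapping to the reference receptor goes
through MSA columns, and the variant's stated reference residue is checked
against the receptor's aligned sequence — a mismatch is an error, because a
silent off-by-signal-peptide shift is the classic failure mode of variant
mapping. Every variant produces exactly one report row; positions the
reference cannot express (gap columns) stay in the report as unmapped.

## BLI kinetics

The 1:1 Langmuir model: during association at analyte concentration C,

```
R(t) = Req (1 − e^{−kobs t}),  kobs = kon·C + koff,  Req = Rmax·C/(C + KD)
```

and exponential dissociation from the association end value; KD = koff/kon.

* **Global fit.** `fit_langmuir_global()` shares kon, koff, Rmax across all
  traces and fits association and dissociation phases **jointly**, with
  each trace's dissociation amplitude tied to its model value at the end of
  association (curve continuity). Joint fitting was chosen over
  association-only because the off-rate is mostly determined by the
  dissociation phase, and tying the amplitude suppresses the kon/Rmax
  trade-off. Optimisation is Levenberg–Marquardt in log-parameter space
  from a 5×5 log-spaced multistart grid (kon ∈ [10³, 10⁷] M⁻¹s⁻¹,
  koff ∈ [10⁻⁵, 10⁻¹] s⁻¹; best RSS wins, ties to the smallest kon),
  because Langmuir fits are multimodal in poor data. The default procedure
  injects no randomness and is deterministic. Fewer than two distinct
  concentrations is an identifiability error; all-flat traces are a
  no-signal error.
* **Steady state.** For weak/fast-off binders where kinetic fitting fails,
  `fit_steady_state()` estimates each trace's equilibrium response as the
  mean of the final 10% of its association window (a robust, documented
  estimator; the true plateau is reached when kobs·t ≫ 1) and fits
  `Req(C) = Rmax·C/(C + KD)`. When the fitted KD exceeds the top analyte
  concentration the series cannot saturate and the fit is **flagged**
  non-saturating rather than rejected: the KD then rests on extrapolation
  of the curve's initial slope and carries wide confidence. kon/koff are
  undefined for this model and reported as `NA`.
* **Baseline.** Traces are assumed reference-subtracted; no drift model is
  fitted.

## Synthetic data: what it emulates, and what it does not

The generators provide ground-truthed inputs for every stage:

* `make_toy_complex()` builds two ideal α-helices (φ/ψ −57°/−47°, NeRF
  internal-coordinate construction) and realises each *planted* contact by
  explicit geometric placement of side-chain atoms, to within 0.1 Å of the
  requested distance. The inter-helix separation is chosen so only planted
  atoms can reach across the interface, and planted residues must be ≥ 5
  apart, so the constructed contact list is exactly the expected
  classification output. Side-chain placement favours exact interaction
  geometry over rotamer realism.
* `make_kir_like_msa()` emulates the *shape* of a receptor-family
  alignment: a gapless reference, homologues differing at a controlled
  number of columns, one homologue with a 3-column deletion (so gap mapping
  is exercised), a variant table in per-receptor numbering, and the
  expected intersection report. Default epitope positions
  (41, 45–48, 50, 65, 72, 87, 88) follow the residue numbering style of
  KIR2D domain-1 epitopes; sequences themselves are random — the generator
  makes no claim of biological sequence realism.
* `make_bli_dataset()` writes two-fold dilution series (defaults: 6 wells
  from 250 nM, 300 s association, 600 s dissociation — a standard
  antibody–receptor panel design) with seed-controlled Gaussian noise.

Passing tests on these fixtures demonstrates that the algorithms implement
their definitions correctly and recover planted truth. They do **not**
demonstrate agreement with any particular published measurement on real
complexes: absolute SASA depends on radii/sampling conventions, contact
counts on cutoff choices, and mapped overlaps on alignment quality. The
opt-in integration tests (deposited structures placed under
`tests/testthat/integration/`) cover that second question when coordinates
are available.

## Numerical choices and degenerate inputs

* Altloc duplicates resolve to the highest occupancy, ties toward `'A'` —
  a deterministic single-conformer rule.
* Multi-model files use model 1 only.
* Zero buried area is a warning plus an empty footprint, not an error;
  empty chain selections and overlapping chain groups are errors.
* ΔSASA is clamped at zero per atom (a no-op in exact arithmetic, a guard
  in floating point).
* Superposition requires ≥ 3 non-collinear pairs; TM-score requires
  `l_target ≥ 16`.
* All generator randomness runs in a private RNG stream restored on exit,
  so library calls never perturb a caller's `set.seed()` state.

## Problem sizes

The shipped test-and-acceptance workload uses 6–24-residue toy complexes
(≈ 100–250 atoms), 960-point SASA (10,000 points in the convergence check),
110-column/7-sequence MSAs with 12 variants, and 6-trace BLI series sampled
at 1–2 s over 300 s + 600 s phases with a 25-start global fit — sizes at
which every stage's behaviour is fully exercised while the complete suite
runs in well under a minute on a single core. All functions accept
full-size inputs (thousands of atoms) with the same code paths.

## Known limitations

* No solvent-excluded (Connolly) surface, interface energetics, ΔΔG
  prediction or shape complementarity.
* TM-score has no alignment search; it scores the pairing you give it.
* The hbond donor angle is a heavy-atom proxy; true hydrogen positions are
  never inferred.
* No mass-transport-limited or bivalent-analyte kinetic models; avidity
  effects (bivalent IgG on a surface) are outside the 1:1 model by
  construction.
* Footprint overlap is residue-granular; sub-residue (atom-level) overlap
  between homologs is intentionally not defined.
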