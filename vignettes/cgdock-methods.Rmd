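---
title: "cgdock: model, sampling protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cgdock: model, sampling protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgdock)
```

This vignette is the package's own account of its science: the reduced
protein model, the energy function, the replica-exchange annealing
protocol, the contact-map clustering stage, the quality metrics, and —
importantly — which numbers are established modelling conventions, which
are calibrated, and which are simply this package's choices where the
design was genuinely open.

## 1. The reduced representation

A protein chain is a sequence of Cα beads on a fine cubic lattice.

* **Lattice spacing**: 0.61 Å. **Allowed bonds**: all integer displacement
  vectors whose physical length lies in **[3.5, 4.1] Å** — 558 vectors at
  the default spacing. The band brackets the canonical 3.8 Å Cα–Cα virtual
  bond and gives the trace enough orientational freedom that projecting a
  real (off-lattice) trace distorts it by well under the guaranteed 0.6 Å
  RMSD bound (ideal helices project at ≈ 0.3 Å). Neither the spacing nor
  the band is dictated by theory; they are implementation choices tuned for
  "slight bond-length fluctuation, many bond orientations, local moves",
  and both are exposed through `lattice_spec()`.
* **Pseudo-atoms.** Residue `i`'s local frame comes from Cα `i−1, i, i+1`:
  with unit bond vectors $v_1, v_2$, the Cβ direction is
  $\cos(0.66)\,\widehat{(v_1 - v_2)} + \sin(0.66)\,\widehat{(v_1 \times
  v_2)}$, i.e. a fixed tilt of the bisector out of the backbone plane, so
  placement is deterministic and equivariant under rigid motions. Cβ sits
  1.53 Å out; the united side-chain centre lies along the same direction at
  a per-residue distance (1.5–4.1 Å, `SC_DISTANCE`) derived from idealized
  residue geometry — a deliberate simplification of database-derived
  placement statistics. Glycine's side-chain centre is its Cα; alanine's is
  its Cβ (these two identities are contractual and tested, because the
  contact criterion below depends on them). Peptide-bond centres are bond
  midpoints. Terminal residues copy the neighbouring frame; a locally
  straight backbone has no canonical frame, and there a fixed axis-based
  fallback keeps placement deterministic though not equivariant (an
  explicitly degenerate, measure-zero case).

## 2. Energy function

All terms are in kT units and pairwise/locally additive. The published
statistical-potential tables this class of model normally uses are not
available, so the package ships a simplified potential of the same
functional classes, with these defaults:

| term | form | default |
|---|---|---|
| side-chain contacts | matrix value for pairs with $d \in [2.8, 6]$ Å | $e(a,b) = -(0.2 + h_a h_b)$, $h$ = Kyte–Doolittle hydropathy rescaled to [0,1] |
| hard core | linear, $5\,(r_0 - d)$ | $r_0$ = 2.8 Å (side chain), 3.8 Å (Cα) |
| hydrogen bond | −1 per eligible peptide-bond-centre pair | distance window [4.2, 5.4] Å, bond alignment $|\cos| \ge 0.48$, ≥ 3 bonds apart in sequence |
| local bias | +0.6 per backbone 4-mer outside preferred windows | dihedral in [30°, 75°] (helical) or \|φ\| ≥ 140° (extended); pseudo-angle in [75°, 155°] |

The windows were set from ideal geometry: an ideal α-helix trace scores
zero local bias and gains one hydrogen bond per (i, i+2)/(i, i+3)
peptide-bond pair, while an extended strand scores zero hydrogen bonds —
the qualitative ordering the suite asserts. Hydrophobic–hydrophobic
contacts (Ile–Ile ≈ −1.2) dominate polar ones (≈ −0.2), so toy complexes
with hydrophobic interface patches have a genuine funnel.

Two numerical points worth recording:

* **Thresholds vs the lattice.** Energy terms are step functions of
  geometry, and on a lattice some pair geometries hit rational values
  exactly — e.g. bond vectors $(5,3,2)$ and $(3,-2,5)$ have
  $\cos = 19/38 = 0.5$ exactly. The incremental (per-move) and
  from-scratch energy paths therefore share bit-identical per-pair
  arithmetic (coordinate-difference distances, fixed summation order), and
  the hydrogen-bond alignment threshold is 0.48, a value not attainable as
  an exact rational cosine on the allowed-vector set. Before these two
  measures, a single threshold flip could silently desynchronize the
  energy cache by a full well depth.
* **Incremental evaluation.** A move recomputes exactly the terms whose
  footprint it touches, before and after the coordinate write; the cached
  decomposition is audited against a full recomputation at every snapshot
  and the run aborts beyond 1e−4 kT divergence. Observed drift after
  thousands of accepted moves is ~1e−13 kT.

## 3. Restraints: the two-tier flat-bottom scheme

From the *input* coordinates, every residue pair with sequence separation
≥ 5 and Cα distance in [5, 15] Å is restrained to its observed distance
with a ±1 Å flat bottom and a linear penalty beyond. Linearity (rather
than a quadratic) is this package's choice where the functional form was
open: it is robust to the large excursions the flexible ligand must be
allowed to make. The receptor set keeps weight scale 1.0; the ligand set
is scaled by **0.1** — the tenfold weakening is what separates "near-rigid
receptor" from "mobile, refoldable ligand".

The absolute weight is the one deliberately *calibrated* constant: with
the default ladder's cold end at T = 1.0, a weight sweep on a restrained
60-residue helix (sampled to convergence of the estimate — short runs
systematically underestimate the fluctuation) gave mean backbone RMSF of
about 1.15 / 1.09 / 0.97 Å at w = 6 / 8 / 12 kT·Å⁻¹; **w = 12** is the
default, landing the restrained receptor in the intended ≈ 1 Å
fluctuation regime. The curve saturates because much of the residual
fluctuation lives *inside* the ±1 Å flat bottom, which no weight can
suppress. `scripts/acceptance.R` recomputes exactly this quantity. Whether the ligand's 2–12 Å fluctuation range
emerges from the 0.1 scale alone is treated as emergent and checked only
qualitatively (the ligand's centre wanders far more than the receptor's in
the protocol tests).

## 4. Sampling protocol

* **Ladder.** `build_temperature_ladder(t_min, t_max, n, r)` spaces `n`
  rungs so increments grow geometrically with ratio `r`; the first
  increment is solved from the geometric sum so the hottest rung lands on
  `t_max` exactly; `r = 1` recovers the classical uniform ladder. Defaults
  `t_min = 1.0, t_max = 3.5, r = 1.1, n = 20`: the cold end freezes a
  restrained toy complex, the hot end lets an unrestrained-scale ligand
  unfold. None of the three numeric values is externally prescribed; they
  are documented model-scale choices.
* **Moves.** Single-bead re-placement (uniform over the lattice positions
  bridging the fixed neighbours), two-bead shift by a small lattice vector,
  chain-end regrowth, and — ligand only — rigid translations (vectors of
  squared norm ≤ 4) and the 23 proper 90° lattice rotations about the
  ligand's middle bead (the only rotations that preserve lattice validity;
  the pivot bead maps to itself, so the proposal set is closed under
  inversion). Every proposal distribution is symmetric by construction,
  so plain Metropolis acceptance is correct; proposals that break a bond
  or the bead excluded volume count as rejections. Intra-chain fragment
  moves beyond two beads are intentionally absent: on toy scales the
  single/shift/end movers relax internal structure adequately.
* **Exchange and annealing.** Adjacent rungs attempt swaps every 5 sweeps
  (alternating pair parity) with the standard criterion
  $\min(1, e^{(\beta_i-\beta_j)(E_i-E_j)})$; only rung assignments move, so
  the conformation multiset is conserved. Annealing multiplies the whole
  ladder by `cooling` (default 0.95) at each of the 20 stages — whole-ladder
  cooling was chosen over per-rung re-assignment as the cleaner reading of
  a replica-flow picture, and the schedule invariant (elementwise
  non-increasing ladder) is asserted.
* **Reproducibility.** One L'Ecuyer-CMRG substream per replica plus one for
  exchanges, all derived from the master seed; trajectories replay
  bit-identically.
* **Snapshots.** With fraction `f` (default 2%) one model per `1/f` sweeps
  is saved, `snapshot_per_replica` (default 500) per replica — the
  saved/generated ratio is exact by construction, and pool size is exactly
  `n_replicas × snapshot_per_replica`.

## 5. Post-processing

Contacts are side-chain-centre pairs ≤ 6 Å across the interface. The
pipeline keeps the 1000 models with the most contacts (ties broken by
lower energy then model id, so runs are reproducible), clusters the kept
maps by complete-link hierarchical clustering under the Jaccard distance
(`stats::hclust` behind the module surface; a naive agglomerative
implementation serves as the test oracle), ranks clusters by **density =
member count / mean pairwise distance**, and returns the top 10
representatives (member minimizing summed distance to co-members).

Conventions this package had to fix where the procedure was open:

* the dendrogram is cut at a configurable **30 clusters** before density
  ranking (density ranking presupposes multiple clusters; the count is a
  flag, and clustering to fewer maps than the cut simply caps it);
* "density" uses the Jaccard *distance* in the denominator, so tighter
  clusters rank higher; two empty maps are at distance 0;
* a singleton has density 0 and ranks last; a multi-member cluster of
  bit-identical maps has density ∞ and ranks first;
* a cluster whose members are all *empty* maps (unbound models that
  survived the filter) has no binding mode to report and gets density 0
  regardless of size — without this rule a short run's unbound snapshots
  would form a large "perfect" cluster and outrank every real contact
  pattern;
* maps are canonically ordered by model id before clustering, making the
  partition independent of input order.

## 6. Metrics

iRMSD superposes the *reference-defined* interface Cαs of both molecules
jointly (the CAPRI-style convention adopted here; the interface membership
criterion is the same 6 Å side-chain-centre rule as fNAT, for internal
consistency). LRMSD superposes receptors only; LoRMSD superposes the
ligand onto itself; all superpositions are proper-rotation Kabsch fits
(reflections excluded). RMSF uses the mean structure after superposition
as the reference position, iterating the fit once; `fit = FALSE` switches
to plain variance about the mean for trajectories already in a common
frame — the "reference position" was otherwise undefined. fNAT counts
reference contacts reproduced by the model. All metrics are invariant
under a common rigid transform of model and reference (property-tested).

## 7. Synthetic data

`make_toy_complex()` builds the study systems: ideal-geometry templates
(helix: 1.5 Å rise, 100°/residue, 2.3 Å radius — 3.83 Å virtual bonds;
hairpin: two lightly zig-zagged antiparallel strands with a two-residue
turn), a deterministic hydrophobic-patch sequence, and a native pose with
the ligand docked against the receptor mid-face (~14 contacts at the
default sizes). "Unbound-like" inputs are generated by deforming the
reference along a few smooth low-frequency modes, rescaled and re-projected
until the superposed Cα RMSD lands near the requested value (white noise,
even smoothed, breaks virtual bonds long before reaching 2 Å
deformations). `make_decoy_ensemble()` produces labelled model sets:
rigid-body pose noise around the native, plus reversed-face decoys with
fNAT exactly 0.

What the toys do *not* emulate: real side-chain packing, sequence-specific
secondary-structure propensities, solvation beyond the implicit contact
term, crystallographic detail of real interfaces. Passing tests therefore
demonstrate that the *machinery* — sampling correctness, restraint
behaviour, clustering, metrics — is right, not that the force field
predicts real complexes; on real inputs the expected behaviour is the
broad sampling typical of lattice coarse-grained models combined with
modest scoring accuracy, and ligands
beyond ~150 residues are warned against as impractical for whole-molecule
local-move sampling.

## 8. Problem sizes used by the tests and acceptance script

Chosen so the full suite runs in minutes on one CPU: oracle and metric
checks use 6–12-item instances; sampler statistics use 10⁴–10⁵ draws; the
protocol-count check runs 20 replicas × 500 snapshots on a 16+8-residue
complex; the fluctuation check samples a 60-residue restrained receptor
at two cold rungs (400 sweeps in the test, 1200 sweeps — the converged
estimate — in the acceptance script, which repeats the measurement with
the caller's seed); the smoke test docks a 30+12 toy
with 4 replicas × 50 snapshots and must recover a planted near-native
decoy family among the top three clusters.

## 9. Known limitations

* The contact matrix is hydropathy-derived, not statistics-derived; its
  absolute scale is meaningful only relative to this package's kT ladder.
* Rigid ligand rotations are restricted to the cubic group; intermediate
  orientations are reached through flexible relaxation, which is slower.
* Energies are step functions; there is no force-based refinement, and no
  all-atom reconstruction — outputs are Cα + pseudo-atom models.
* Single-threaded by design; replicas are deterministic substreams, not
  parallel workers.
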