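---
title: "bendkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bendkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bendkit)
```

`bendkit` measures how far an αβ-tubulin heterodimer is bent, how its α
subunit is internally rearranged, what a bound partner protein buries and
touches, and what a one-site binding equilibrium predicts — with every stage
validated against synthetic structures and isotherms of known ground truth.
This vignette records the scientific conventions and the design decisions
behind each stage.

## Coordinate model and I/O policies

Structures are parsed with `bio3d` (PDB and mmCIF, auto-detected from the
extension) into a flat atom table. Three policies are applied at read time
and everywhere downstream:

* **First model only.** Crystal structures are single-model; for multi-model
  files only the first deposited model is kept.
* **Altloc resolution.** Within each (chain, residue, atom name), the
  conformer of highest occupancy wins; ties break by altloc letter order.
  Any consistent policy would do for Cα-level metrics; this one is
  deterministic and matches common practice.
* **Hydrogens are ignored for geometry.** Crystal structures at 2.6–3.2 Å
  deposit none; "heavy atoms" below always means non-H, non-D.

Waters and other hetero components are retained in the model but flagged,
and excluded from surface areas and contacts by default. Van der Waals radii
come from a fixed bundled table (C 1.70, N 1.55, O 1.52, S 1.80 Å, …,
`extdata/vdw_radii.tsv`) so that surface areas are reproducible run to run;
an element without a tabulated radius is a configuration error rather than a
silent default. A truncated coordinate record is a parse error — no partial
model is ever returned.

## Canonical numbering, roles and the element registry

All metrics are defined on a *canonical* tubulin numbering, carried by two
bundled reference sequences (consensus mammalian brain α- and β-tubulin, 451
and 444 residues, `extdata/*.fasta`). Chains are classified by alignment-free
k-mer similarity (k = 4) against both references; a chain is tubulin when its
best score reaches 0.6 — tubulin paralogs and isotypes score far above this,
unrelated chains far below. Non-tubulin chains of 80–300 residues within 5 Å
of a tubulin chain are binders; anything else is `other`. Author numbering is
mapped onto canonical numbering by global alignment (BLOSUM62, gap open 10,
extend 0.5); unmodeled residues are simply absent from the map.

Named elements (H7, T7 loop, H8, S8, S9, H10, the H1-S2 and H10-S9 loops, …)
and the tripartite domain partition (N-terminal 1–205, intermediate 206–381,
C-terminal 382–440) live in a plain-text registry
(`extdata/sse_registry.tsv`), deliberately user-replaceable: the exact
helix/strand boundaries differ by a residue or two between published
assignments, and every consumer of the registry tolerates that uncertainty.
The element intervals outside the handful fixed by the tubulin literature
are plausible canonical assignments and should be treated as provisional for
quantitative work on real structures.

Because the bend angle compares the two *different* subunits, a fixed α↔β
position table (`extdata/alpha_beta_correspondence.tsv`), generated once
from the global alignment of the two references, defines which positions are
structurally equivalent; only positions aligned in both subunits and modeled
in both chains enter any α-vs-β fit. With the default registry, 121
N-terminal-domain helix/strand positions survive the correspondence.

## Superposition and the bend angle

Rigid fits use the Kabsch algorithm: center both point sets, SVD of the
cross-covariance, sign-correct the smallest singular direction so the
rotation is proper (a reflection is never returned). No per-atom weighting
is applied and occupancies are ignored — the source analyses give no
weighting scheme. The scalar rotation angle is `arccos((tr R − 1)/2)`,
which is invariant under conjugation (i.e. under any change of global
frame); rotation axes are not reported.

Degeneracy is detected on the centered point spread: if its second singular
value is below 1e-10 the points are collinear or coincident and there is no
unique rotation. (A threshold on the *smallest* singular value would also
reject perfectly planar sets, for which the proper-rotation optimum is still
unique, so the second singular value is the right test.)

The **bend angle** of a heterodimer is the rotation angle of the fit of the
α-chain Cα at the N-terminal-domain helix/strand positions onto the β-chain
Cα at the corresponding positions. Loops are excluded — the fit follows the
"secondary structural elements" convention — and at least 50 correspondence
positions must be modeled in both chains for a reportable value, which
guards entries with disordered termini. Whether the published per-entry
angles used SSE-only or whole-domain Cα sets is not recoverable; the ±0.5°
regression tolerance in the acceptance suite is meant to cover both
conventions plus ±2-residue registry boundary uncertainty.

Heterodimers are paired by nearest Cα-centroid among unpaired β chains
within 50 Å (about half the 81 Å dimer repeat, so longitudinal neighbors in
a lattice cannot steal a partner), with α chains processed in file order for
determinism. Surveys report one row per heterodimer plus the per-entry mean,
sorted ascending by mean angle.

The **H7 shift** is the displacement of the H7 Cα centroid after aligning
the two α subunits on their N-terminal-domain SSE Cα. A centroid metric was
chosen over an axis-projected one because the underlying observation is a
translation of the whole helix; the centroid is parameter-free and
rotation-insensitive for a 20-residue helix.

The **pairwise complex RMSD** matrix compares the copies of a complex in one
asymmetric unit over the intersection of resolved Cα: tubulin positions (in
canonical numbering, per role) modeled in *all* copies, plus binder
positions sharing author numbering across copies. An intersection set is the
only reconstructable interpretation of a "~1010 Cα compared" figure and
makes the matrix symmetric by construction.

## Surface areas, contacts and the lattice graft

SASA uses the Shrake–Rupley construction with a 1.4 Å probe: an atom's
accessible area is the exposed fraction of test points on its expanded
sphere (r_vdw + probe), with occlusion tested against every neighbor within
the sum of expanded radii. The test points are a deterministic golden-spiral
set, 960 per atom by default — on a free sphere the quadrature error is
below 0.5%, and halving/quadrupling the point count moves protein-fragment
totals by less than 0.5% (checked as a property test). Buried surface area
is the symmetric difference `SASA(A) + SASA(B) − SASA(A∪B)` under identical
parameters; values within −1 Å² of zero are clamped to 0 as quadrature
noise. Nucleotides and other ligands are excluded by default (a toggle
exists): published buried-area figures rarely state their convention, which
is why the acceptance tolerance on the ~1650/~2470 Å² values is ±10%.

Contacts are residue pairs with minimum heavy-atom distance strictly below
5 Å, annotated — when a residue map is available for the tubulin partner —
with the registry element containing the canonical position, so a binder
footprint reads as "T7 loop, H8, H10-S9 loop, S9" rather than a residue
list.

The lattice graft superposes the complex's α subunit onto a chosen lattice α
subunit (N-terminal-domain SSE Cα fit), carries the binder along, and counts
binder/lattice heavy-atom pairs below 2.2 Å. The cutoff is deliberately
conservative — far below any plausible nonbonded separation, roughly
two-thirds of a C–C vdW contact — because the scientific claim being tested
is qualitative (*the binder cannot be accommodated*), so only positivity of
the count is asserted; a vdW-sum criterion would flag looser contacts and
make the count cutoff-sensitive.

## One-site thermodynamics

The 1:1 equilibrium is solved in closed form; the complex concentration is
evaluated as `2TA / (S + sqrt(S² − 4TA))` with `S = T + A + K_D`, which is
algebraically the physical quadratic root but avoids cancellation when
`S ≫ TA`. Free concentrations are computed as totals minus complex, so mass
conservation is exact by construction (asserted as an identity, not a
tolerance, in the tests).

Simulated ITC heats follow the overflow-cell (displaced volume) convention
of the standard instruments: each injection instantaneously mixes `dV` of
syringe solution into the constant-volume cell and expels an equal volume of
mixed contents, so

```
M_i = M_{i−1}(1 − dV_i/V0)
X_i = X_{i−1}(1 − dV_i/V0) + X_syr · dV_i/V0
q_i = ΔH · V0 · (C_i − C_{i−1}(1 − dV_i/V0))   [converted to μcal]
```

with `C_i` the equilibrium complex concentration at totals `(n·M_i, X_i)`.
The subtraction uses the *pre-re-equilibration* complex (diluted by the
expelled volume): complex leaving the cell during the injection releases no
heat. A naive accumulating-volume model is available behind a flag for
comparison. The default geometry is 19 × 2 μL injections of 160 μM titrant
into 0.24 mL of 15 μM macromolecule at 20 °C — the conditions of the
titrations this package is built to re-analyze; under them the c-value is
~160 for K_D = 95 nM and ~56 for 270 nM, comfortably inside the fittable
window.

Fitting is Levenberg–Marquardt least squares (via `minpack.lm`) over
`(n, log K_D, ΔH)` in μcal space — the log parameterization enforces
positivity, and fitting raw per-injection heats rather than normalized
kcal/mol-of-injectant keeps the noise model additive. Standard errors come
from the Jacobian at the optimum (delta method for K_D). Start values
default to `n = 1`, `K_D = [cell]/10` and a ΔH estimated from the total
integrated heat; the noise-free round trip recovers generating parameters to
better than 1e-6 relative error across K_D from 50 nM to 1 μM. A c-value
outside [1, 1000] attaches an ill-conditioning note; an all-zero series
(ΔH = 0, K_D unidentifiable) or fewer than 8 injections is an error. A
constant heat-of-dilution offset is not co-fitted by default — the synthetic
series have none — and stoichiometry `n` is always free, since real
titrations report n ≈ 0.8–1. Derived quantities use
`ΔG = RT ln K_D` (R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹) and `TΔS = ΔH − ΔG`;
note that a K_D of 270 nM with ΔH = −8 gives ΔG = −8.81 kcal/mol, which
printed tables may round to −8.4 depending on their K_D rounding, so
cross-checks against published tables use a 0.5 kcal/mol band.

## What the synthetic generators do and do not emulate

The bent-dimer generator places the full bundled α sequence on a smooth,
bounded, non-degenerate space curve and builds the β chain by rotating a
copy of the curve (evaluated at the corresponding α position for each β
residue) by a chosen angle — so the measured bend angle has an exact known
truth, and classification, alignment, correspondence and pairing are all
exercised on realistic-length chains rather than mocked. The toy lattice
stacks straight dimers at the ~81 Å tubulin repeat. Sphere systems carry
explicit radii for analytic SASA oracles; isotherms carry their generating
parameters alongside the data.

What these fixtures deliberately do **not** emulate: real backbone geometry
and side-chain packing (chains are Cα-only), crystallographic disorder,
isotype mixtures, B-factors, or inter-subunit interfaces with realistic
chemistry. Passing the synthetic suite therefore demonstrates that the
*algorithms* are correct (angles, areas and equilibria are recovered from
known truth), not that the registry boundaries or the published per-entry
values are reproduced; that regression requires real coordinate files,
which the user must fetch (the package never downloads), and runs as its
own acceptance block when `tests/testthat/structures/` is populated.

## Problem sizes and determinism

The test suite runs entirely on synthetic data: chains of 444–451 residues
for annotation and bend angles, 100–150-atom fragments for SASA
convergence, 19-injection isotherms, 100 seeded replicates for the noisy
K_D recovery and 10 for the bias-decay property. All randomness flows
through explicit seeds; the structure generators are pure functions of
their arguments, and the ITC noise generator isolates its RNG stream so
callers' seed state is untouched.

## Known limitations

* Role classification assumes approximately full-length tubulin chains;
  short fragments (< ~80 aligned residues) may fail the identity threshold.
* The registry's element boundaries outside the well-established core set
  are approximate; quantitative element-level claims on real structures
  should be re-run with a registry matching the user's preferred
  assignment.
* No crystallographic symmetry expansion: analyses see exactly the chains
  present in the file.
* Binder-side metrics use author numbering; binders get no canonical map.
* The ITC model is strictly one-site; multi-site or sequential schemes and
  raw thermogram integration are out of scope.
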