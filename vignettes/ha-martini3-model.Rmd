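---
title: "The hacg model: Martini 3 hyaluronic acid, from tables to topologies and chain observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hacg model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hacg)
```

## The model

Hyaluronic acid (HA) is a linear glycosaminoglycan built from a strict
disaccharide repeat, N-acetyl-D-glucosamine (GlcNAc) joined to
D-glucuronic acid (GlcA) through beta(1-3) and beta(1-4) glycosidic
linkages. In the Martini 3 coarse-grained description implemented here,
each disaccharide repeat is represented by nine interaction centers
("beads"): five on GlcNAc and four on GlcA. Beads come in three size
classes — tiny (T, two heavy atoms, mass 36 u), small (S, three, 54 u)
and regular (R, four, 72 u) — and each carries a Martini 3 chemical type
that defines its nonbonded behavior through the force field's pair
tables. The carboxylate bead of GlcA (S6, type Q5n) carries charge -1;
all other beads are neutral, so an HA chain of n monosaccharides has net
charge -n/2.

```{r}
bead_catalog("internal")
```

The anomeric beads (2 on GlcNAc, 7 on GlcA) are tiny inside a chain but
grow to small when the residue carries a free anomeric hydroxyl: in the
free monosaccharides, and at the chain's reducing end. Because chains are
built with GlcNAc at the non-reducing end, the reducing end is always
GlcA, so in chains only the terminal bead 7 is resized; bead 2 stays tiny
throughout. A consequence worth noting for readers of the parameter
tables: the free GlcA monomer's anomeric bead is labelled S7 here (its
actual size class), even though the monosaccharide table rows name it by
the chain-internal label T7.

## Bonded interactions and their functional forms

Four interaction classes define the bonded model, each in a specific
GROMACS functional dialect:

* **Bonds** (GROMACS bond type 1): `V = 1/2 k_b (b - b0)^2`, with `k_b` in
  kJ mol^-1 nm^-2 and `b0` in nm.
* **Angles** (angle type 2, the G96 cosine-harmonic form):
  `V = 1/2 k (cos th - cos th0)^2`. The printed unit of `k`
  (kJ mol^-1, not per squared angle) corroborates the cosine form; a
  harmonic-in-theta alternative is deliberately not provided, to avoid
  silent unit misuse.
* **Restricted bending** (angle type 10):
  `V = 1/2 k (cos th - cos th0)^2 / sin^2 th`, used for the one angle per
  repeat whose equilibrium approaches linearity (B6-B9-B8, 146 degrees).
  The sin^2 denominator makes the energy diverge at 180 degrees, which is
  the term's purpose: it keeps near-linear triplets away from the
  geometry where a torsion defined through them becomes numerically
  undefined.
* **Improper dihedrals** (dihedral type 2): harmonic in the angle
  deviation, with the deviation wrapped to (-180, 180] degrees and
  converted to radians before squaring. The parameter tables print the
  force constant under a per-degree-squared header, but GROMACS
  interprets dihedral-type-2 constants per radian squared; this package
  stores and serializes the printed values verbatim (so emitted
  topologies match the published files) and evaluates energies with the
  GROMACS convention. This is the one place where the printed unit and
  the evaluated unit differ, and it is intentional.
* **Proper dihedrals** (dihedral type 1): `V = k (1 + cos(m phi - phi0))`,
  with multiplicity 1 for both HA torsions. These two torsions —
  B1-B3-B8-B6 for the 1-4 linkage and B8-B7-B12-B11 for the 1-3
  linkage — are what restrains each glycosidic linkage to its main
  (exo-syn) conformational well; their force constants are negative
  (-32 and -60 kJ/mol), which simply inverts the cosine well.

Some bonds connect beads that are not covalent neighbors in the mapped
chemistry (for example B2-B9 and the four junction bonds with small force
constants). They exist to stabilize near-linear triplets, and they are
bonds in the full GROMACS sense: their endpoint pairs are excluded from
nonbonded interactions like any other bonded pair, because the model uses
`nrexcl = 1` (first covalent neighbors excluded).

All numbers live in one checksummed JSON file inside the package, loaded
once per session; no table value is hard-coded in function bodies. Every
other module queries this single source.

## Chain periodicity

The parameter template stores the repeat's terms once: twelve intra-repeat
bonds, eight angles, five impropers and one torsion among beads 1-9, plus
the junction terms that reference beads 10-18 of the following repeat
(four bonds, three angles, two impropers, one torsion). A chain of n
repeats is produced by emitting the intra terms at offsets 9r for every
repeat r and the junction terms for every r except the last. The
published tetramer table lists the second repeat's rows explicitly (in
italics in the original); those rows are periodic images and are *not*
stored — they fall out of the offset rule, and the test suite checks the
expansion against a brute-force oracle that instantiates the printed rows
one by one.

Term counts therefore grow linearly: `|bonds| = 12n + 4(n-1)`,
`|angles| = 8n + 3(n-1)`, `|impropers| = 5n + 2(n-1)`,
`|dihedrals| = n + (n-1)`.

Odd monosaccharide counts are rejected rather than truncated: the
parameter set has no rows for a GlcNAc reducing end, so such a chain
cannot be parameterized faithfully.

```{r}
build_chain_topology(8)
```

## Nonbonded scope

The model's nonbonded interactions are pair-specific Martini 3
Lennard-Jones terms plus Coulomb electrostatics under reaction field
(relative permittivity 15, 1.1 nm cutoffs). The pair C6/C12 matrix
belongs to the Martini 3 distribution and is deliberately not duplicated
here: emitted topologies reference bead type names (TP3r, SN4r, SQ5n,
...), and the generated `.top` includes the user's Martini 3 master file.
The package's `write_mdp()` emits a run-settings template with the
settings above, V-rescale temperature coupling, Parrinello-Rahman
pressure coupling, and the recommended timestep (0.01 ps for chains,
0.03 ps for free monosaccharides — the chain value reflects the stiffer
junction terms).

## Atomistic-to-CG mapping

Mapping is by center of geometry: each bead is the unweighted mean of its
member atoms — the bead's heavy atoms plus hydrogens bonded to carbon.
Hydroxyl and amide hydrogens are excluded, and weights are equal
regardless of element (this is COG, not center of mass; the test suite
pins the distinction by mapping a two-atom group and checking the exact
midpoint). The default atom-naming dialect is CHARMM36 carbohydrate
naming; tables for another dialect can be passed as a plain data.frame
without code changes.

One convention is ours rather than the parameter set's: the glycosidic
bridging oxygen is assigned to the bead containing the anomeric carbon of
its parent residue (bead 2 for the GlcNAc 1-4 linkage, bead 7 for the
GlcA 1-3 linkage). This keeps the ring-oxygen-plus-anomeric-carbon
groups intact and is recorded here because the mapping's owner for these
oxygens is not specified by the published scheme.

## Starting structures

`build_initial_coordinates()` is deterministic: it places each repeat at
a frozen, idealized repeat geometry advanced by a fixed per-repeat
translation. The template was obtained once by minimizing the model's own
bonded energy for a two-repeat fragment under a rigid-shift constraint,
then rounded to 0.1 pm and committed as a constant. The resulting
structures are not equilibrium conformations — they are compact,
clash-free inputs whose every bonded pair lies well within three times
its reference length, suitable for energy minimization and equilibration
in an MD engine. Bit-exact reproducibility was preferred over realism
here because these structures exist to seed external runs and regression
tests.

## Chain observables

**Backbone selection.** The chain direction is traced through the R3 and
S9 beads (indices 3 + 9r and 9 + 9s), giving 2n - 1 bond vectors for n
repeats — for the 100-mer, 99 vectors.

**Bond-vector autocorrelation.** `C(n)` is the mean cosine between unit
bond vectors separated by n bonds, averaged over all index pairs and
frames. Unit-vector normalization is used (rather than normalizing raw
dot products by the mean squared bond length); the choice is recorded in
the result's metadata, and `C(0) = 1` holds by construction.

**Persistence length.** `l_p` is obtained by fitting
`C(n) = exp(-n d / l_p)`, where d is the mean backbone bond length over
all selected vectors and frames (the averaging set is a documented choice;
"residue-to-residue bond length" admits several readings). The default
fit range is n from 1 to the last point above a noise floor of 0.05,
capped at half the number of bonds — beyond that, C(n) is dominated by
Monte-Carlo noise and fewer vector pairs. The fit is direct nonlinear
least squares in the single parameter l_p (robust when noisy C values
cross zero); a log-space linear fit is available as a cross-check. A
series that never decays is reported as "exceeds resolvable range"
rather than as a number.

**Radius of gyration and end-to-end distance.** Per frame, with equal
bead weights and the first-to-last-bead distance; means and standard
deviations are summarized.

**Surface area.** A Shrake-Rupley-style point-sampling SASA over beads,
with the size-class radii 0.191 nm (T), 0.230 nm (S) and 0.264 nm (R) and
a default probe of 0.14 nm. Surface points come from a deterministic
Fibonacci sphere (no RNG in the area estimate); 480 points per bead keeps
the area stable to well under 0.5 percent upon doubling the resolution,
which the test suite asserts. Exactly coincident identical spheres are
counted once — a degenerate input that a lattice-based method would
resolve the same way.

**Aggregates.** Molecules are clustered by single linkage on their
minimum inter-bead distances with a 0.6 nm contact cutoff — a
bead-contact convention (of the order of an R-bead diameter), not a
published value; it is a parameter of `cluster_aggregates()`.

## The worm-like-chain generator

`sample_wlc()` realizes the Kratky-Porod picture directly: successive
unit bond vectors with independent bending steps, where the bending
cosine is drawn from the equilibrium distribution
`p(cos t) ~ exp(kappa cos t)` with kappa solved (inverse Langevin) so
that `<cos t> = exp(-d / l_p)` exactly. Because steps are independent with
uniform azimuth, `E[C(n)] = exp(-n d / l_p)` holds in closed form, which
gives the estimator tests an analytic target instead of a simulated one —
the reason this construction was chosen over Metropolis sampling of a
bending energy. Frames are independent draws, seeded explicitly
(Mersenne-Twister), and the seed travels in the output metadata.

What the generator emulates is the decay of orientational correlations at
a known persistence length. What it does not emulate: excluded volume,
electrostatics, bond-length fluctuations, or any correlation between
frames. Tests passing on these ensembles therefore validate the
estimator pipeline (selection, autocorrelation, fit), not the physics of
real HA in solution, which requires actual MD.

## Numerical choices and degenerate inputs

* Angles are computed through the clamped arccosine; exactly collinear
  triplets raise an error, near-collinear ones (within 0.1 degree) return
  a value with a warning.
* Dihedrals follow the IUPAC sign convention via the atan2 formulation
  and wrap to [-180, 180); a trans-planar quadruplet reports -180.
  Impropers use the same four-point construction as propers.
* The restricted-bending energy is capped (default 1e6 kJ/mol, with a
  warning) when sin(theta) falls below 1e-6, so a pathological input
  yields a finite, flagged number rather than infinity mid-scan.
* Vectors shorter than 1e-9 nm are rejected as degenerate.
* ITP numeric formatting is fixed (bond lengths to three decimals,
  constants in their printed form), making write-parse-write
  byte-identical and diffs against distributed files meaningful.

## Problem sizes used by the checks

The shipped tests and the acceptance script run entirely on generated
data: chains up to the 100-mer (450 beads) for topology and
serialization checks, worm-like-chain ensembles of 50 bonds by 10^4
frames at l_p/d of 5, 10 and 20 for estimator validation (recovering
l_p to within a fraction of a percent; the acceptance threshold is 10
percent), and single-molecule surface-area and clustering fixtures.
These sizes were chosen so the whole validation runs in seconds while
keeping Monte-Carlo error an order of magnitude below the tolerances.

## Known limitations

* The package emits run-ready inputs but does not run MD; observables
  that require equilibrium ensembles (persistence length of real HA in
  salt, transfer free energies, aggregation kinetics, membrane and
  protein interactions) need an external engine and the Martini 3
  distribution files.
* Trajectory input is multi-frame GRO (or in-memory arrays); compressed
  trajectory formats are not read.
* The mapper handles free monosaccharides and residue-wise mapping of HA
  fragments under CHARMM36 naming; back-mapping (CG to atomistic) is out
  of scope.
* Bonded parameters are identical for internal and end residues (only
  bead sizes change at the reducing end); this mirrors the parameter
  set, which contains no end-specific bonded rows.
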