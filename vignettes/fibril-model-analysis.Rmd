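---
title: "Building and analysing three-fold-symmetric amyloid fibril models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing three-fold-symmetric amyloid fibril models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilTools)
```

## The system

Amyloid-beta (Aβ) fibrils isolated from patient brain tissue can adopt a
three-fold-symmetric architecture: three protofilaments of in-register,
parallel-stacked Aβ1–40 chains wind about a common axis, their C-terminal
β-strands lining a central water-filled pore. Unusually for mature fibrils,
the N-terminal residues 1–8 are structurally resolved in this polymorph, and
they matter: the polar contacts the N-terminal arm makes with the turn
region (residues 21–30) of the neighbouring chain in the same layer —
Arg5–Glu22, Arg5–Val24, Asp7–Ser26, Ser8–Ser26 — staple the three filaments
together. Removing the arm (Aβ9–40, acetyl-capped) destabilises the
three-fold fold, which then either dissociates or rearranges into a "2+1"
topology in which two filaments pair tightly along their C-terminal sheets
while the third hangs on laterally.

`fibrilTools` re-implements the model-building arithmetic and the
trajectory-analysis machinery needed to study this system: replicating a
template layer into stacks of arbitrary depth, truncating and capping the
N-terminus, accounting for every atom of a solvated, neutralised simulation
box, adjusting a periodic box so the fibril becomes infinite across the z
boundary, and computing the order parameters — inter-filament angle, pore
dimension, RMSD/RMSF, radius of gyration, contact statistics — by which
fibril stability is judged. Because the underlying molecular-dynamics
trajectories (200 ns, all-atom, explicit water) cannot be regenerated at
desk scale, the package carries a deterministic synthetic generator that
emulates the observed phenomenology and closes the loop between generator
and analyser in the test suite.

## Composition accounting

`countChainAtoms()` and `netChainCharge()` work from sequence alone under
one fixed protonation convention: Asp/Glu deprotonated, Lys/Arg protonated,
His neutral, charged termini contributing two extra hydrogens (N) and one
extra oxygen (C), and an acetyl cap contributing six atoms and no terminal
hydrogen. This convention is not a free choice: it is the only one under
which all eight published solvated-system totals are reproduced exactly
(598 atoms per full-length chain with net charge −3; 481 atoms per capped
truncated chain with net charge −2; each system's total being protein +
Na⁺ counter ions + 3 × waters).

```{r}
countChainAtoms(ABETA40)
netChainCharge(ABETA40)
systemComposition(3, 12, ABETA40, "charged", 24488)
```

Only anionic chains are supported; a cationic system would need counter
anions that the modelled setups never contained, so it is an error.

## The infinite fibril

For the periodic ("infinite") systems the twelve-layer stack is aligned
with z and the box height is shrunk until the distance between the top
layer and the periodic image of the bottom layer equals the template layer
spacing. `periodicZAdjustment()` measures that image distance on matched
reference atoms — by default the Cα centroids of the terminal layers, since
the original procedure does not name the atoms it measured in the
visualiser — and returns the shrink and new height; the adjustment is
idempotent by construction. `pruneWatersOutside()` then deletes waters
whose oxygen falls outside the half-open interval [0, newZ); the half-open
convention prevents a molecule sitting exactly on the periodic face from
being counted in two images.

## Geometry metrics

* **Inter-filament angle.** Each filament's axis is the vector between the
  Phe19 Cα atoms of its two outermost layers; the order parameter is the
  arc-cosine of the normalised dot product, averaged over the three
  unordered filament pairs, with the dot product clamped to [−1, 1]. The
  printed formula in the source material is typographically corrupted; this
  reading is the one consistent with its surrounding text and with the
  near-zero values reported for aligned stacks. For the periodic system the
  "outermost" layers are those of the primary cell.
* **Pore dimension.** Mean intra-layer Met35–Met35 side-chain distance. The
  reference atom is selectable (`SD` sulfur by default, `CE` or the
  side-chain centroid as alternatives) because the original analysis does
  not name it.
* **RMSD/RMSF.** Backbone (N, Cα, C, O) over residues 9–40, so full-length
  and truncated systems are compared on identical atoms. RMSD is minimised
  over rigid-body transforms (Kabsch/SVD). RMSF is measured about the
  time-average structure after per-frame superposition onto the reference —
  the first frame unless one is supplied, since no reference is stated.
  Whether the published scalar summary averaged atoms or residues first is
  also unstated, so both reductions are returned.
* **Radius of gyration.** Mass-weighted; the per-system reading "averaged
  over all layers" is resolved as the mean over layers of each layer's
  three-chain Rg, with the whole-assembly value also available.

All of these are invariant under rigid-body motion of a frame, which the
test suite asserts under random rotations. Note one numerical caveat: near
0° the arc-cosine loses half the working precision, so identities involving
the untwisted fibril are asserted to absolute 1e-5 degrees rather than
relative tolerance.

## Contact statistics

A contact is an atom pair closer than 4 Å; the comparison is strict, so
boundary equality is reproducibly "no contact". Hydrogens are included by
default (the trajectories being emulated are all-atom, and the reported
inter-filament magnitudes are consistent with all-atom pairs), with a
heavy-atom scope available. Counting uses a cell-list spatial grid in C++,
which the tests hold equal to an O(n²) double loop on seeded random
instances.

The residue-level map follows the published reading: a residue pair is "in
contact" in a frame if at least one atom pair is within the cutoff, and the
map reports the percentage of frames in contact between the N-terminal
residues 1–8 of each chain and the turn residues 21–30 of its *cyclic
successor* in the same layer (1→2, 2→3, 3→1), averaged over layers and, when
several runs are supplied, over runs with equal weight. The frame-fraction
reading (rather than normalised atom-pair counts) is taken as primary
because the published figure is captioned as mean percentage values.
Kymographs order the chain pairs as in the stack — pair-major, layers bottom
to top, so a 12-layer fibril yields 36 rows. Inter-filament series divide by
the layer count by default, matching the "contacts per layer" narration of
the reported magnitudes (~60 per interface in the retained triple fibril,
~160 versus ~20 in the 2+1 state).

## Topology classification

The published taxonomy — triple-symmetric, 2+1, dissociated — is qualitative;
no numeric state boundaries are defined. The classifier therefore exposes
its thresholds (`tLow = 10` contacts/layer for a broken interface,
`tHigh = 40` for a paired one, both echoed in every result) with defaults
placed to separate the reported per-layer magnitudes. The rules are applied
in a fixed precedence:

1. `TWO_PLUS_ONE`: exactly one interface ≥ `tHigh` while the other two are
   below `2 * tLow`;
2. `DISSOCIATED`: at least two interfaces below `tLow`;
3. `TRIPLE`: all three interfaces ≥ `tLow` with max/min ratio < 3;
4. `OTHER` otherwise.

The 2+1 signature is tested first deliberately: its defining pattern (one
strongly reinforced interface, two collapsed ones) would otherwise be
swallowed by the dissociation rule. A natural-language reading of the rule
set in which `TRIPLE` requires *not* exceeding `tHigh` would misclassify
the benchmark case of three ~60-contact interfaces, so the balanced-triple
condition does not cap the counts. Trajectory classification smooths each
interface series with a centred moving average (default window 10 frames,
chosen to suppress single-frame flicker) and reports the modal label of the
final window as the end state; trajectories much shorter than about four
windows leave too little settled tail to classify reliably.

## The synthetic generator

`buildIdealFibril()` constructs a coarse, analytically engineered triple
fibril: one Cα per residue plus named side-chain reference atoms (the Met35
SD lining the pore, the arm references Arg5 CZ / Asp7 CG / Ser8 OG, turn
references on Glu22/Asp23/Val24/Ser26/Asn27, and Cβ atoms on non-glycine
strand residues). The three chains of a layer are exact C3 images about z;
layers are exactly in register at 4.8 Å. Three features are engineered to
be *exactly* recoverable:

* the stacking vector — `meanLayerDisplacement()` returns
  `(0, 0, layerSpacing)` to machine precision;
* the pore — the Met35 SD sits at `poreRadius` from the axis, so the
  intra-layer SD–SD distance is √3 · `poreRadius`. The default radius of
  11.5 Å gives 19.9 Å, the relaxed ~20 Å pore seen in simulation rather
  than the 23 Å of the deposited starting structure; the blueprint dial
  reaches the latter at 13.28 Å;
* the contact pattern — the N-terminal arm reaches the successor chain's
  turn with reference-atom pairs at 3.8–3.9 Å placed so that the arm–turn
  contact map lights **exactly** the four initial-structure cells
  (Arg5–Glu22, Arg5–Val24, Asp7–Ser26, Ser8–Ser26), while the C-terminal
  strand ends ladder against the neighbour's N-strand to give each
  interface a fixed ~26 contacts per layer, inside the classifier's TRIPLE
  band.

`simulateTrajectory()` layers rigid-body motions over this scaffold with
i.i.d. isotropic Gaussian jitter (simplest noise model with a closed-form
RMSF, σ√3) and a fixed seed giving byte-identical frames:

* `stable` — jitter only;
* `twist` — each filament tilts about its own radial direction by a
  linearly growing angle; the mean pairwise axis angle follows the analytic
  form `acos(cos²θ − sin²θ/2)`;
* `dissociate` — filament 1 translates radially outward at constant
  velocity (default 1 Å/frame, far enough over a default trajectory for its
  interfaces to empty completely);
* `two_plus_one` — filament 1 detaches while, after an onset delay at 40 %
  of the trajectory, filament 3 swings its C-terminal sheet across the
  vacated pore and docks it antiparallel against filament 2's C-terminal
  sheet — the published hallmark of the 2+1 interface. The total contact
  count consequently dips and then recovers, and the reinforced interface
  ends several-fold above the two broken ones. Both motions saturate before
  the final frames so the end state is held.

What the generator does **not** emulate: real side-chain packing and
rotamers, the initial 23 → 20 Å pore relaxation (an equilibration
phenomenon), solvent, secondary structure, and any energetics — the
magnitudes of its contact counts are those of a coarse scaffold, not of an
all-atom system. A green test on synthetic data therefore establishes that
the *analysis machinery* is correct and self-consistent, not that any
physical simulation would behave this way.

```{r}
model <- buildIdealFibril(fibrilBlueprint(nLayers = 6))
tr <- simulateTrajectory(model, trajectoryConfig("two_plus_one", seed = 104))
series <- interfilamentSeries(tr, model)
classifyTrajectory(series)$endState
```

## Degenerate inputs and tie-breaks

Zero-norm filament axes, empty selections, missing residues/atoms, chain
counts that do not fill the filament × layer grid, single-frame RMSF
requests and cationic compositions are all errors with named causes rather
than silent results. Boundary cases that are defined, not errors: a contact
at exactly the cutoff is no contact; a water exactly on the periodic face
is deleted; truncation at residue 1 only replaces the charged N-terminus
with the cap; re-truncating an already capped chain at the same residue is
a no-op, while a *different* requested range on a capped chain is an
incomplete-chain error.

## Known limitations

* The chain → (filament, layer) assignment of a deposited multi-chain entry
  is a convention (`layer-major` by default, overridable by an explicit
  mapping), because the deposition order is not documented against the
  filament labels used in the analyses.
* The published per-system RMSD/RMSF/Rg/angle values require the original
  200 ns trajectories and are deliberately out of reach; the package
  validates those operations against closed forms and independent oracles
  instead.
* Geometry checks against the deposited entry (initial 23 Å pore, 3.85 Å
  adjacent-layer Asp7–Asp7 distance) need the entry's coordinates, which an
  offline environment cannot fetch; the corresponding acceptance test fails
  with a clear message unless a local copy is provided, and a synthetic
  stand-in exercises the same measurement pipeline.
* The acetyl cap is placed with ideal internal geometry along the former
  backbone direction; no energetics are computed, so any chemically sane
  placement is equivalent for this package's purposes.
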