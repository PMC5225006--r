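---
title: "Predicting active sites from normal-mode exposure changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting active sites from normal-mode exposure changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposite)
```

## The model

Enzymes breathe. Their low-frequency collective motions — well captured by
the normal modes of a coarse-grained elastic network — open and close the
catalytic cleft, and the residues lining that cleft are exactly the ones
whose solvent-accessible surface area (SASA) changes most as the molecule
moves between the two opposite extremes of a mode. `exposite` turns this
observation into a predictor:

1. **Elastic network.** One node per residue at its C-alpha; uniform
   springs of stiffness $\gamma$ join all node pairs closer than a cutoff
   $r_c$ (a Tirion network, no energy minimisation). The potential is
   $V = \tfrac{\gamma}{2}\sum_{(i,j)} (|\mathbf{r}_{ij}| -
   |\mathbf{r}_{ij}^0|)^2$, whose Hessian has the standard
   anisotropic-network block structure
   $H_{ij} = -\gamma\,\hat{\mathbf d}_{ij}\hat{\mathbf d}_{ij}^{\mathsf T}$
   for contacting pairs.
2. **Modes.** The Hessian is diagonalised; the six zero-frequency
   rigid-body modes are removed and the $K$ lowest non-trivial modes are
   kept.
3. **Extreme conformers.** For each mode the structure is displaced along
   the eigenvector in both directions (each residue moves rigidly with
   its node), producing a "plus" and a "minus" conformer whose midpoint
   is the input structure.
4. **Exposure change.** Per-residue SASA is computed for both conformers
   (Shrake–Rupley) and the absolute difference $|\Delta SAS|$ taken.
5. **Flagging and the site.** A residue is flagged when its
   $|\Delta SAS|$ falls in a window $[w_\min, w_\max]$ in at least one
   mode. The predicted active site is the unweighted centroid of the
   flagged residues' C-alpha coordinates.
6. **Pockets.** LIGSITE-style geometric pockets (grid scan for
   protein–solvent–protein enclosure, clustering, a 7 Å³ volume floor,
   at most 10 kept) are ranked by distance of their centre to the
   predicted site. The ranking embodies the method's central claim: the
   active site need not be the largest pocket, but it is the pocket
   closest to the centre of maximal exposure change.

Evaluation uses two criteria: the **centroid criterion** (distance from
the predicted site to the centroid of annotated catalytic residues,
success strictly below 12 Å) and the **ligand criterion** (any bound
ligand atom within 4 Å of the site, inclusive). The strict/inclusive
readings follow the criteria's plain wording; the boundary cases are
exercised in the test suite.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `enm_cutoff` | 12 | Å | standard C-alpha ANM contact cutoff; dense enough for rigid domains |
| `gamma` | 1 | energy/Å² | only sets the eigenvalue scale; mode shapes are scale-free |
| `n_modes` | 10 | — | the lowest non-trivial modes carry the hinge content; accuracy plateaus near 8–10 |
| `amplitude` | 2.0 | Å | inter-extreme C-alpha RMSD of each deformation (see below) |
| `dsas_min`, `dsas_max` | 20, 40 | Å² | below ~10 Å² ordinary exposure fluctuations dominate; far above 40 Å² the "tip effect" of flexible termini does |
| `dsas_ceiling` | off | Å² | optional hard cap (e.g. 75 Å²) against termini artefacts |
| `n_sphere_points` | 960 | — | Shrake–Rupley lattice size; ~0.5 % area accuracy |
| probe radius | 1.4 | Å | water |
| vdW radii | C 1.70, N 1.55, O 1.52, S 1.80 | Å | compact heavy-atom table; $|\Delta SAS|$ is a difference, so calculator-specific offsets cancel |
| `grid_spacing` | 1.0 | Å | LIGSITE-family default |
| `min_psp` | 3 of 7 | — | LIGSITE-family default scan rule |
| `pocket_min_volume` | 7 | Å³ | pockets smaller than this cannot hold a ligand |
| `keep_pockets` | 10 | — | the largest ten suffice |

**Amplitude convention.** Mode eigenvectors have no natural length scale,
and a fixed program-internal amplitude produces smaller deformations for
larger molecules. We therefore parameterise the deformation by the
C-alpha RMSD between the two extreme conformers (default 2 Å), which is
physically interpretable and size-independent. The flagging window was
confirmed against this convention with the `sweep_thresholds()` utility
on hinge fixtures: the [20, 40] Å² window dominates high windows such as
[60, 80] Å², mirroring the trained operating point.

**Aggregation over modes.** A residue qualifying in *any* sampled mode is
flagged (union semantics) — the most literal reading of flagging "for
each mode" and predicting over "all residues" in the window. A
max-over-modes alternative (`aggregate = "max"`), under which a residue
whose maximum exposure change overshoots the window is excluded even if
some mode lands inside it, is exposed as a configuration switch.
Residues flagged in several modes are *not* weighted in the centroid.

## Numerical choices

* **Deterministic SASA lattice.** Test points come from a golden-section
  spiral, not random sampling, so there is no seed anywhere in the
  default pipeline and identical inputs give bitwise-identical reports.
* **Locally oriented lattice.** Each atom's point lattice is rotated into
  a frame built from its two nearest neighbours (nearest atom defines the
  first axis, nearest non-collinear atom completes it). Because the frame
  co-rotates with the structure, computed areas are *exactly* invariant
  under rigid-body motion — a pure rotation of the input produces a
  per-residue $|\Delta SAS|$ of numerically zero rather than lattice
  noise. This matters because the exposure-change signal itself is a
  small difference of large areas.
* **Trivial-mode tolerance.** Eigenvalues below $10^{-8}$ of the largest
  are treated as rigid-body modes. A connected, non-collinear network has
  exactly six; a collinear network (e.g. the two-node dimer used in
  closed-form tests) has five; more than six signals a disconnected
  network and is refused with an error rather than silently analysed.
* **Pocket tie-breaks.** Pockets sort by volume (descending), then by
  distance of the centre to the molecular centroid (closer first), then
  lexicographically by centre — a total, reproducible order.
* **6-connectivity clustering** avoids diagonal leakage that would merge
  adjacent sub-pockets across corner contacts.
* **Degenerate inputs.** An empty flagging window raises a typed
  no-signal condition (`exposite_no_signal`) so callers can widen the
  window; rigid single-domain structures (the helix fixture) end there
  rather than in a spurious prediction.

## The synthetic fixtures

Real benchmark sets require coordinated downloads of structures and
curated catalytic-residue annotations. The package instead ships
generators whose ground truth is fixed *geometrically at build time*, so
no stage of testing can overfit to a discovered answer.

**Hinge fixture** (`make_hinge()`). Two 40-residue lattice domains face
each other across a cleft (`gap`, default 6 Å between the facing C-beta
shells) and are joined by a sparse 3-residue linker bar above it. The
linker acts as a door hinge: rotation about the bar is the one relative
domain motion its springs do not resist, so the softest non-trivial mode
is a clamshell opening along the inter-domain axis (its displacement
variance along that axis exceeds 60 %). The facing C-alpha planes sit
just beyond the elastic-network cutoff, so no spring crosses the cleft to
stiffen the opening. The central patch of each face carries an extended
pseudo side chain (C-beta at 1.8 Å plus a C-gamma "finger" reaching into
the cleft); opposing finger tips rest ~5.4 Å apart, at the edge of mutual
occlusion, and the cleft's breathing switches their occlusion on and off
— a per-residue exposure change of a few tens of Å², the signal the
window is tuned to. One domain's outer plate is pushed outward and
roofed, enclosing a decoy canyon *larger* than the cleft pocket but far
too wide for any atom–atom occlusion: size-ranking would pick the decoy,
exposure-ranking must pick the cleft. Coordinates carry seeded uniform
jitter (±0.3 Å); fixtures are bitwise reproducible per seed.

What the fixture does **not** emulate: real side-chain packing and
chemistry, solvent structure, anharmonicity, multi-domain allostery, or
the statistics of real catalytic-site annotations. Passing the fixture
suite therefore demonstrates that the pipeline's geometry, signal
extraction and decision logic are correct and robust to coordinate
noise — not that the trained thresholds transfer to any particular real
enzyme family.

**Slab-with-well** (`make_slab_with_well()`) is the pocket-detection test
bed: a dense pseudo-atom slab with a rectangular excavation open at the
top face. Its reported nominal volume is computed by an independent
continuum oracle (`psp_void_volume()`): a fine point lattice combined
with *analytic ray–sphere intersections* for the 7-direction enclosure
criterion — no occupancy grid, no marching. The grid detector's volume
error against this reference drops from ~14 % at 1 Å spacing to <1 % at
0.5 Å. We deliberately define nominal volume this way rather than as the
product of the well dimensions: the walls of any real excavation bulge
inward by the probe-expanded atom radius, so the box product is not a
quantity any accessibility-based detector converges to.

**Helix** (`make_helix()`) is the rigid negative control: an ideal
C-alpha helix whose modes change no residue's exposure into the flagging
window, ending in the no-signal condition.

## Problem sizes

The shipped tests and the acceptance script use: 1000 (tests) / 200
(script) random connected globules of 10–200 residues for the
elastic-network properties; 20 separations for the two-sphere closed
form; 20 seeded rigid-motion null cases; the 10×10×5 slab with a 2×2×2
well at 1.0 and 0.5 Å grid spacing; and 50 seeded hinge fixtures
end-to-end. On one CPU the full test suite runs in about two minutes and
the acceptance script in under one.

## Known limitations

* The per-residue rigid translation of side-chain atoms along a mode does
  not repair bond geometry; large amplitudes can create locally
  unphysical conformers. The flagging window suppresses the resulting
  exaggerated exposure changes, and the default 2 Å RMSD amplitude keeps
  deformations modest.
* Single-chain input is recommended. Multi-chain assemblies are parsed,
  but a binding site at a chain interface can present as several partial
  pockets, and the exposure centroid of several clefts is a compromise
  coordinate near none of them.
* Chain termini and long flexible loops can flag spuriously (the tip
  effect). The CLI accepts `--residue-range FIRST:LAST` to clip them, and
  `dsas_ceiling` caps pathological exposure changes; neither is automatic.
* No conservation, sequence or chemical features are used — by design
  this is a structure-only method, and it should be combined with
  homology-based evidence where available.

## A worked run

```{r example}
fx <- make_hinge(seed = 1)
pred <- predict_active_site(fx$structure)
pred
round(sqrt(sum((pred$site - fx$cleft_center)^2)), 2)  # distance to truth, A
evaluate_centroid(pred, fx$cleft_lining_residues, fx$structure)
```
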