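---
title: "From 3D label masks to calibrated Cellular Potts simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 3D label masks to calibrated Cellular Potts simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherosim)
```

## The problem

Segmenting every cell of an optically cleared tumor spheroid yields a 3D
*label mask*: an integer lattice in which voxels of cell *i* carry the ID
*i* and medium is 0. spherosim turns such a mask into the initial state of
a Cellular Potts Model (CPM) simulation, evolves it with Metropolis Monte
Carlo dynamics, and calibrates the model's energy parameters so that the
simulated tissue keeps realistic single-cell morphology. Starting the
simulation from the imaged configuration — instead of stacked cubes that
must first relax into something tissue-like — lets a deliberately simple
model produce plausible short-term dynamics.

Because the raw microscopy is not redistributable, the package carries a
synthetic generator that emulates the segmented input, so every stage is
testable end to end.

## The model

Each voxel of the lattice belongs to a cell, to the medium, or to a frozen
one-voxel *wall* shell lining the lattice boundary (a barrier that stops
cells from adhering to the box). The energy of a configuration is

$$
H = \sum_i \lambda_V \left(V_i - V_i^{t}\right)^2
  + \sum_i \lambda_A \left(A_i - A_i^{t}\right)^2
  + \sum_{i<j} J^{c\text{-}c} A_{ij}^{c\text{-}c}
  + \sum_i J^{c\text{-}m} A_i^{c\text{-}m}
  + \sum_i J^{c\text{-}w} A_i^{c\text{-}w},
$$

with $V_i$ the voxel count of cell $i$, $A_i$ its face-contact area (in
lattice faces), and the $A^{\cdot}$ terms the contact areas between the
respective entity pairs. One Monte Carlo step (MCS) is one copy attempt
per interior lattice site: a random site and a random neighbor from the
copy neighborhood are drawn; if their IDs differ and neither is wall, the
neighbor's ID is copied into the site with probability
$\min(1, e^{-\Delta H / T})$. The engine keeps $V_i$, $A_i$ and the total
energy incrementally; an independent full-recomputation `hamiltonian()`
exists purely so tests can verify the incremental path against it.

### Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `lambda_V` | J/pix^6 | 10 | strong volume constraint; the value grid scans select for HT-29-like spheroids |
| `lambda_A` | J/pix^4 | 0.001 | near-zero surface constraint, ditto |
| `J_cc` | J/pix^2 | 2 | weak cell–cell interface cost (cells prefer each other over medium) |
| `J_cm` | J/pix^2 | 55 | high cell–medium cost keeps the aggregate compact |
| `J_cw` | J/pix^2 | 100 | wall contact prohibitively expensive; the original study leaves this to unavailable supplementary material, so it is an explicit, configurable stand-in |
| `temperature` | units of H | 10 | Metropolis fluctuation amplitude, a typical magnitude relative to the J values; also a documented stand-in |
| `contact_neighbor_order` | – | 1 (faces) | contact energies summed over face pairs keeps $A$ interpretable as pix²; orders 2–3 available |
| `copy_neighborhood` | – | 26 | standard CPM copy kernel |

### Targets: "already at its target volume and surface"

Cells whose volume lies in $[0.15\,\bar V,\ \bar V + 2\,\mathrm{sd}(V)]$
are treated as correctly segmented and start at their own measured
$(V, A)$; cells outside the band (likely segmentation errors) receive the
jointly sampled $(V, A)$ pair of a random in-band donor. Two points are
easy to get wrong:

* the pair is sampled **jointly** — mixing one donor's volume with
  another's surface would produce physically inconsistent targets;
* the surface target must be measured in the **engine's** units
  (face-contact area, `face_contact_areas()`), not the border-voxel count
  of the feature table. The two differ by roughly 3×; using the wrong one
  silently puts every cell far off its surface target at MCS 0,
  contradicting the premise that in-band cells start at equilibrium. This
  was caught by a frozen-limit test (huge constraint weights must keep
  IoU ≈ 1) and is why `init_state()` builds default targets through an
  engine-unit feature table.

## Morphometrics

`compute_features()` reports, per cell: volume; surface as the
*border-voxel count* (cell voxels with a 6-neighbor outside the cell);
major/minor principal axis lengths of the second-moment ellipsoid;
eccentricity $\sqrt{1 - (\text{minor}/\text{major})^2}$; V/A; and
sphericity $\pi^{1/3}(6V)^{2/3}/A$. Conventions worth noting:

* Second moments include a per-axis $1/12$ unit-cube term, so a single
  voxel has axis length $\sqrt{20/12}\approx 1.29$ and eccentricity is
  always strictly below 1 (without the term, 1-voxel-wide rods degenerate
  to eccentricity exactly 1). Axis length is $\sqrt{20\lambda}$ because a
  solid ellipsoid of semi-axis $a$ has principal moment $a^2/5$.
* 3D eccentricity is defined from the extreme axes so it reduces to the
  planar meaning for flat objects; the convention is isolated in this
  module and can be swapped.
* Border-voxel counting *underestimates* continuum area: digital balls
  score sphericity ≈ 1.3, not 1. Sphericity is a relative compactness
  score; tests pin its value for digital balls to a regression band
  rather than to a continuum limit.
* The border-voxel surface is deliberately distinct from the engine's
  face-contact $A_i$; both are exposed (`compute_features()` vs
  `face_contact_areas()`).

## Preprocessing

`preprocess_pipeline()` applies, in order: removal of labels smaller than
5 voxels (strictly smaller — a 5-voxel label survives), per-label binary
closing then opening, thin-label resolution, and nearest-neighbor
z-upsampling to isotropic voxels. Decisions behind the stages:

* **Structuring element.** A Chebyshev ball (3×3×3 box at radius 1). A
  Euclidean ball of radius 1 (the octahedron) rounds the edges of convex
  solids, so even a perfect cube would not survive opening unchanged; the
  box leaves convex solids exactly invariant while still filling
  single-voxel holes and shaving single-voxel spikes. Morphology is done
  per label on its binary mask (grayscale morphology on the ID image
  would mix labels); voxels still claimed by their original owner keep
  it, remaining claims go to the lowest ID.
* **Thin labels.** A label spanning ≤ 2 z-planes is "thin". Face-adjacent
  thin labels merge transitively under the lowest participating ID (the
  only order-independent extension of pairwise merging); a thin label
  with no thin neighbor is deleted. The rule iterates to a fixed point:
  a merge whose result is still thin and isolated is deleted on the next
  sweep. Fixed-point semantics is what makes the operation idempotent —
  with single-pass semantics, a merged-but-still-thin label would be
  deleted only on a second call. Note that with the default radius-1
  opening, any ≤2-plane object is erased at the morphology stage already
  (its z-neighbors cannot both lie inside), so the merge rule matters
  chiefly when `opening_radius = 0`.
* **Upsampling.** The slice count scales by $d_z/d_x$, rounded half away
  from zero: a 517×517×136 stack at 0.5682×0.5682×2.0 µm becomes
  517×517×479 (136·2.0/0.5682 = 478.7). Every output slice is an exact
  copy of some input slice, and since $d_z \ge d_x$ every input slice
  appears, so no label can vanish. Thin-label extent is measured *after*
  closing/opening, per the stage order.

## Similarity and the calibration objective

For each morphological feature $k$, the start and current per-cell
samples are compared with

$$ W_k = \left( \tfrac1n \sum_i (X_{(i)} - Y_{(i)})^2 \right)^{1/2}, $$

the root-mean-square of ordered differences. This printed form is an L2
variant of the classical first Wasserstein (order-statistics) distance;
the L1 form $\frac1n\sum_i |X_{(i)}-Y_{(i)}|$ is available via
`form = "l1"`, and the RMS form is the default for fidelity to the
formula the pipeline was built around. Unequal sample sizes (cells can
vanish) are first interpolated to common quantile ranks at $n=\max$
size, which reduces exactly to the order statistics at equal sizes.
Per-feature distances are averaged *raw*, mixing units, exactly as the
objective defines; an optional normalization by the start-sample standard
deviation exists but is off by default.

Spatial fidelity is the per-cell intersection over union against the
initial frame; vanished cells score 0 and drop out of the current feature
sample (no feature row can exist for them). The calibration objective is

$$ \mathrm{WIP} = \Big(\tfrac1{N_f}\sum_k W_k\Big)\cdot\Big(\tfrac1{N_c}\sum_i \mathrm{IoU}_i\Big), $$

minimized over a parameter grid. The first factor rewards stable ensemble
distributions; the second penalizes frozen simulations (IoU ≈ 1), which
would otherwise trivially win on $W$ alone.

## The synthetic world

`generate_spheroid()` tessellates a digital ball with the Voronoi cells
of jittered grid seed points: convex-ish, space-filling cells with a
controllable count and size spread — the salient features of a packed
spheroid interior. Defaults (80 cells, radius 20 voxels, jitter 0.35 of
the seed pitch) give cells of a few hundred voxels, the scale at which
the published filters (5-voxel debris, 1–2-plane slivers, the 15 % /
mean + 2 sd band) are meaningful. Anisotropic spacing is supported (the
ball and metric live in physical units), reproducing the flattened
geometry of a raw confocal stack for the upsampling stage.
`inject_artifacts()` adds the three error classes the cleanup stage is
designed for: 1–4-voxel debris and ≤2-plane slivers carved out of medium
adjacent to the aggregate surface (mimicking shed-voxel errors without
damaging real cells), and size outliers made by eroding or dilating
existing cells, which preserves connectivity.

What a green test does *not* establish: the generator produces no
intensity data, no realistic noise statistics for artifact *frequencies*
(the source only defines the filter rules, not error rates — counts are
user parameters), and its cells are more convex than real segmented
cells. Quantitative agreement with any particular imaged spheroid is out
of reach by design; the tests establish correctness of the operations
and the *direction* of calibration effects.

The directional calibration check fixes $J_{cm}=55$, $J_{cc}=2$,
$\lambda_A=2$, $T=10$ on a 48³ spheroid (80 cells), 60 MCS, seeds 1–3,
and compares $\lambda_V = 10$ against $\lambda_V = 0.001$: the strong
volume constraint must yield the smaller volume-feature Wasserstein
distance. $\lambda_A$ is set mid-grid so the weak-$\lambda_V$ arm
degrades through volume drift specifically (with both constraints near
zero the high $J_{cm}$ shrinks cells outright, which also separates the
arms but tests less specifically). These choices were fixed before
measuring. Typical output: median $W_{\text{volume}}\approx 6$ (strong)
vs $\approx 109$ (weak) — a ~17× separation, with WIP also preferring
the strong constraint.

## Numerical choices and degenerate inputs

* Determinism: all stochastic stages consume R's RNG; the C++ engine
  draws through the same stream, so `set.seed()` reproduces trajectories
  bit for bit regardless of how the run is chunked.
* A copy attempt whose candidate equals the site's ID counts as an
  attempt but is skipped (one MCS stays exactly $N$ attempts); wall is
  never source nor target.
* Cells may fragment or vanish — there is no connectivity constraint;
  calibration is expected to penalize such outcomes via the objective.
* Empty volumes: features return an empty table; an empty interior gives
  a wall-only state; scoring a frame in which *every* start cell vanished
  is an error (the feature sample would be empty).
* Voronoi ties go to the lowest seed index; grid enumeration and scan
  ranking tie-breaks are lexicographic in the parameter tuple, so ranked
  output is reproducible.
* PIF coordinates are 0-based inclusive ranges, matching the CompuCell3D
  convention (the format's purpose is interop); the writer emits strictly
  one voxel per line, the reader also accepts genuine boxes, with later
  records overwriting earlier ones.
* TIFF I/O is a minimal baseline implementation (uncompressed,
  strip-based, integer 8/16/32-bit, both byte orders) because no R TIFF
  reader is available in the target environment; it is cross-validated
  against an independent implementation in the test suite. Voxel spacing
  never comes from TIFF metadata: a JSON sidecar or an explicit argument
  is required, and missing spacing is an error rather than a guess.

## Known limitations

* The Metropolis copy-from-neighbor proposal is not symmetric in
  general, so detailed balance holds only up to proposal multiplicity —
  a standard CPM caveat. The engine's sampling is verified on a
  constructed two-state system where the proposals *are* symmetric and
  the occupancy ratio is exactly Boltzmann.
* Temperature, wall energies and neighbor orders are documented
  stand-ins for constants the original study does not print; absolute
  energies are in arbitrary lattice units.
* No chemical fields, growth, mitosis, or cell-type differentiation; no
  GPU path. Whole-volume scans at full microscopy scale are possible but
  expensive; the intended calibration path is a cropped patch with
  boundary-clipped cells removed (`drop_boundary_labels()`).
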