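---
title: "Methods: bilayer-constrained isosurface docking in memdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilayer-constrained isosurface docking in memdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memdock)
```

This vignette is the package's own account of its model, the parameters that
matter, the numerical choices behind the implementation, and what the
synthetic fixtures do and do not demonstrate.

## The docking model

`memdock` docks a mobile *ligand* monomer onto a fixed *receptor* monomer,
both transmembrane proteins preoriented in the OPM convention: the membrane
normal is **+z** and the centre of mass of the transmembrane region sits at
z = 0. Preorientation is an input contract, not something the package
computes; `check_preorientation()` reports the signed z-offset of the TM
centre of mass and warns beyond a tolerance (3 Å by default). When no TM
residue range is supplied, the TM region defaults to all residues whose Cα
lies in the slab |z| ≤ 15 Å — a typical bilayer half-thickness — and the
centre is mass-weighted (geometric weighting is available via a flag; the
convention itself does not fix the choice, and for roughly homogeneous
protein matter the two differ negligibly).

### Density maps

Each partner is represented by a scalar field on a regular cubic grid. For
an ensemble of F frames with atom positions r_a and weights w_a (uniform, or
atomic masses):

ρ(x) = (1/F) Σ_f Σ_a w_a · G(x − r_a; σ)

with G an isotropic Gaussian of width σ, after which the map is divided by
its maximum so the peak value is 1. The kernel is truncated at 4σ (the
neglected mass is below 1e−4 of a kernel); the grid spans the ensemble
bounding box plus a padding margin; grid axes stay aligned with the
laboratory frame because the membrane frame is already fixed by
preorientation.

This functional form is deliberately a *stand-in* for richer
spatial-influence density maps that also encode electrostatics and
correlated dynamics. Everything downstream — the isovalue cutoff, surface
extraction, complementarity scoring, the positive-score convention — depends
only on having a smooth, ensemble-derived, max-normalised field, so a more
faithful density model can be dropped in behind `density_params()` without
touching the rest of the engine. For the same reason the package does not
attempt the solvent-accessible-surface-area calibration that selects the
ideal isovalue for true influence maps: the relationship is not derivable
from first principles here, so the isovalue is an explicit parameter
instead.

Defaults, all overridable through `density_params()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `grid_spacing` | 1.0 | Å | resolves σ = 1.8 Å kernels; tests and the acceptance run use 1.5–2.0 Å to cut vertex counts |
| `kernel_sigma` | 1.8 | Å | of the order of a heavy-atom van der Waals radius, so atoms blur into a molecular envelope |
| `atom_weighting` | uniform | — | shape is what matters for complementarity; mass weighting available |
| `padding` | 8.0 | Å | > 4σ, so no kernel mass is clipped at the grid boundary |
| `isovalue` | 0.5 | fraction of max | places the surface near the ensemble envelope on a max-normalised map |

### Isosurfaces

`extract_isosurface()` triangulates the level set with marching tetrahedra
on a six-tetrahedron cube decomposition. Marching tetrahedra was chosen over
the classic 256-case cube table because every sign configuration is
topologically unambiguous, the shared-diagonal decomposition is watertight
across cube faces, and the code is small enough to verify. Edge vertices are
first placed by linear interpolation and then refined by 24 bisection steps
of the *trilinear* interpolant along the edge, so every vertex lies on the
level set of the continuous field (the level-set residual tolerance asserted
in the tests, 5% of the isovalue, is met with orders of magnitude to spare).
Vertex normals are the trilinearly interpolated central-difference gradient,
oriented down-gradient — away from high density, i.e. outward; gradient
normals are more robust on coarse grids than face-averaged ones. In the
degenerate case of a vanishing gradient the normal falls back to the
direction away from the map centroid.

### The complementarity score

For a pose transform T, ligand vertices v (and normals n_v) are moved
rigidly, and

score(T) = Σ_{v : d(v) ≤ c} max(0, −n_v · n_r(v)) − λ · #{v strictly inside}

where n_r(v) is the normal of the nearest receptor vertex, c the contact
distance and λ the clash penalty. "Inside" is decided by the sign of
(v − nearest receptor vertex) · n_r(v): negative means below the local
surface plane. The score rewards large, apposed, anti-aligned surface
patches, punishes interpenetration, and is exactly zero for separated
surfaces — which grounds the "positive score" convention used by the
ranking stage: a pose with score > 0 touches its partner somewhere without
being dominated by clashes.

Score parameters (`score_params()`): `contact_distance` 1.4 Å (half a water
diameter — two surfaces closer than this exclude solvent), `clash_depth`
0 Å (any strictly interior vertex counts), `clash_penalty` 2.0 (a clashing
vertex must be outweighed by two perfect contact vertices). The published
score this stands in for is not reproducible from public material; these
parameters are honest stand-ins exposed in one place.

Nearest-vertex queries use a uniform cell grid with an expanding-ring
search. The search is exact: the ring lower bound is
sqrt(d_box² + ((r−1)·cell)²), which is provably conservative (per axis, the
out-of-box offset and the in-grid ring offset add in quadrature at worst),
and scanning stops only when the bound strictly exceeds the best distance,
so equidistant vertices are still compared and ties resolve to the lowest
index. A brute-force scan in the test suite pins this. Two exact
optimisations make the 72,000-evaluation budget cheap: a vertex farther than
the contact distance from the receptor's vertex bounding box can neither be
in contact nor inside the closed surface, so it is rejected before any
query; and the receptor index is built once per docking run
(`make_score_function()`).

## The search

### Pose space

A pose has seven nominal coordinates — three translations, a rotation axis,
a rotation angle — constrained by the bilayer: t_z ∈ [−5, 5] Å, the axis
within 0.157 rad (9°) of +z, θ ∈ [0, 2π) periodic. The x/y bounds are
derived from the receptor: [−E/2 − 5, E/2 + 5] where E is the larger of the
receptor's x/y extents, letting the ligand reach any receptor face with a
5 Å margin (the bound rule is overridable through `search_space()`).
Internally the axis is parameterised by precession and azimuth angles so the
spherical-cap constraint becomes a box constraint; `sample_pose()` draws the
axis uniformly on the cap (cos φ uniform), translations uniformly, θ
uniformly. Only θ is treated as periodic (wrapped); all other dimensions are
clamped, matching the geometry and avoiding boundary artifacts in the
rotation angle.

### PSO with kick and reseed

`pso_kar()` runs independent global-best particle swarms (default 3
repetitions × 80 particles × 300 iterations; one evaluation per particle
per iteration, hence exactly 72,000 evaluations regardless of reseeding).
Velocity updates use inertia 0.72 and cognitive/social weights 1.49 —
standard constriction-style values, configurable, since only the swarm
size, iteration count, repetition count and the 4% kick rule are fixed by
the protocol the package implements. Velocities are clamped to one range
per dimension; personal/global bests are chosen on the *penalised* score;
raw scores are logged for every pose so ranking is never influenced by
repulsion penalties.

After each iteration, a particle whose velocity has decayed below 4% of the
range in every dimension is declared converged: its position becomes a
repulsion site, and the particle is resampled uniformly over the full space
with a fresh velocity. Design choices where the protocol is silent, resolved
here: reseeding samples the *full* space (local restarts would defeat the
purpose of escaping explored basins); the reseeded particle's personal best
is *reset* (it refers to an abandoned basin); the repulsion potential is an
isotropic Gaussian in range-normalised coordinates with width 5% of each
range and height 10% of the largest raw-score magnitude seen so far (floored
at 1) — two interpretable knobs, adaptive so the penalty is commensurate
with the objective's scale. Repulsion sites persist across repetitions.
Determinism: all randomness flows from `rng_seed`; identical seeds give
bit-identical traces (asserted in the tests), and the previous RNG state is
restored on exit.

## Ranking

`select_representatives()` keeps poses with raw score > 0. If more than k
(default 300) remain, K-means with k clusters runs on the range-normalised
pose coordinates, with θ embedded as (cos θ, sin θ) so 0 and 2π are
neighbours — eight features in all. K-means details the protocol leaves
open: `stats::kmeans` with 10 restarts, a 300-iteration cap and a fixed
seed; the pose pool is put into a canonical order (score-descending, then
evaluation order) before clustering so the output is invariant to how the
trace was stored, up to documented tie-breaking. Each non-empty cluster is
represented by its *best-scoring* member, not the nearest-to-centroid pose:
the goal is a diverse ensemble ranked by achievable score, and a centroid is
not a pose that was ever evaluated. Empty clusters simply yield fewer
models, with a warning; zero positive poses yield an empty result with a
warning — the documented "docking failed" signal, not an error.

## Assessment

The three CAPRI metrics: f_nat is the fraction of the *reference* complex's
residue–residue contacts (any heavy-atom pair within 5 Å) reproduced by the
model — the CAPRI denominator; the looser reading that divides by the
number of residues in the predicted complex is available behind
`fnat(..., denominator = "model_residues")` but is not the default. Ligand
RMSD superposes model receptor Cα onto reference receptor Cα
(SVD/Kabsch, proper rotations only) and measures ligand Cα RMSD without
further fitting. Interface RMSD selects interface residues on the
*reference* (any heavy atom within 10 Å of the partner), then superposes
interface Cα. Hydrogens are ignored throughout so models and hydrogen-free
crystal references are treated symmetrically. Residue correspondence is by
(chain, residue number) and mismatches are hard errors — silent
intersection would corrupt RMSD comparability. Degenerate inputs (fewer
than 3 points, collinear point sets, contact-free references, empty
interfaces) raise typed errors rather than returning numbers.

The tier ladder is applied in order, incorrect first:

* incorrect: f_nat < 0.1, or (RMSD > 10 and iRMSD > 4);
* otherwise the best of high / intermediate / acceptable whose condition
  holds, with the grouped inequalities bracketed the CAPRI way (e.g. high
  is "(RMSD ≤ 1 or iRMSD ≤ 1) and f_nat ≥ 0.5").

The prose form of these inequalities is ambiguous in AND/OR precedence;
the implementation's bracketing is pinned by an exhaustive truth-table test
over ~10⁴ grid points against an independently coded oracle, which also
verifies that the ladder partitions the metric space and that raising f_nat
alone can never demote a model. Case difficulty uses the same interface
machinery on a bound/unbound pair: Δ < 1 Å easy, 1–2.5 Å medium, > 2.5 Å
difficult.

## What the synthetic fixtures show — and what they do not

`make_toy_dimer()` builds two deterministic dimers from Cα/Cβ pseudo-atoms
spanning z ∈ [−15, 15]: `"ridge_groove"` (block lattices, 3 Å spacing, with
a complementary plus-shaped ridge/groove interface two lattice rows deep)
and `"bundle"` (three pseudo-helical rods leaving a groove that a fourth
rod fills). Both are preoriented, carry a recorded true pose inside the
default search space, and place the bound partners at a closest approach of
2–6 Å with no pair under 1.5 Å. Two geometry choices matter:

* the facing atom planes sit 3.5 Å apart, which with the default density
  model (σ = 1.8 Å, isovalue 0.5) puts the two isosurfaces in kissing
  contact at the true pose — as in a real complex, where the bound pose is
  where molecular surfaces meet;
* the back faces of both partners carry checkerboard stud atoms. Early
  versions had flat backs, and the flat–flat back-to-back contact offered
  more contact area than the grooved interface, so the score preferred a
  wrong pose for some seeds. Real membrane proteins are not flat-faced
  blocks; the studs make only the designed interface a large complementary
  patch.

`make_jitter_ensemble()` emulates only the *amplitude* of thermal
fluctuation: i.i.d. Gaussian displacements per atom per frame. It has no
inter-atom correlation, no collective modes, no side-chain rearrangement and
no solvent. Consequently the end-to-end tests demonstrate that the engine —
maps, surfaces, constrained search, clustering, metrics — recovers a planted
pose whose surfaces genuinely complement each other; they do not demonstrate
docking accuracy on real MD ensembles, conformational-change cases, or the
difficulty spectrum of experimental benchmarks. `plant_decoys()` labels its
perturbed poses with whatever tier the assessment module computes, never
with a priori labels.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run the full search budget (72,000
evaluations) on the ridge_groove dimer with 1.5 Å map spacing and 10-frame
ensembles — about 18,000 voxels and 3,000–4,000 surface vertices per
partner, a couple of minutes on one CPU; the seed-determinism check uses a
smaller swarm (20 × 60 × 2) at 2 Å spacing, since reproducibility does not
depend on budget. Rotation matrices are validated to 1e−8
(orthonormality, unit determinant); rigid-transform round-trips hold to
1e−9 Å; superposition agrees with an independent quaternion-eigenvector
oracle to 1e−9 Å; PDB coordinate round-trips are limited by the format's
0.001 Å precision; OpenDX round-trips hold to 1e−6.

## Known limitations

* The density model ignores electrostatics and correlated dynamics by
  design; the score therefore cannot distinguish interfaces that differ
  only in charge complementarity.
* Rigid-body only: no backbone or side-chain flexibility during search, so
  cases whose bound/unbound interface deformation is large (the "difficult"
  class) are outside what the engine can recover even in principle.
* The isovalue is a free parameter here, not calibrated against solvent
  accessibility as for true influence maps.
* K-means representative selection depends on a clustering seed; results
  are reproducible given (trace, k, seed) but a different seed can select
  different near-tied representatives.
* The search assumes the preorientation contract; structures far from
  z-centred will be warned about but not fixed.
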