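# memdock

Rigid-body docking of transmembrane protein dimers, constrained by the lipid
bilayer and driven by the complementarity of ensemble-derived density
isosurfaces.

## The problem

Most protein–protein docking tools were built for soluble proteins. Membrane
proteins bind under different rules: the bilayer fixes their vertical
placement and orientation, so the binding partner cannot approach from
arbitrary directions, and the lipid-facing transmembrane surface is smooth
and weakly featured, which makes hard-sphere atomic scoring functions
brittle. `memdock` implements a docking engine specialised for this setting,
for structural biologists and method developers who have (or can simulate)
preoriented membrane protein monomers and want ranked models of the dimer.

Both partners must be preoriented in the OPM convention: membrane normal
along **+z**, centre of mass of the transmembrane region at **z = 0**.
`check_preorientation()` verifies this and every pipeline entry point calls
it.

## The method

1. **Density maps.** Each partner is represented not by atoms but by a
   volumetric density field built from a conformational ensemble (e.g. MD
   snapshots, or the package's jittered pseudo-ensembles): a frame-averaged,
   weighted Gaussian kernel density, max-normalised so the peak is 1
   (`build_density_map()`, OpenDX I/O via `read_dx()`/`write_dx()`). The
   field is a documented stand-in for richer spatial-influence maps; every
   downstream stage depends only on having a smooth, normalised scalar
   field.
2. **Isosurfaces.** Maps are converted to triangulated level sets at a
   predetermined cutoff (default 0.5 of the maximum) by marching tetrahedra,
   with outward normals taken from the map gradient
   (`extract_isosurface()`).
3. **Surface-complementarity score.** A ligand pose is scored as

   score(T) = Σ_{v : d(v) ≤ c} max(0, −n_v · n_r(v)) − λ · #{v inside receptor}

   over transformed ligand vertices *v*, where *n_r(v)* is the normal of the
   nearest receptor vertex, *d(v)* the distance to it, *c* the contact
   distance (1.4 Å, half a water diameter) and λ the clash penalty (2.0).
   Apposed, anti-parallel surface patches score high; separated surfaces
   score exactly 0; interpenetration is punished. A pose is *positive* iff
   its score is > 0 (`complementarity_score()`).
4. **Bilayer-constrained 7D search.** A pose is (t_x, t_y, t_z, axis,
   θ): x/y translation limited by the receptor's size, z translation limited
   to ±5 Å, the rotation axis allowed to precess at most 0.157 rad (9°) from
   the membrane normal, θ ∈ [0, 2π). The score is maximised with a
   particle-swarm "kick and reseed" optimiser: 3 repetitions × 80 particles ×
   300 iterations = 72,000 pose evaluations; particles whose velocity decays
   below 4% of the range in every dimension are reseeded and leave Gaussian
   repulsion potentials that persist across repetitions (`pso_kar()`).
5. **Ranking.** The positive-score pose pool is clustered by K-means on the
   range-normalised 7D pose coordinates (θ embedded on the unit circle) into
   300 clusters; each cluster's best-scoring member becomes a ranked model
   (`select_representatives()`, `emit_models()`).
6. **Assessment.** Models are compared against a reference complex with the
   CAPRI metrics — f_nat (fraction of native residue–residue contacts, 5 Å
   heavy-atom cutoff), ligand RMSD (Cα, after receptor superposition) and
   interface RMSD (Cα within 10 Å of the partner) — and classified as
   incorrect / acceptable / intermediate / high (`report_top_n()`,
   `classify_quality()`). Bound/unbound interface deformation classifies
   case difficulty (`classify_difficulty()`).

## Worked example

The package ships a deterministic synthetic benchmark: a "ridge and groove"
toy dimer whose partners are preoriented block lattices with a complementary
plus-shaped ridge/groove interface and a recorded true bound pose.

```r
library(memdock)

dimer <- make_toy_dimer("ridge_groove", seed = 1)
dimer
#> <toy_dimer> style ridge_groove, receptor 261 atoms, ligand 202 atoms
#> <pose> t = (9.32, -0.01, 0.01) A, axis = (0.000, 0.000, 1.000), theta = 0.000 rad

ens_rec <- make_jitter_ensemble(dimer$receptor, sigma = 0.3, n_frames = 10, seed = 2)
ens_lig <- make_jitter_ensemble(dimer$ligand,  sigma = 0.3, n_frames = 10, seed = 3)

run <- dock_pair(dimer$receptor, dimer$ligand, ens_rec, ens_lig,
                 density = density_params(grid_spacing = 1.5),
                 swarm = swarm_config(rng_seed = 1))
run
#> <dock_run>
#>   <search_trace> 72000 evaluations, 850 repulsion sites, best raw score 1058.6924
#>   <docking_result> 300 of 300 requested models
#>   score range: 1058.692 (rank 1) to 100.898

report_top_n(run$result, dimer$receptor, dimer$ligand,
             dimer_reference(dimer), n = 5)
#> <assessment_report> 5 models, best tier: high, first success rank: 1
#> # A tibble: 5 × 5
#>    rank  fnat ligand_rmsd interface_rmsd tier
#>   <int> <dbl>       <dbl>          <dbl> <chr>
#> 1     1 0.997       0.608          0.315 high
#> 2     2 0.992       0.633          0.311 high
#> 3     3 0.992       0.649          0.331 high
#> 4     4 0.997       0.518          0.265 high
#> 5     5 0.997       0.528          0.273 high
```

The search spent its full 72,000-evaluation budget, kept the 300 best-scoring
cluster representatives, and the rank-1 model reproduces essentially all
native contacts (f_nat ≈ 1) with a ligand RMSD of 0.6 Å from the planted
pose — a high-quality prediction at the top of the ranking. The full budget
matters: with a quarter of the evaluations the swarm can settle on the
studded back face of the receptor instead of the true interface.

Results are tibbles throughout: `tidy()`, `glance()` and `autoplot()`
methods are provided for traces, results and assessment reports.

## Command line

A thin subcommand CLI wraps the same functions
(`inst/cli/memdock.R`; resolve via `system.file("cli", "memdock.R", package = "memdock")`):

```sh
Rscript memdock.R fixture --style ridge_groove --seed 1 --outdir fx
Rscript memdock.R map     --input fx/ligand_ens.pdb --output ligand.dx
Rscript memdock.R dock    --receptor fx/receptor_ens.pdb --ligand fx/ligand_ens.pdb \
                          --outdir run1 --seed 1
Rscript memdock.R assess  --models run1 --reference fx/reference.pdb --ligand-chains B
```

Every dock run directory receives the config snapshot, seed, version string,
evaluation trace and ranking table needed to reproduce it bit-for-bit.

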