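# End-to-end docking orchestration: ensembles -> density maps -> isosurfaces
# -> swarm search -> representative selection.

#' Dock a preoriented receptor/ligand pair
#'
#' Runs the full map-based docking pipeline: build (or accept) a density map
#' per partner, extract isosurfaces at the configured cutoff, search the
#' bilayer-constrained pose space with the kick-and-reseed particle swarm,
#' and select ranked representatives from the positive-score pose pool.
#'
#' @param receptor,ligand preoriented `structure_model` objects (membrane
#'   normal +z, TM centre of mass at the origin).
#' @param receptor_ens,ligand_ens optional `ensemble` objects; when `NULL`
#'   the static structure is used as a single frame.
#' @param receptor_map,ligand_map optional precomputed `volumetric_map`s
#'   (e.g. read from OpenDX files); when given they override map building.
#' @param density a [density_params()].
#' @param score a [score_params()].
#' @param swarm a [swarm_config()].
#' @param k number of representative models to request (default 300).
#' @param check_orientation warn when either partner violates the
#'   preorientation convention.
#' @param trace_file optional tab-separated evaluation log path.
#' @return an object of class `dock_run`: list with `result` (a
#'   `docking_result`), `trace` (a `search_trace`), the two maps, the two
#'   surfaces, the `space`, and the configuration.
#' @export
dock_pair <- function(receptor, ligand, receptor_ens = NULL, ligand_ens = NULL,
                      receptor_map = NULL, ligand_map = NULL,
                      density = density_params(), score = score_params(),
                      swarm = swarm_config(), k = 300,
                      check_orientation = TRUE, trace_file = NULL) {
  if (check_orientation) {
    check_preorientation(receptor)
    check_preorientation(ligand)
  }
  if (is.null(receptor_map)) {
    receptor_map <- build_density_map(receptor, receptor_ens, density)
  }
  if (is.null(ligand_map)) {
    ligand_map <- build_density_map(ligand, ligand_ens, density)
  }
  rec_surf <- extract_isosurface(receptor_map, density$isovalue)
  lig_surf <- extract_isosurface(ligand_map, density$isovalue)
  space <- make_search_space(receptor)
  score_fn <- make_score_function(rec_surf, lig_surf, score)
  objective <- function(p) score_fn(pose_to_transform(p))
  trace <- pso_kar(objective, space, swarm, trace_file = trace_file)
  result <- select_representatives(trace, k = k, seed = swarm$rng_seed)
  structure(list(result = result, trace = trace,
                 receptor_map = receptor_map, ligand_map = ligand_map,
                 receptor_surface = rec_surf, ligand_surface = lig_surf,
                 space = space,
                 config = list(density = density, score = score, swarm = swarm,
                               k = k)),
            class = "dock_run")
}

#' @export
print.dock_run <- function(x, ...) {
  cat("<dock_run>\n  ")
  print(x$trace)
  cat("  ")
  print(x$result)
  invisible(x)
}
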