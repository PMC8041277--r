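# Isosurface extraction and the surface-complementarity docking score.
# Docking never touches atoms: the score sees two triangulated level sets of
# the partners' density maps and rewards apposed, anti-aligned surface
# patches while penalising interpenetration.

#' Construct an isosurface object
#'
#' Normally produced by [extract_isosurface()]; the constructor only checks
#' mesh consistency (valid face indices, unit normals), so synthetic surfaces
#' can be built directly in tests.
#'
#' @param vertices N x 3 matrix of vertex positions (Angstrom).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param normals N x 3 matrix of outward unit normals.
#' @param isovalue the map cutoff this surface was extracted at.
#' @return an object of class `iso_surface`.
#' @export
iso_surface <- function(vertices, faces, normals, isovalue = NA_real_) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  normals <- matrix(as.numeric(normals), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(nrow(normals) == nrow(vertices))
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices))) {
    rlang::abort("face indices out of range", class = "memdock_surface_error")
  }
  nl <- sqrt(rowSums(normals^2))
  if (any(abs(nl - 1) > 1e-6)) {
    rlang::abort("normals must be unit length", class = "memdock_surface_error")
  }
  structure(list(vertices = vertices, faces = faces, normals = normals,
                 isovalue = isovalue),
            class = "iso_surface")
}

#' @export
print.iso_surface <- function(x, ...) {
  cat(sprintf("<iso_surface> %d vertices, %d faces, isovalue %.4g, area %.1f A^2\n",
              nrow(x$vertices), nrow(x$faces), x$isovalue, surface_area(x)))
  invisible(x)
}

#' Total triangle area of an isosurface
#' @param surf an `iso_surface`.
#' @return area in Angstrom^2.
#' @export
surface_area <- function(surf) {
  stopifnot(inherits(surf, "iso_surface"))
  if (nrow(surf$faces) == 0) return(0)
  a <- surf$vertices[surf$faces[, 1], , drop = FALSE]
  b <- surf$vertices[surf$faces[, 2], , drop = FALSE]
  c <- surf$vertices[surf$faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Extract the isosurface of a volumetric map
#'
#' Marching-tetrahedra triangulation (6 tetrahedra per voxel cube) of the
#' level set, with vertices refined onto the trilinear interpolant of the
#' map. Normals are taken from the map gradient at each vertex (central
#' differences, trilinearly interpolated) and oriented down-gradient, i.e.
#' away from higher map values, which for a molecular density means outward.
#'
#' @param m a `volumetric_map`.
#' @param isovalue cutoff; must lie strictly between the map minimum and
#'   maximum.
#' @return an `iso_surface` in laboratory Angstrom coordinates.
#' @export
extract_isosurface <- function(m, isovalue) {
  stopifnot(inherits(m, "volumetric_map"))
  rng <- range(m$values)
  if (!(isovalue > rng[1] && isovalue < rng[2])) {
    rlang::abort(sprintf(
      "isovalue %.4g outside the map value range [%.4g, %.4g]",
      isovalue, rng[1], rng[2]), class = "memdock_levelset_error")
  }
  mesh <- marching_tetrahedra_cpp(m$values, m$origin, m$spacing, isovalue)
  V <- mesh$vertices
  if (nrow(V) == 0) {
    rlang::abort("isosurface is empty", class = "memdock_levelset_error")
  }
  g <- map_gradient_at(m, V)
  gl <- sqrt(rowSums(g^2))
  degenerate <- gl < 1e-12
  if (any(degenerate)) {
    # fall back to the direction away from the map centroid
    ctr <- m$origin + m$spacing * (dim(m$values) - 1) / 2
    dir <- sweep(V[degenerate, , drop = FALSE], 2, ctr)
    dl <- pmax(sqrt(rowSums(dir^2)), 1e-12)
    g[degenerate, ] <- -dir / dl
    gl[degenerate] <- 1
  }
  normals <- -g / gl  # down-gradient = outward
  iso_surface(V, mesh$faces, normals, isovalue = isovalue)
}

#' Nearest surface vertex to a query point
#'
#' Exact nearest vertex under Euclidean distance via a uniform cell index;
#' ties are broken by the lowest vertex index.
#'
#' @param surf an `iso_surface`.
#' @param points 3-vector or N x 3 matrix of query points.
#' @return a tibble with columns `index` and `distance` (one row per query).
#' @export
nearest_surface_point <- function(surf, points) {
  stopifnot(inherits(surf, "iso_surface"), nrow(surf$vertices) > 0)
  pts <- matrix(as.numeric(points), ncol = 3)
  res <- nearest_point_cpp(surf$vertices, pts)
  tibble::tibble(index = res$index, distance = res$distance)
}

#' Scoring parameters for surface complementarity
#'
#' @param contact_distance vertices within this distance of the partner
#'   surface count as in contact (Angstrom; default 1.4 A, about half a water
#'   diameter).
#' @param clash_depth a vertex deeper than this inside the partner surface
#'   counts as clashing (default 0: any strictly interior vertex clashes).
#' @param clash_penalty score deducted per clashing vertex.
#' @return an object of class `score_params`.
#' @export
score_params <- function(contact_distance = 1.4, clash_depth = 0.0,
                         clash_penalty = 2.0) {
  stopifnot(contact_distance > 0, clash_penalty >= 0, clash_depth >= 0)
  structure(list(contact_distance = contact_distance, clash_depth = clash_depth,
                 clash_penalty = clash_penalty),
            class = "score_params")
}

#' Surface-complementarity score of a ligand pose
#'
#' The ligand surface is placed by `pose_transform`; every transformed ligand
#' vertex within `contact_distance` of its nearest receptor vertex
#' contributes `max(0, -n_lig . n_rec)` (so apposed, anti-parallel patches
#' score highest), and every vertex strictly inside the receptor surface
#' (negative signed distance along the receptor normal) costs
#' `clash_penalty`. Separated surfaces score exactly 0; a pose is "positive"
#' when its score is greater than 0.
#'
#' @param receptor_surf,ligand_surf `iso_surface` objects.
#' @param pose_transform a `rigid_transform` placing the ligand.
#' @param params a [score_params()] object.
#' @return scalar score (dimensionless; higher is more complementary).
#' @export
complementarity_score <- function(receptor_surf, ligand_surf,
                                  pose_transform = rigid_transform(),
                                  params = score_params()) {
  stopifnot(inherits(receptor_surf, "iso_surface"),
            inherits(ligand_surf, "iso_surface"),
            nrow(receptor_surf$vertices) > 0, nrow(ligand_surf$vertices) > 0)
  idx <- nn_index_build_cpp(receptor_surf$vertices)
  score_pose_cpp(idx, receptor_surf$normals, ligand_surf$vertices,
                 ligand_surf$normals, pose_transform$rotation,
                 pose_transform$translation, pose_transform$center,
                 params$contact_distance, params$clash_penalty,
                 params$clash_depth)
}

#' Build a fast pose-scoring closure for a fixed surface pair
#'
#' Prebuilds the receptor spatial index once, so the particle-swarm search
#' can evaluate tens of thousands of poses cheaply. The returned function
#' maps a `rigid_transform` to the same value as [complementarity_score()].
#'
#' @inheritParams complementarity_score
#' @return function(`rigid_transform`) -> score.
#' @export
make_score_function <- function(receptor_surf, ligand_surf,
                                params = score_params()) {
  stopifnot(inherits(receptor_surf, "iso_surface"),
            inherits(ligand_surf, "iso_surface"))
  idx <- nn_index_build_cpp(receptor_surf$vertices)
  recN <- receptor_surf$normals
  ligV <- ligand_surf$vertices
  ligN <- ligand_surf$normals
  force(params)
  function(pose_transform) {
    score_pose_cpp(idx, recN, ligV, ligN, pose_transform$rotation,
                   pose_transform$translation, pose_transform$center,
                   params$contact_distance, params$clash_penalty,
                   params$clash_depth)
  }
}

#' Dump an isosurface as Wavefront OBJ (for visual inspection)
#' @param surf an `iso_surface`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(surf, path) {
  stopifnot(inherits(surf, "iso_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", surf$vertices[, 1], surf$vertices[, 2],
                     surf$vertices[, 3]), con)
  writeLines(sprintf("vn %.6f %.6f %.6f", surf$normals[, 1], surf$normals[, 2],
                     surf$normals[, 3]), con)
  if (nrow(surf$faces) > 0) {
    writeLines(sprintf("f %d//%d %d//%d %d//%d",
                       surf$faces[, 1], surf$faces[, 1],
                       surf$faces[, 2], surf$faces[, 2],
                       surf$faces[, 3], surf$faces[, 3]), con)
  }
  invisible(path)
}
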