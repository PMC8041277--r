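#' @useDynLib memdock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Standard atomic masses (Da) for the elements seen in protein PDB files.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  CA = 40.078, "NA" = 22.99, K = 39.098, CL = 35.45, MN = 54.938
)

#' Atomic masses for a vector of element symbols
#'
#' Unknown elements fall back to the mass of carbon with a warning, so that
#' sloppy PDB files do not derail mass-weighted calculations.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in Daltons.
#' @export
element_masses <- function(element) {
  key <- toupper(trimws(element))
  m <- .atomic_masses[key]
  bad <- is.na(m)
  if (any(bad)) {
    warn(sprintf(
      "unknown element(s) %s: using the mass of carbon",
      paste(unique(key[bad]), collapse = ", ")
    ))
    m[bad] <- .atomic_masses[["C"]]
  }
  unname(m)
}

#' Construct a structure model
#'
#' A structure model is the unit that gets docked and assessed: a flat atom
#' table plus an optional transmembrane residue range. Structures are assumed
#' to be preoriented in the OPM convention (membrane normal along +z,
#' transmembrane centre of mass at z = 0); [check_preorientation()] verifies
#' this.
#'
#' @param atoms data frame with columns `chain_id`, `residue_number`,
#'   `residue_name`, `atom_name`, `element`, `x`, `y`, `z` (coordinates in
#'   Angstrom).
#' @param tm_residue_range optional length-2 integer vector giving the first
#'   and last residue number of the transmembrane region. When `NULL`, a
#'   default slab selection (|z| <= 15 A on C-alpha atoms) is used wherever a
#'   transmembrane selection is needed.
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, tm_residue_range = NULL) {
  atoms <- as_tibble(atoms)
  needed <- c("chain_id", "residue_number", "residue_name", "atom_name",
              "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms is missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "memdock_structure_error")
  }
  if (nrow(atoms) == 0) {
    abort("structure has no atoms", class = "memdock_empty_structure_error")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("non-finite coordinates in structure", class = "memdock_structure_error")
  }
  if (!is.null(tm_residue_range)) {
    stopifnot(length(tm_residue_range) == 2)
    tm_residue_range <- as.integer(sort(tm_residue_range))
  }
  structure(
    list(atoms = atoms, tm_residue_range = tm_residue_range),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  n_res <- nrow(dplyr::distinct(x$atoms, .data$chain_id, .data$residue_number))
  cat(sprintf(
    "<structure_model> %d atoms, %d residues, chains: %s\n",
    nrow(x$atoms), n_res, paste(unique(x$atoms$chain_id), collapse = " ")
  ))
  if (!is.null(x$tm_residue_range)) {
    cat(sprintf("  TM residues %d-%d\n", x$tm_residue_range[1], x$tm_residue_range[2]))
  }
  invisible(x)
}

#' Coordinates of a structure model as an N x 3 matrix
#' @param s a `structure_model`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  unname(as.matrix(s$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a structure model
#' @param s a `structure_model`.
#' @param xyz N x 3 matrix congruent with `s`.
#' @return `s` with new coordinates.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(inherits(s, "structure_model"), nrow(xyz) == nrow(s$atoms))
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

# Atom-table rows of the transmembrane selection. With an explicit residue
# range, all atoms in that range; otherwise all atoms of residues whose
# C-alpha lies in the slab |z| <= slab_half_width.
tm_selection <- function(s, slab_half_width = 15) {
  a <- s$atoms
  if (!is.null(s$tm_residue_range)) {
    sel <- a$residue_number >= s$tm_residue_range[1] &
      a$residue_number <= s$tm_residue_range[2]
  } else {
    ca <- a$atom_name == "CA" & abs(a$z) <= slab_half_width
    keys <- unique(paste(a$chain_id[ca], a$residue_number[ca]))
    sel <- paste(a$chain_id, a$residue_number) %in% keys
    if (!any(sel)) sel <- abs(a$z) <= slab_half_width  # no CA atoms at all
  }
  if (!any(sel)) {
    abort("no atoms in transmembrane selection", class = "memdock_selection_error")
  }
  which(sel)
}

#' Check the membrane preorientation convention
#'
#' Structures entering the docking pipeline must be preoriented with the
#' membrane normal along +z and the transmembrane-region centre of mass at
#' z = 0 (the OPM convention). This returns the signed z-offset of the
#' transmembrane centre of mass and warns when it exceeds a tolerance.
#'
#' @param s a `structure_model`.
#' @param tolerance_z warn when the absolute offset exceeds this (Angstrom).
#' @param weighting `"mass"` (default) for a mass-weighted centre, or
#'   `"geometric"` for the unweighted mean.
#' @return signed z-offset of the TM centre of mass, in Angstrom.
#' @export
check_preorientation <- function(s, tolerance_z = 3, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  idx <- tm_selection(s)
  z <- s$atoms$z[idx]
  w <- if (weighting == "mass") element_masses(s$atoms$element[idx]) else rep(1, length(z))
  offset <- sum(w * z) / sum(w)
  if (abs(offset) > tolerance_z) {
    warn(sprintf(
      "transmembrane centre of mass is at z = %.2f A (|offset| > %.1f A): structure may not be preoriented",
      offset, tolerance_z
    ))
  }
  offset
}

#' Construct a rigid transform
#'
#' Transformed coordinates are
#' `x' = rotation %*% (x - center) + center + translation`.
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 translation vector (Angstrom).
#' @param center length-3 point about which the rotation is applied.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3, 3)),
            length(translation) == 3, length(center) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    abort("rotation matrix is not orthonormal", class = "memdock_transform_error")
  }
  if (abs(det(rotation) - 1) > 1e-8) {
    abort("rotation matrix must be proper (det = +1)", class = "memdock_transform_error")
  }
  structure(
    list(rotation = rotation, translation = as.numeric(translation),
         center = as.numeric(center)),
    class = "rigid_transform"
  )
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  # x' = R (x - c) + c + d  =>  x = R^T (x' - c) + c - R^T d
  rigid_transform(
    rotation = t(t$rotation),
    translation = -t(t$rotation) %*% t$translation,
    center = t$center
  )
}

#' Apply a rigid transform to coordinates
#' @param xyz N x 3 matrix.
#' @param t a `rigid_transform`.
#' @return transformed N x 3 matrix.
#' @export
transform_coords <- function(xyz, t) {
  stopifnot(inherits(t, "rigid_transform"))
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, t$center) %*% t(t$rotation), 2,
        t$center + t$translation, "+")
}

#' Apply a rigid transform to a structure model
#' @param s a `structure_model`.
#' @param t a `rigid_transform`.
#' @return the transformed `structure_model` (topology unchanged).
#' @export
apply_transform <- function(s, t) {
  set_coords(s, transform_coords(coords(s), t))
}

# ---- PDB I/O ---------------------------------------------------------------

# Atoms-per-model pre-scan: bio3d silently recycles incongruent multi-model
# files, so congruence is checked on the raw text first.
scan_model_atom_counts <- function(lines) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) return(sum(is_atom))
  ends <- which(startsWith(lines, "ENDMDL"))
  if (length(ends) < length(model_starts)) ends <- c(ends, length(lines))
  vapply(seq_along(model_starts), function(i) {
    sum(is_atom[model_starts[i]:ends[i]])
  }, integer(1))
}

bio3d_to_atoms <- function(atom_df) {
  elesy <- trimws(atom_df$elesy)
  # fall back to the first letter of the atom name when the element column is blank
  blank <- is.na(elesy) | elesy == ""
  if (any(blank)) {
    elesy[blank] <- substr(gsub("[0-9]", "", trimws(atom_df$elety[blank])), 1, 1)
  }
  chain <- atom_df$chain
  chain[is.na(chain) | chain == ""] <- "A"
  tibble(
    chain_id = chain,
    residue_number = as.integer(atom_df$resno),
    residue_name = trimws(atom_df$resid),
    atom_name = trimws(atom_df$elety),
    element = elesy,
    x = atom_df$x, y = atom_df$y, z = atom_df$z
  )
}

#' Read a PDB file into a structure model
#'
#' Reads fixed-column PDB ATOM records. Multi-model files yield the first
#' model only; use [read_ensemble()] to ingest all models as frames.
#'
#' @param path path to a PDB file.
#' @param protein_only drop HETATM records (default `TRUE`).
#' @param tm_residue_range optional TM residue range forwarded to
#'   [structure_model()].
#' @return a `structure_model`.
#' @export
read_pdb <- function(path, protein_only = TRUE, tm_residue_range = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot read PDB file: ", path), class = "memdock_io_error")
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse PDB file ", path, ": ",
                                     conditionMessage(e)),
                              class = "memdock_io_error")
  )
  atom <- pdb$atom
  if (protein_only) atom <- atom[atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0) {
    abort(paste0("no atoms after filtering in ", path,
                 if (protein_only) " (HETATM records are dropped by default)" else ""),
          class = "memdock_empty_structure_error")
  }
  # multi = FALSE still concatenates coordinates of later models in some
  # dialects; restrict to the first model's atom rows
  structure_model(bio3d_to_atoms(atom), tm_residue_range = tm_residue_range)
}

#' Read a multi-model PDB file as a conformational ensemble
#'
#' Each MODEL block becomes one frame; the topology is taken from the first
#' model. Ensembles stand in for snapshots of a molecular-dynamics production
#' run (for the real pipeline, frames saved every few picoseconds).
#'
#' @param path path to a multi-model PDB file.
#' @param frame_interval time between frames in picoseconds (metadata only).
#' @param protein_only drop HETATM records (default `TRUE`).
#' @return list with `topology` (a `structure_model`) and `ensemble` (class
#'   `ensemble`: list of N x 3 coordinate matrices plus `frame_interval`).
#' @export
read_ensemble <- function(path, frame_interval = 5, protein_only = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("cannot read PDB file: ", path), class = "memdock_io_error")
  }
  counts <- scan_model_atom_counts(readLines(path, warn = FALSE))
  if (length(counts) == 0 || sum(counts) == 0) {
    abort(paste0("no atoms in ", path), class = "memdock_empty_structure_error")
  }
  if (length(unique(counts)) > 1) {
    abort(sprintf("models in %s have differing atom counts (%s)",
                  path, paste(counts, collapse = ", ")),
          class = "memdock_congruence_error")
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse PDB file ", path, ": ",
                                     conditionMessage(e)),
                              class = "memdock_io_error")
  )
  atom <- pdb$atom
  keep <- if (protein_only) atom$type == "ATOM" else rep(TRUE, nrow(atom))
  if (!any(keep)) {
    abort(paste0("no atoms after filtering in ", path),
          class = "memdock_empty_structure_error")
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    m[keep, , drop = FALSE]
  })
  topology <- structure_model(bio3d_to_atoms(atom[keep, , drop = FALSE]))
  topology <- set_coords(topology, frames[[1]])
  list(topology = topology, ensemble = new_ensemble(frames, frame_interval))
}

#' Construct an ensemble from a list of coordinate frames
#' @param frames list of congruent N x 3 coordinate matrices.
#' @param frame_interval time between frames in ps (metadata only).
#' @return an object of class `ensemble`.
#' @export
new_ensemble <- function(frames, frame_interval = 5) {
  stopifnot(length(frames) >= 1)
  n <- vapply(frames, nrow, integer(1))
  if (length(unique(n)) > 1) {
    abort("ensemble frames have differing atom counts",
          class = "memdock_congruence_error")
  }
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames x %d atoms (frame interval %g ps)\n",
              length(x$frames), nrow(x$frames[[1]]), x$frame_interval))
  invisible(x)
}

#' Write a docked receptor/ligand pair to a single PDB file
#'
#' Ligand chains colliding with receptor chain ids are relabelled (with a
#' warning) so the two partners stay distinguishable.
#'
#' @param receptor,ligand `structure_model` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(receptor, ligand, path) {
  stopifnot(inherits(receptor, "structure_model"), inherits(ligand, "structure_model"))
  rc <- unique(receptor$atoms$chain_id)
  lig <- ligand
  if (any(unique(lig$atoms$chain_id) %in% rc)) {
    pool <- setdiff(c(LETTERS, letters, as.character(0:9)), rc)
    old <- unique(lig$atoms$chain_id)
    if (length(pool) < length(old)) {
      abort("cannot relabel ligand chains: chain id pool exhausted",
            class = "memdock_io_error")
    }
    map <- stats::setNames(pool[seq_along(old)], old)
    warn(sprintf("ligand chain id(s) %s collide with receptor; relabelled to %s",
                 paste(old, collapse = ","), paste(map, collapse = ",")))
    lig$atoms$chain_id <- unname(map[lig$atoms$chain_id])
  }
  atoms <- dplyr::bind_rows(receptor$atoms, lig$atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(abs(xyz) >= 1e4)) {
    abort("coordinates exceed the PDB fixed-width field range (|x| >= 10^4 A)",
          class = "memdock_format_error")
  }
  ok <- tryCatch({
    suppressWarnings(bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(xyz)),
      resno = atoms$residue_number,
      resid = atoms$residue_name,
      eleno = seq_len(nrow(atoms)),
      elety = atoms$atom_name,
      chain = atoms$chain_id,
      elesy = atoms$element
    ))
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    abort(paste0("failed to write PDB file: ", path), class = "memdock_io_error")
  }
  invisible(path)
}

#' Write a structure (optionally with extra frames) as a (multi-model) PDB
#'
#' @param s a `structure_model` providing the topology.
#' @param path output path.
#' @param ensemble optional `ensemble`; when given, one MODEL block per frame.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, ensemble = NULL) {
  stopifnot(inherits(s, "structure_model"))
  a <- s$atoms
  frames <- if (is.null(ensemble)) list(coords(s)) else ensemble$frames
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (i in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    xyz <- frames[[i]]
    if (any(abs(xyz) >= 1e4)) {
      abort("coordinates exceed the PDB fixed-width field range",
            class = "memdock_format_error")
    }
    lines <- sprintf(
      "ATOM  %5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)) %% 100000,
      ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
      a$residue_name, a$chain_id, a$residue_number,
      xyz[, 1], xyz[, 2], xyz[, 3], a$element
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
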