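# Volumetric density maps built from conformational ensembles, plus OpenDX
# grid I/O and trilinear sampling. The density model is a frame-averaged,
# weighted Gaussian kernel density, max-normalised so the map maximum is 1;
# it is deliberately a pluggable stand-in for richer influence-density maps
# (see the methods vignette) and everything downstream depends only on having
# a smooth, ensemble-derived, normalised scalar field.

#' Density map parameters
#'
#' @param grid_spacing voxel edge length in Angstrom.
#' @param kernel_sigma Gaussian kernel width in Angstrom. The default (1.8 A)
#'   is on the order of a heavy-atom van der Waals radius, so single atoms
#'   blur into a molecular envelope rather than a point cloud.
#' @param atom_weighting `"uniform"` (every atom weight 1) or `"mass"`
#'   (weight = atomic mass in Da).
#' @param padding grid margin beyond the ensemble bounding box, in Angstrom.
#' @param isovalue default map-intensity cutoff used when extracting the
#'   molecular isosurface from a max-normalised map; must be in (0, 1).
#' @return an object of class `density_params`.
#' @export
density_params <- function(grid_spacing = 1.0, kernel_sigma = 1.8,
                           atom_weighting = c("uniform", "mass"),
                           padding = 8.0, isovalue = 0.5) {
  atom_weighting <- match.arg(atom_weighting)
  stopifnot(grid_spacing > 0, kernel_sigma > 0, padding > 0,
            isovalue > 0, isovalue < 1)
  structure(list(grid_spacing = grid_spacing, kernel_sigma = kernel_sigma,
                 atom_weighting = atom_weighting, padding = padding,
                 isovalue = isovalue),
            class = "density_params")
}

#' Construct a volumetric map
#'
#' @param values 3D numeric array of non-negative intensities.
#' @param origin coordinates (Angstrom) of the centre of voxel \[1,1,1\].
#' @param spacing voxel edge length in Angstrom (cubic voxels).
#' @return an object of class `volumetric_map`.
#' @export
volumetric_map <- function(values, origin, spacing) {
  stopifnot(length(dim(values)) == 3, length(origin) == 3, spacing > 0)
  if (any(dim(values) < 2)) {
    rlang::abort("map must have at least 2 voxels along each axis",
                 class = "memdock_map_error")
  }
  if (!all(is.finite(values)) || any(values < 0)) {
    rlang::abort("map values must be finite and non-negative",
                 class = "memdock_map_error")
  }
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "volumetric_map")
}

#' @export
print.volumetric_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<volumetric_map> %d x %d x %d voxels, spacing %g A, origin (%.2f, %.2f, %.2f), max %.4g\n",
    d[1], d[2], d[3], x$spacing, x$origin[1], x$origin[2], x$origin[3], max(x$values)
  ))
  invisible(x)
}

#' Build a density map from a conformational ensemble
#'
#' Each frame deposits a truncated isotropic Gaussian per atom (separable in
#' x/y/z, cut at 4 sigma); frames are averaged and the map divided by its
#' maximum so the peak value is 1. The grid spans the ensemble bounding box
#' plus `padding` on each side, with axes fixed to the laboratory frame (the
#' membrane frame is already set by preorientation).
#'
#' @param topology a `structure_model` congruent with the ensemble.
#' @param ens an `ensemble` (or `NULL` to use the topology's own coordinates
#'   as a single frame).
#' @param params a [density_params()] object.
#' @return a `volumetric_map`. The attribute `"raw_max"` stores the
#'   pre-normalisation maximum so the raw field can be recovered, and
#'   `"total_weight"` the summed atom weight per frame.
#' @export
build_density_map <- function(topology, ens = NULL, params = density_params()) {
  stopifnot(inherits(topology, "structure_model"))
  if (is.null(ens)) ens <- new_ensemble(list(coords(topology)), frame_interval = 0)
  stopifnot(inherits(ens, "ensemble"))
  if (length(ens$frames) == 0) {
    rlang::abort("empty ensemble", class = "memdock_congruence_error")
  }
  if (nrow(ens$frames[[1]]) != nrow(topology$atoms)) {
    rlang::abort("ensemble is not congruent with topology",
                 class = "memdock_congruence_error")
  }
  w <- switch(params$atom_weighting,
              uniform = rep(1, nrow(topology$atoms)),
              mass = element_masses(topology$atoms$element))
  all_xyz <- do.call(rbind, ens$frames)
  lo <- apply(all_xyz, 2, min) - params$padding
  hi <- apply(all_xyz, 2, max) + params$padding
  h <- params$grid_spacing
  n <- pmax(2L, as.integer(ceiling((hi - lo) / h)) + 1L)
  ax <- lapply(1:3, function(k) lo[k] + h * (seq_len(n[k]) - 1))
  vals <- array(0, dim = n)
  sig <- params$kernel_sigma
  cut <- 4 * sig
  norm3 <- (2 * pi * sig^2)^(-3 / 2)
  for (fr in ens$frames) {
    for (a in seq_len(nrow(fr))) {
      p <- fr[a, ]
      ix <- which(abs(ax[[1]] - p[1]) <= cut)
      iy <- which(abs(ax[[2]] - p[2]) <= cut)
      iz <- which(abs(ax[[3]] - p[3]) <= cut)
      if (!length(ix) || !length(iy) || !length(iz)) next
      gx <- exp(-(ax[[1]][ix] - p[1])^2 / (2 * sig^2))
      gy <- exp(-(ax[[2]][iy] - p[2])^2 / (2 * sig^2))
      gz <- exp(-(ax[[3]][iz] - p[3])^2 / (2 * sig^2))
      vals[ix, iy, iz] <- vals[ix, iy, iz] +
        (w[a] * norm3) * (gx %o% gy %o% gz)
    }
  }
  vals <- vals / length(ens$frames)
  raw_max <- max(vals)
  if (raw_max <= 0) {
    rlang::abort("density map is identically zero", class = "memdock_map_error")
  }
  m <- volumetric_map(vals / raw_max, origin = lo, spacing = h)
  attr(m, "raw_max") <- raw_max
  attr(m, "total_weight") <- sum(w)
  m
}

#' Sample a map by trilinear interpolation
#'
#' @param m a `volumetric_map`.
#' @param points 3-vector or N x 3 matrix of query points (Angstrom).
#' @return numeric vector of interpolated intensities; 0 outside the grid.
#' @export
map_value_at <- function(m, points) {
  stopifnot(inherits(m, "volumetric_map"))
  pts <- matrix(as.numeric(points), ncol = 3)
  trilinear_cpp(m$values, m$origin, m$spacing, pts)
}

#' Map gradient by central differences plus trilinear interpolation
#' @param m a `volumetric_map`.
#' @param points 3-vector or N x 3 matrix.
#' @return N x 3 matrix of gradient vectors (intensity per Angstrom).
#' @export
map_gradient_at <- function(m, points) {
  stopifnot(inherits(m, "volumetric_map"))
  pts <- matrix(as.numeric(points), ncol = 3)
  gradient_cpp(m$values, m$origin, m$spacing, pts)
}

# ---- OpenDX I/O ------------------------------------------------------------
# Supported dialect: "object 1" regular positions with one positive uniform
# delta per axis (cubic voxels), "object 2" gridconnections, "object 3" a
# float array in x-fastest-last C order (z fastest), as written by common
# molecular map tools.

#' Write a map in OpenDX general-array format
#' @param m a `volumetric_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(m, path) {
  stopifnot(inherits(m, "volumetric_map"))
  d <- dim(m$values)
  con <- tryCatch(file(path, "w"),
                  error = function(e) rlang::abort(
                    paste0("cannot open ", path, " for writing"),
                    class = "memdock_io_error"))
  on.exit(close(con))
  writeLines(c(
    "# OpenDX density map written by memdock",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", m$origin[1], m$origin[2], m$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", m$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", m$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", m$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(d))
  ), con)
  # z fastest (C order over [x][y][z]): aperm so R's column-major flattening
  # emits the DX ordering
  flat <- as.numeric(aperm(m$values, c(3, 2, 1)))
  idx <- seq(1, length(flat), by = 3)
  lines <- vapply(idx, function(i) {
    paste(sprintf("%.6e", flat[i:min(i + 2, length(flat))]), collapse = " ")
  }, character(1))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Read a map from OpenDX general-array format
#' @param path path to a `.dx` file.
#' @return a `volumetric_map`.
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("cannot read DX file: ", path), class = "memdock_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    rlang::abort("empty DX file", class = "memdock_parse_error")
  }
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  gp <- grep("gridpositions", lines, value = TRUE)
  if (length(gp) == 0) {
    rlang::abort("not an OpenDX grid file (no gridpositions object)",
                 class = "memdock_parse_error")
  }
  counts <- as.integer(utils::tail(num(sub(".*counts", "", gp[1])), 3))
  oline <- grep("^\\s*origin", lines, value = TRUE)
  if (length(oline) == 0) rlang::abort("DX file lacks an origin line",
                                       class = "memdock_parse_error")
  origin <- num(sub("origin", "", oline[1]))
  dlines <- grep("^\\s*delta", lines, value = TRUE)
  if (length(dlines) != 3) rlang::abort("DX file must have three delta lines",
                                        class = "memdock_parse_error")
  deltas <- t(vapply(dlines, function(l) num(sub("delta", "", l)), numeric(3)))
  diagd <- diag(deltas)
  offdiag <- deltas; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-9) || diff(range(diagd)) > 1e-9 * max(diagd) ||
      any(diagd <= 0)) {
    rlang::abort("unsupported DX dialect: grid deltas must be uniform, axis-aligned and positive",
                 class = "memdock_dialect_error")
  }
  data_start <- grep("data follows", lines)
  if (length(data_start) == 0) rlang::abort("DX file lacks a data section",
                                            class = "memdock_parse_error")
  body <- lines[(data_start[1] + 1):length(lines)]
  body <- body[!grepl("^(attribute|object|component|end)", trimws(body))]
  flat <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  flat <- flat[!is.na(flat)]
  if (length(flat) != prod(counts)) {
    rlang::abort(sprintf("DX data section has %d values, expected %d",
                         length(flat), prod(counts)),
                 class = "memdock_parse_error")
  }
  vals <- aperm(array(flat, dim = rev(counts)), c(3, 2, 1))
  volumetric_map(vals, origin = origin, spacing = diagd[1])
}
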