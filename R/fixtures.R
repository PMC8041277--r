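# Deterministic synthetic toy dimers and jittered pseudo-MD ensembles. These
# stand in for preoriented benchmark structures and their dynamics: both
# partners are built from C-alpha/C-beta pseudo-atoms spanning the membrane
# slab (z in [-15, 15]), preoriented with their transmembrane centre of mass
# at the origin, and carry a recorded true bound pose inside the default
# bilayer-constrained search space.

atoms_from_xyz <- function(xyz, chain_id, atom_name = "CA") {
  n <- nrow(xyz)
  tibble::tibble(
    chain_id = chain_id,
    residue_number = seq_len(n),
    residue_name = "GLY",
    atom_name = if (length(atom_name) == 1) rep(atom_name, n) else atom_name,
    element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

# closest heavy-atom approach between two structures
closest_approach <- function(a, b) {
  sqrt(min(cross_dist2(coords(a), coords(b))))
}

centre_xy_mass <- function(xyz) {
  c(mean(xyz[, 1]), mean(xyz[, 2]), mean(xyz[, 3]))
}

#' Deterministic synthetic toy dimer with a known bound pose
#'
#' Two styles:
#' * `"ridge_groove"`: block-shaped point lattices (3 Angstrom spacing). The
#'   receptor's +x face carries a plus-shaped groove; the ligand carries the
#'   complementary plus-shaped ridge, locking x, y, z and the rotation angle
#'   at the true pose.
#' * `"bundle"`: the receptor is three parallel pseudo-helical C-alpha/C-beta
#'   rods spanning z in \[-15, 15\] arranged to leave a groove; the ligand is
#'   a fourth rod that fits it.
#'
#' Both partners are returned preoriented (TM centre of mass at the origin);
#' `true_pose` maps the ligand into contact (closest approach in \[2, 6\]
#' Angstrom, no pair under 1.5 Angstrom). A small seeded coordinate jitter
#' (sigma 0.1 Angstrom) keeps the lattices from being unrealistically exact.
#'
#' @param style `"ridge_groove"` or `"bundle"`.
#' @param seed integer seed; the dimer is a deterministic function of it.
#' @return an object of class `toy_dimer`: list with `receptor`, `ligand`
#'   (both `structure_model`), `true_pose` (a `pose`), `description`.
#' @export
make_toy_dimer <- function(style = c("ridge_groove", "bundle"), seed = 1L) {
  style <- match.arg(style)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  if (style == "ridge_groove") {
    lat <- function(xs, ys, zs) as.matrix(expand.grid(x = xs, y = ys, z = zs))
    ys <- seq(-9, 9, by = 3)
    zs <- seq(-15, 15, by = 3)
    plus_shape <- function(y, z) (abs(y) < 1e-9 & abs(z) <= 6 + 1e-9) |
      (abs(z) < 1e-9 & abs(y) <= 6 + 1e-9)
    rec <- lat(c(-6, -3, 0), ys, zs)
    rec <- rec[!(abs(rec[, 1]) < 1e-9 & plus_shape(rec[, 2], rec[, 3])), ]
    # checkerboard studs roughen the back faces so only the ridge/groove
    # interface offers a large complementary contact patch
    studs <- function(x0) {
      g <- lat(x0, ys, zs)
      g[((g[, 2] + g[, 3]) / 3) %% 2 == 0, ]
    }
    rec <- rbind(rec, studs(-8))
    # facing atom planes 3.5 A apart: with the default density model the two
    # 0.5-isovalue surfaces sit in kissing contact at the bound pose
    lig_ridge <- lat(0.5, ys, zs)
    lig_ridge <- lig_ridge[plus_shape(lig_ridge[, 2], lig_ridge[, 3]), ]
    lig_body <- lat(c(3.5, 6.5), ys, zs)
    lig_bound <- rbind(lig_ridge, lig_body, studs(8.5))
    desc <- "ridge_groove: complementary plus-shaped ridge/groove block lattices"
  } else {
    rod <- function(centre_xy, phase = 0) {
      z <- seq(-15, 15, by = 1.5)
      ang <- phase + (seq_along(z) - 1) * (100 * pi / 180)
      ca <- cbind(centre_xy[1] + 2.3 * cos(ang), centre_xy[2] + 2.3 * sin(ang), z)
      cb <- cbind(centre_xy[1] + 3.8 * cos(ang), centre_xy[2] + 3.8 * sin(ang), z)
      list(xyz = rbind(ca, cb),
           names = c(rep("CA", nrow(ca)), rep("CB", nrow(cb))))
    }
    angles <- c(90, 210, 330) * pi / 180
    rods <- lapply(seq_along(angles), function(i) {
      rod(6 * c(cos(angles[i]), sin(angles[i])), phase = i)
    })
    rec <- do.call(rbind, lapply(rods, `[[`, "xyz"))
    rec_names <- unlist(lapply(rods, `[[`, "names"))
    lrod <- rod(c(0, 0), phase = 0.5)
    # slide the ligand rod outward along the inter-rod groove direction until
    # the closest approach reaches ~3 A (deterministic construction search)
    u <- c(cos(30 * pi / 180), sin(30 * pi / 180), 0)
    rec_tmp <- structure_model(atoms_from_xyz(rec, "A", rec_names))
    d <- 30
    repeat {
      shifted <- sweep(lrod$xyz, 2, d * u, "+")
      ca <- sqrt(min(cross_dist2(rec, shifted)))
      if (ca <= 3.5 || d <= 0) break
      d <- d - 0.1
    }
    lig_bound <- sweep(lrod$xyz, 2, d * u, "+")
    desc <- "bundle: three-rod pseudo-helical receptor with a groove-filling rod ligand"
  }

  jitter <- function(xyz) xyz + matrix(stats::rnorm(length(xyz), sd = 0.1),
                                       ncol = 3)
  rec <- jitter(rec)
  lig_bound <- jitter(lig_bound)
  # preorient the receptor (TM centre of mass at the origin) and carry the
  # bound ligand along in the same frame so the complex geometry is kept
  rec_shift <- centre_xy_mass(rec)
  rec <- sweep(rec, 2, rec_shift)
  lig_bound <- sweep(lig_bound, 2, rec_shift)
  ctr <- centre_xy_mass(lig_bound)
  lig0 <- sweep(lig_bound, 2, ctr)

  rec_names <- if (style == "bundle") rec_names else "CA"
  lig_names <- if (style == "bundle") lrod$names else "CA"
  receptor <- structure_model(atoms_from_xyz(rec, "A", rec_names))
  ligand <- structure_model(atoms_from_xyz(lig0, "B", lig_names))
  true_pose <- pose(tx = ctr[1], ty = ctr[2], tz = ctr[3])

  structure(list(receptor = receptor, ligand = ligand, true_pose = true_pose,
                 description = desc, style = style, seed = seed),
            class = "toy_dimer")
}

#' @export
print.toy_dimer <- function(x, ...) {
  cat(sprintf("<toy_dimer> style %s, receptor %d atoms, ligand %d atoms\n",
              x$style, nrow(x$receptor$atoms), nrow(x$ligand$atoms)))
  print(x$true_pose)
  invisible(x)
}

#' Reference (bound) complex of a toy dimer
#' @param dimer a `toy_dimer`.
#' @return a [dimer_complex()] with the ligand in its true pose.
#' @export
dimer_reference <- function(dimer) {
  stopifnot(inherits(dimer, "toy_dimer"))
  dimer_complex(dimer$receptor,
                apply_transform(dimer$ligand, pose_to_transform(dimer$true_pose)))
}

#' Jittered pseudo-MD ensemble of a structure
#'
#' Each frame is the input structure with i.i.d. Gaussian displacement of
#' every atom. This emulates the thermal fluctuation amplitude of an MD
#' production run for map building; it deliberately has no inter-atom
#' correlation or collective motion (see the methods vignette).
#'
#' @param s a `structure_model`.
#' @param sigma per-coordinate displacement standard deviation (Angstrom).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return an `ensemble`.
#' @export
make_jitter_ensemble <- function(s, sigma = 0.3, n_frames = 10, seed = 1L) {
  stopifnot(inherits(s, "structure_model"), sigma >= 0, n_frames >= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  xyz <- coords(s)
  frames <- lapply(seq_len(n_frames), function(i) {
    xyz + matrix(stats::rnorm(length(xyz), sd = sigma), ncol = 3)
  })
  new_ensemble(frames, frame_interval = 5)
}

#' Plant labelled decoy poses around a toy dimer's true pose
#'
#' Emits near-native poses (translational perturbations of the true pose
#' with ascending magnitude) and far decoys (large in-plane rotations and
#' translations), each labelled with the CAPRI tier the assessment module
#' itself computes for it.
#'
#' @param dimer a `toy_dimer`.
#' @param n total number of decoys (at least 2; roughly half near, half far).
#' @param seed integer seed.
#' @return tibble with columns `kind`, `magnitude` (Angstrom), `pose`
#'   (list-column of `pose` objects), `fnat`, `ligand_rmsd`,
#'   `interface_rmsd`, `tier`.
#' @export
plant_decoys <- function(dimer, n = 10, seed = 1L) {
  stopifnot(inherits(dimer, "toy_dimer"), n >= 2)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  n_near <- ceiling(n / 2)
  n_far <- n - n_near
  tp <- dimer$true_pose
  reference <- dimer_reference(dimer)

  dir_ang <- stats::runif(1, 0, 2 * pi)
  near <- lapply(seq_len(n_near), function(i) {
    mag <- (i - 1) * 0.8  # 0, 0.8, 1.6, ... A: first decoy is the true pose
    list(kind = "near", magnitude = mag,
         pose = pose(tx = tp$tx + mag * cos(dir_ang),
                     ty = tp$ty + mag * sin(dir_ang),
                     tz = tp$tz, axis = tp$axis, theta = tp$theta))
  })
  far <- lapply(seq_len(n_far), function(i) {
    ang <- stats::runif(1, 0, 2 * pi)
    mag <- stats::runif(1, 25, 50)
    list(kind = "far", magnitude = mag,
         pose = pose(tx = tp$tx + mag * cos(ang), ty = tp$ty + mag * sin(ang),
                     tz = stats::runif(1, -5, 5), axis = c(0, 0, 1),
                     theta = stats::runif(1, 0, 2 * pi)))
  })
  all <- c(near, far)
  rows <- lapply(all, function(d) {
    posed <- apply_transform(dimer$ligand, pose_to_transform(d$pose))
    model <- dimer_complex(dimer$receptor, posed)
    f <- tryCatch(fnat(model, reference), error = function(e) 0)
    r <- ligand_rmsd(model, reference)
    ir <- interface_rmsd(model, reference)
    tibble::tibble(kind = d$kind, magnitude = d$magnitude,
                   pose = list(d$pose), fnat = f, ligand_rmsd = r,
                   interface_rmsd = ir, tier = classify_quality(f, r, ir))
  })
  dplyr::bind_rows(rows)
}
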