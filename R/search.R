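# Bilayer-constrained 7D pose space and the particle-swarm "kick and reseed"
# optimiser. A pose has three translations, a rotation axis allowed to
# precess only slightly away from the membrane normal (+z), and a rotation
# angle; the swarm maximises the surface-complementarity score, restarting
# converged particles and leaving Gaussian repulsion potentials at their
# convergence sites so later particles avoid already-explored basins.

#' Construct a docking pose
#'
#' @param tx,ty,tz translations in Angstrom.
#' @param axis length-3 rotation-axis direction (will be normalised).
#' @param theta rotation angle in radians, wrapped into \[0, 2pi).
#' @return an object of class `pose`.
#' @export
pose <- function(tx = 0, ty = 0, tz = 0, axis = c(0, 0, 1), theta = 0) {
  axis <- as.numeric(axis)
  l <- sqrt(sum(axis^2))
  if (l < 1e-12) {
    rlang::abort("rotation axis has zero length", class = "memdock_axis_error")
  }
  structure(list(tx = tx, ty = ty, tz = tz, axis = axis / l,
                 theta = theta %% (2 * pi)),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf(
    "<pose> t = (%.2f, %.2f, %.2f) A, axis = (%.3f, %.3f, %.3f), theta = %.3f rad\n",
    x$tx, x$ty, x$tz, x$axis[1], x$axis[2], x$axis[3], x$theta))
  invisible(x)
}

#' Numeric 7-vector of a pose (tx, ty, tz, ax, ay, az, theta)
#' @param p a `pose`.
#' @return named numeric vector of length 7.
#' @export
pose_coords <- function(p) {
  c(tx = p$tx, ty = p$ty, tz = p$tz,
    ax = p$axis[1], ay = p$axis[2], az = p$axis[3], theta = p$theta)
}

#' Convert a pose to a rigid transform
#'
#' The rotation is built from the axis-angle pair (Rodrigues formula) and
#' applied about `rotation_center`; by the preorientation convention both
#' partners have their transmembrane centre of mass at the origin, so the
#' default centre is the origin.
#'
#' @param p a `pose`.
#' @param rotation_center length-3 centre of rotation (Angstrom).
#' @return a `rigid_transform`.
#' @export
pose_to_transform <- function(p, rotation_center = c(0, 0, 0)) {
  stopifnot(inherits(p, "pose"))
  a <- p$axis
  ct <- cos(p$theta)
  st <- sin(p$theta)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  R <- diag(3) * ct + st * K + (1 - ct) * (a %o% a)
  rigid_transform(rotation = R, translation = c(p$tx, p$ty, p$tz),
                  center = rotation_center)
}

#' Construct a bilayer-constrained search space
#'
#' @param tx_bounds,ty_bounds length-2 intervals for x/y translation (A).
#' @param tz_bounds z-translation interval; the ligand may slide only
#'   +-5 Angstrom along the membrane normal by default.
#' @param precession_max maximum tilt of the rotation axis away from +z, in
#'   radians (default 0.157 rad = 9 degrees).
#' @return an object of class `search_space`.
#' @export
search_space <- function(tx_bounds, ty_bounds, tz_bounds = c(-5, 5),
                         precession_max = 0.157) {
  stopifnot(length(tx_bounds) == 2, length(ty_bounds) == 2,
            length(tz_bounds) == 2, diff(tx_bounds) > 0, diff(ty_bounds) > 0,
            diff(tz_bounds) > 0, precession_max >= 0, precession_max <= pi / 2)
  structure(list(tx_bounds = as.numeric(tx_bounds),
                 ty_bounds = as.numeric(ty_bounds),
                 tz_bounds = as.numeric(tz_bounds),
                 precession_max = precession_max,
                 theta_bounds = c(0, 2 * pi)),
            class = "search_space")
}

#' Search space derived from the receptor's extent
#'
#' x/y translation is limited by the size of the receptor: both bounds are
#' `[-E/2 - 5, E/2 + 5]` where `E` is the larger of the receptor's x and y
#' extents, so the ligand can reach any receptor face with a 5 A margin.
#'
#' @param receptor a `structure_model`.
#' @inheritParams search_space
#' @return a `search_space`.
#' @export
make_search_space <- function(receptor, tz_bounds = c(-5, 5),
                              precession_max = 0.157) {
  xyz <- coords(receptor)
  e <- max(diff(range(xyz[, 1])), diff(range(xyz[, 2])))
  b <- c(-e / 2 - 5, e / 2 + 5)
  search_space(b, b, tz_bounds = tz_bounds, precession_max = precession_max)
}

# Internal box parameterisation: (tx, ty, tz, phi, psi, theta) where the
# rotation axis is (sin phi cos psi, sin phi sin psi, cos phi). This keeps
# the precession-cap constraint a box constraint on phi. theta is periodic;
# all other dimensions are clamped.
internal_bounds <- function(space) {
  rbind(tx = space$tx_bounds, ty = space$ty_bounds, tz = space$tz_bounds,
        phi = c(0, space$precession_max), psi = c(0, 2 * pi),
        theta = c(0, 2 * pi))
}

internal_to_pose <- function(x) {
  phi <- x[4]; psi <- x[5]
  pose(tx = x[1], ty = x[2], tz = x[3],
       axis = c(sin(phi) * cos(psi), sin(phi) * sin(psi), cos(phi)),
       theta = x[6])
}

# Uniform sample in the internal box with the axis uniform on the spherical
# cap (cos phi uniform on [cos phi_max, 1]).
sample_internal <- function(space, n = 1) {
  b <- internal_bounds(space)
  m <- matrix(0, n, 6)
  for (k in 1:3) m[, k] <- stats::runif(n, b[k, 1], b[k, 2])
  m[, 4] <- acos(stats::runif(n, cos(space$precession_max), 1))
  m[, 5] <- stats::runif(n, 0, 2 * pi)
  m[, 6] <- stats::runif(n, 0, 2 * pi)
  m
}

#' Draw a random pose from a search space
#'
#' Translations are uniform in their intervals, the rotation axis uniform on
#' the spherical cap within the precession limit of +z, and theta uniform on
#' \[0, 2pi).
#'
#' @param space a `search_space`.
#' @return a `pose`.
#' @export
sample_pose <- function(space) {
  internal_to_pose(drop(sample_internal(space, 1)))
}

#' Swarm configuration for the kick-and-reseed optimiser
#'
#' @param n_particles swarm size per repetition.
#' @param n_iterations iterations per repetition (one evaluation per particle
#'   per iteration, so the default budget is 80 x 300 x 3 = 72,000).
#' @param n_repetitions independent swarm repetitions; repulsion potentials
#'   are retained from one repetition to the next.
#' @param kick_fraction a particle whose velocity falls below this fraction
#'   of the bound range in every dimension is declared converged and
#'   reseeded.
#' @param inertia,cognitive,social standard global-best PSO weights.
#' @param repulsion_height height of the Gaussian repulsion penalty;
#'   `NA` (default) means adaptive: 10% of the largest raw-score magnitude
#'   seen so far, floored at 1.
#' @param repulsion_sigma repulsion width as a fraction of each dimension's
#'   range.
#' @param rng_seed integer seed; identical seeds give bit-identical traces.
#' @return an object of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 80, n_iterations = 300,
                         n_repetitions = 3, kick_fraction = 0.04,
                         inertia = 0.72, cognitive = 1.49, social = 1.49,
                         repulsion_height = NA_real_, repulsion_sigma = 0.05,
                         rng_seed = 1L) {
  stopifnot(n_particles >= 1, n_iterations >= 1, n_repetitions >= 1,
            kick_fraction > 0, kick_fraction < 1, repulsion_sigma > 0)
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 n_repetitions = as.integer(n_repetitions),
                 kick_fraction = kick_fraction, inertia = inertia,
                 cognitive = cognitive, social = social,
                 repulsion_height = repulsion_height,
                 repulsion_sigma = repulsion_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "swarm_config")
}

# A particle counts as converged when its velocity is below kick_fraction of
# the bound range in every dimension (degenerate zero-range dimensions are
# trivially converged).
velocity_converged <- function(V, ranges, kick_fraction) {
  thr <- ifelse(ranges > 0, kick_fraction * ranges, Inf)
  rowSums(abs(V) < rep(thr, each = nrow(V))) == length(ranges)
}

#' Particle-swarm "kick and reseed" pose search
#'
#' Runs `n_repetitions` independent global-best particle swarms of
#' `n_particles` for `n_iterations` each, maximising `objective`. The angle
#' dimension wraps periodically; all other dimensions are clamped at their
#' bounds. After each iteration, particles whose velocity has decayed below
#' `kick_fraction` of the range in every dimension are declared converged: a
#' Gaussian repulsion penalty is dropped at their position (and persists for
#' the rest of the run, across repetitions), and the particle is resampled
#' uniformly with a fresh velocity and a reset personal best. Raw
#' (unpenalised) scores are recorded for every evaluated pose; the penalised
#' score drives the swarm.
#'
#' @param objective function(`pose`) -> finite numeric score to maximise;
#'   must be deterministic.
#' @param space a `search_space`.
#' @param config a [swarm_config()].
#' @param trace_file optional path; when given, every evaluation is appended
#'   as tab-separated text (repetition, iteration, particle, pose, scores).
#' @return an object of class `search_trace` with elements `evaluations`
#'   (tibble: repetition, iteration, particle, tx, ty, tz, ax, ay, az, theta,
#'   raw_score, penalized_score), `repulsion_sites` (matrix in internal
#'   coordinates), `eval_count`, `best_pose`, `best_raw_score`.
#' @export
pso_kar <- function(objective, space, config = swarm_config(),
                    trace_file = NULL) {
  stopifnot(is.function(objective), inherits(space, "search_space"),
            inherits(config, "swarm_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$rng_seed)

  b <- internal_bounds(space)
  ranges <- b[, 2] - b[, 1]
  np <- config$n_particles
  ni <- config$n_iterations
  nr <- config$n_repetitions
  total <- np * ni * nr
  sig <- config$repulsion_sigma

  # evaluation log (preallocated)
  ev <- matrix(NA_real_, total, 12)
  colnames(ev) <- c("repetition", "iteration", "particle", "tx", "ty", "tz",
                    "ax", "ay", "az", "theta", "raw_score", "penalized_score")
  row <- 0L
  sites <- matrix(numeric(0), 0, 6)
  best_abs_raw <- 0
  best_raw <- -Inf
  best_raw_x <- NULL

  con <- if (!is.null(trace_file)) {
    fh <- file(trace_file, "w")
    writeLines(paste(colnames(ev), collapse = "\t"), fh)
    fh
  } else NULL
  if (!is.null(con)) on.exit(close(con), add = TRUE)

  repulsion_at <- function(X) {
    if (nrow(sites) == 0) return(numeric(nrow(X)))
    h <- if (is.na(config$repulsion_height)) {
      max(1, 0.1 * best_abs_raw)
    } else config$repulsion_height
    pen <- numeric(nrow(X))
    for (s in seq_len(nrow(sites))) {
      d <- sweep(X, 2, sites[s, ]) / rep(ranges, each = nrow(X))
      # theta (dim 6) is periodic: wrap the normalised difference
      d[, 6] <- d[, 6] - round(d[, 6])
      pen <- pen + h * exp(-rowSums(d^2) / (2 * sig^2))
    }
    pen
  }

  for (rep_i in seq_len(nr)) {
    X <- sample_internal(space, np)
    V <- matrix(stats::runif(np * 6, -0.25, 0.25), np, 6) *
      rep(ranges, each = np)
    pbest_x <- X
    pbest_v <- rep(-Inf, np)
    gbest_x <- X[1, ]
    gbest_v <- -Inf

    for (it in seq_len(ni)) {
      raw <- numeric(np)
      for (pi in seq_len(np)) {
        p <- internal_to_pose(X[pi, ])
        val <- objective(p)
        if (!is.finite(val)) {
          rlang::abort(
            sprintf("objective returned a non-finite value at pose (%s)",
                    paste(sprintf("%.3f", pose_coords(p)), collapse = ", ")),
            class = "memdock_evaluation_error", pose = p)
        }
        raw[pi] <- val
      }
      best_abs_raw <- max(best_abs_raw, max(abs(raw)))
      pen <- raw - repulsion_at(X)

      r0 <- row + seq_len(np)
      poses7 <- t(apply(X, 1, function(x) pose_coords(internal_to_pose(x))))
      ev[r0, ] <- cbind(rep_i, it, seq_len(np), poses7, raw, pen)
      row <- row + np
      if (!is.null(con)) {
        utils::write.table(ev[r0, , drop = FALSE], con, sep = "\t",
                           row.names = FALSE, col.names = FALSE)
      }
      if (max(raw) > best_raw) {
        k <- which.max(raw)
        best_raw <- raw[k]
        best_raw_x <- X[k, ]
      }

      improved <- pen > pbest_v
      pbest_v[improved] <- pen[improved]
      pbest_x[improved, ] <- X[improved, , drop = FALSE]
      if (max(pen) > gbest_v) {
        gbest_v <- max(pen)
        gbest_x <- X[which.max(pen), ]
      }

      r1 <- matrix(stats::runif(np * 6), np, 6)
      r2 <- matrix(stats::runif(np * 6), np, 6)
      dp <- pbest_x - X
      dg <- sweep(X, 2, gbest_x, function(x, g) g - x)
      # wrap the periodic angle differences to the short way round
      dp[, 6] <- (dp[, 6] + pi) %% (2 * pi) - pi
      dg[, 6] <- (dg[, 6] + pi) %% (2 * pi) - pi
      V <- config$inertia * V + config$cognitive * r1 * dp +
        config$social * r2 * dg
      V <- pmin(pmax(V, -rep(ranges, each = np)), rep(ranges, each = np))
      X <- X + V
      X[, 6] <- X[, 6] %% (2 * pi)
      for (k in 1:5) X[, k] <- pmin(pmax(X[, k], b[k, 1]), b[k, 2])

      kicked <- velocity_converged(V, ranges, config$kick_fraction)
      if (any(kicked)) {
        sites <- rbind(sites, X[kicked, , drop = FALSE])
        nk <- sum(kicked)
        X[kicked, ] <- sample_internal(space, nk)
        V[kicked, ] <- matrix(stats::runif(nk * 6, -0.25, 0.25), nk, 6) *
          rep(ranges, each = nk)
        pbest_v[kicked] <- -Inf  # abandoned basin: forget the personal best
        pbest_x[kicked, ] <- X[kicked, , drop = FALSE]
      }
    }
  }

  structure(list(
    evaluations = tibble::as_tibble(ev),
    repulsion_sites = sites,
    eval_count = row,
    best_pose = internal_to_pose(best_raw_x),
    best_raw_score = best_raw,
    space = space,
    config = config
  ), class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf(
    "<search_trace> %d evaluations, %d repulsion sites, best raw score %.4f\n",
    x$eval_count, nrow(x$repulsion_sites), x$best_raw_score))
  invisible(x)
}
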