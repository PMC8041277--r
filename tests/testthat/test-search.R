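quat_rotate <- function(axis, theta, pts) {
  # quaternion route, independent of the package's Rodrigues matrix
  a <- axis / sqrt(sum(axis^2))
  w <- cos(theta / 2)
  v <- sin(theta / 2) * a
  t(apply(pts, 1, function(p) {
    t2 <- 2 * c(v[2] * p[3] - v[3] * p[2],
                v[3] * p[1] - v[1] * p[3],
                v[1] * p[2] - v[2] * p[1])
    p + w * t2 + c(v[2] * t2[3] - v[3] * t2[2],
                   v[3] * t2[1] - v[1] * t2[3],
                   v[1] * t2[2] - v[2] * t2[1])
  }))
}

test_that("pose transforms match a quaternion rotation oracle", {
  expect_equal(pose_to_transform(pose())$rotation, diag(3))

  half_turn <- pose_to_transform(pose(theta = pi))
  expect_equal(drop(transform_coords(c(1, 0, 0), half_turn)), c(-1, 0, 0))

  set.seed(9)
  pts <- matrix(stats::rnorm(30), ncol = 3)
  for (i in 1:100) {
    ax <- stats::rnorm(3)
    th <- stats::runif(1, 0, 2 * pi)
    p <- pose(tx = stats::rnorm(1), ty = stats::rnorm(1), tz = stats::rnorm(1),
              axis = ax, theta = th)
    got <- transform_coords(pts, pose_to_transform(p))
    want <- sweep(quat_rotate(ax, th, pts), 2, c(p$tx, p$ty, p$tz), "+")
    expect_lt(max(abs(got - want)), 1e-9)
  }

  expect_error(pose(axis = c(0, 0, 0)), class = "memdock_axis_error")
})

test_that("the search space is sized by the receptor with bilayer constraints", {
  rec <- toy_structure(rbind(c(-20, -15, -10), c(20, 15, 10)))
  sp <- make_search_space(rec)
  expect_equal(sp$tx_bounds, c(-25, 25))  # E = 40 (larger of x/y extents)
  expect_equal(sp$ty_bounds, c(-25, 25))
  expect_equal(sp$tz_bounds, c(-5, 5))
  expect_equal(sp$precession_max, 0.157)
  expect_equal(sp$theta_bounds, c(0, 2 * pi))
})

test_that("sampled poses are uniform within the constrained space", {
  sp <- search_space(c(-10, 10), c(-10, 10))
  set.seed(10)
  n <- 1e4
  tz <- numeric(n)
  for (i in seq_len(n)) {
    p <- sample_pose(sp)
    tz[i] <- p$tz
    stopifnot(abs(sum(p$axis^2) - 1) < 1e-9,
              p$theta >= 0, p$theta < 2 * pi,
              acos(min(1, p$axis[3])) <= sp$precession_max + 1e-9,
              p$tx >= -10, p$tx <= 10, p$tz >= -5, p$tz <= 5)
  }
  se <- sd(tz) / sqrt(n)
  expect_lt(abs(mean(tz)), 3 * se)  # symmetric interval: mean ~ 0

  flat <- search_space(c(-10, 10), c(-10, 10), precession_max = 0)
  for (i in 1:50) expect_equal(sample_pose(flat)$axis, c(0, 0, 1))
})

test_that("the kick rule fires exactly when velocity decays in every dimension", {
  ranges <- c(10, 10, 10, 0.157, 2 * pi, 2 * pi)
  v_small <- matrix(0.03 * ranges, nrow = 1)       # 3% everywhere: converged
  v_mixed <- v_small
  v_mixed[1, 2] <- 0.05 * ranges[2]                 # one dimension at 5%: not
  expect_true(memdock:::velocity_converged(v_small, ranges, 0.04))
  expect_false(memdock:::velocity_converged(v_mixed, ranges, 0.04))

  degenerate <- c(10, 10, 10, 0, 2 * pi, 2 * pi)    # zero-range dimension
  expect_true(memdock:::velocity_converged(matrix(0.03 * degenerate, 1),
                                           degenerate, 0.04))
})

test_that("the swarm finds the optimum of a concave bowl and logs every pose", {
  sp <- search_space(c(-10, 10), c(-10, 10))
  bowl <- function(p) {
    -((p$tx - 3)^2 + (p$ty + 2)^2 + (p$tz - 1)^2 + (p$theta - 1)^2) -
      50 * (1 - p$axis[3])
  }
  cfg <- swarm_config(n_particles = 40, n_iterations = 150, n_repetitions = 2,
                      rng_seed = 3)
  tr <- pso_kar(bowl, sp, cfg)
  expect_equal(tr$eval_count, 40 * 150 * 2)
  expect_equal(nrow(tr$evaluations), tr$eval_count)
  expect_gt(tr$best_raw_score, -1e-2)
  expect_equal(c(tr$best_pose$tx, tr$best_pose$ty, tr$best_pose$tz),
               c(3, -2, 1), tolerance = 0.05)

  # every evaluated pose respects the bilayer constraints
  ev <- tr$evaluations
  expect_true(all(ev$tz >= -5 & ev$tz <= 5))
  expect_true(all(ev$tx >= -10 & ev$tx <= 10))
  expect_true(all(acos(pmin(1, ev$az)) <= sp$precession_max + 1e-9))
  expect_true(all(ev$theta >= 0 & ev$theta < 2 * pi))

  # running best raw score is non-decreasing within each repetition
  for (r in 1:2) {
    per_iter <- tapply(ev$raw_score[ev$repetition == r],
                       ev$iteration[ev$repetition == r], max)
    expect_true(all(diff(cummax(per_iter)) >= 0))
  }
})

test_that("identical seeds give bit-identical traces", {
  sp <- search_space(c(-8, 8), c(-8, 8))
  obj <- function(p) -(p$tx^2 + p$ty^2)
  cfg <- swarm_config(n_particles = 15, n_iterations = 40, n_repetitions = 2,
                      rng_seed = 11)
  t1 <- pso_kar(obj, sp, cfg)
  t2 <- pso_kar(obj, sp, cfg)
  expect_identical(t1$evaluations, t2$evaluations)
  expect_identical(t1$repulsion_sites, t2$repulsion_sites)

  t3 <- pso_kar(obj, sp, swarm_config(n_particles = 15, n_iterations = 40,
                                      n_repetitions = 2, rng_seed = 12))
  expect_false(identical(t1$evaluations, t3$evaluations))
})

test_that("converged particles leave repulsion sites that persist across repetitions", {
  sp <- search_space(c(-5, 5), c(-5, 5))
  flat <- function(p) 0  # featureless landscape: swarms settle and get kicked
  cfg <- swarm_config(n_particles = 20, n_iterations = 120, n_repetitions = 2,
                      rng_seed = 4)
  tr <- pso_kar(flat, sp, cfg)
  expect_gt(nrow(tr$repulsion_sites), 0)
  expect_equal(tr$eval_count, 20 * 120 * 2)  # reseeding never changes budget

  ev <- tr$evaluations
  rep2 <- ev[ev$repetition == 2, ]
  # sites dropped in repetition 1 still penalise poses in repetition 2
  expect_true(any(rep2$penalized_score < rep2$raw_score))
})

test_that("non-finite objective values abort with the pose attached", {
  sp <- search_space(c(-5, 5), c(-5, 5))
  bad <- function(p) if (p$tx > 0) NaN else 1
  err <- tryCatch(
    pso_kar(bad, sp, swarm_config(n_particles = 5, n_iterations = 5,
                                  n_repetitions = 1, rng_seed = 1)),
    error = function(e) e)
  expect_s3_class(err, "memdock_evaluation_error")
  expect_s3_class(err$pose, "pose")
})
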