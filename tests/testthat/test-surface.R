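# radially decaying Gaussian field: its isosurface at the value taken at
# radius r0 is a sphere of radius r0, giving analytic area/normal oracles
gaussian_ball_map <- function(sigma = 5, half_extent = 14, spacing = 1,
                              centre = c(0, 0, 0)) {
  ax <- seq(-half_extent, half_extent, by = spacing)
  g1 <- function(x, c0) exp(-(x - c0)^2 / (2 * sigma^2))
  vals <- outer(outer(g1(ax, centre[1]), g1(ax, centre[2])), g1(ax, centre[3]))
  volumetric_map(vals, origin = rep(-half_extent, 3) + centre, spacing = spacing)
}

test_that("the isosurface of a radial field is a sphere with the right area", {
  m <- gaussian_ball_map(sigma = 5)
  iso <- exp(-100 / 50)  # field value at r = 10
  surf <- extract_isosurface(m, iso)
  expect_equal(surface_area(surf), 4 * pi * 100, tolerance = 0.05)

  r <- sqrt(rowSums(surf$vertices^2))
  expect_lt(max(abs(r - 10)), 0.2)

  # normals: unit length, outward (down-gradient = radially out)
  expect_lt(max(abs(sqrt(rowSums(surf$normals^2)) - 1)), 1e-6)
  radial <- surf$vertices / r
  expect_gt(min(rowSums(radial * surf$normals)), 0.9)
})

test_that("every extracted vertex lies on the level set", {
  set.seed(5)
  s <- toy_structure(matrix(stats::runif(45, -5, 5), ncol = 3))
  m <- build_density_map(s, make_jitter_ensemble(s, 0.3, 5, 2))
  for (iso in c(0.2, 0.5, 0.8)) {
    surf <- extract_isosurface(m, iso)
    vals <- map_value_at(m, surf$vertices)
    expect_lt(max(abs(vals - iso)), 0.05 * iso)
  }
  expect_error(extract_isosurface(m, 1.5), class = "memdock_levelset_error")
  expect_error(extract_isosurface(m, -0.1), class = "memdock_levelset_error")
})

test_that("nearest-vertex queries match brute force and break ties low", {
  m <- gaussian_ball_map(sigma = 5)
  surf <- extract_isosurface(m, exp(-2))
  set.seed(6)
  q <- matrix(stats::runif(3000, -14, 14), ncol = 3)
  got <- nearest_surface_point(surf, q)
  oracle <- brute_force_nearest(surf$vertices, q)
  expect_equal(got$index, unname(oracle[, "index"]))
  expect_equal(got$distance, unname(oracle[, "distance"]), tolerance = 1e-12)

  # query exactly at a vertex
  at <- nearest_surface_point(surf, surf$vertices[17, ])
  expect_equal(at$index, 17)
  expect_equal(at$distance, 0)

  # two equidistant vertices: lowest index wins
  pair <- iso_surface(rbind(c(-1, 0, 0), c(1, 0, 0)),
                      matrix(integer(0), 0, 3),
                      rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(nearest_surface_point(pair, c(0, 0, 0))$index, 1)
})

test_that("parallel anti-aligned patches score one per contact vertex", {
  g <- as.matrix(expand.grid(y = 1:10, z = 1:10))
  rec <- iso_surface(cbind(0, g), matrix(integer(0), 0, 3),
                     cbind(1, 0 * g))           # normals +x
  lig <- iso_surface(cbind(1.4, g), matrix(integer(0), 0, 3),
                     cbind(-1, 0 * g))          # normals -x, 1.4 A away
  expect_equal(complementarity_score(rec, lig), 100.0)

  # separated far beyond contact range: exactly zero
  far <- rigid_transform(translation = c(50, 0, 0))
  expect_identical(complementarity_score(rec, lig, far), 0)
})

test_that("a surface strictly inside its partner is pure penalty", {
  m <- gaussian_ball_map(sigma = 5)
  rec <- extract_isosurface(m, exp(-2))        # sphere r = 10
  inner <- rec
  inner$vertices <- rec$vertices * 0.8          # shrunk copy, all inside
  sc <- complementarity_score(rec, inner)
  expect_lte(sc, 0)
  expect_equal(sc, -2 * nrow(inner$vertices))   # every vertex clashes
})

test_that("the score is invariant under a common rigid motion of both surfaces", {
  m1 <- gaussian_ball_map(sigma = 4, half_extent = 12)
  rec <- extract_isosurface(m1, exp(-2))        # sphere r = 8
  m2 <- gaussian_ball_map(sigma = 2, half_extent = 8)
  lig <- extract_isosurface(m2, exp(-2))        # sphere r = 4
  touch <- rigid_transform(translation = c(12.5, 0, 0))  # near kissing
  base <- complementarity_score(rec, lig, touch)
  expect_gt(base, 0)

  set.seed(8)
  R <- random_rotation()
  shift <- c(3, -7, 2)
  move_surf <- function(s) {
    s$vertices <- sweep(s$vertices %*% t(R), 2, shift, "+")
    s$normals <- s$normals %*% t(R)
    s
  }
  # conjugate the pose into the moved frame: T pose T^-1
  conj <- rigid_transform(rotation = R %*% touch$rotation %*% t(R),
                          translation = R %*% touch$translation,
                          center = shift)
  moved <- complementarity_score(move_surf(rec), move_surf(lig), conj)
  expect_equal(moved, base, tolerance = 1e-6)
})

test_that("the score varies continuously along an approach sweep", {
  m1 <- gaussian_ball_map(sigma = 4, half_extent = 12)
  rec <- extract_isosurface(m1, exp(-2))
  m2 <- gaussian_ball_map(sigma = 2, half_extent = 8)
  lig <- extract_isosurface(m2, exp(-2))
  p <- score_params()
  tx <- seq(11.5, 13.5, by = 0.002)
  sc <- vapply(tx, function(t) {
    complementarity_score(rec, lig, rigid_transform(translation = c(t, 0, 0)), p)
  }, numeric(1))
  # per-step change bounded by a handful of vertices crossing the contact or
  # clash boundary (each worth at most 1 + clash_penalty)
  expect_lt(max(abs(diff(sc))), 10 * (1 + p$clash_penalty))
  expect_gt(max(sc), 0)
})

test_that("OBJ dumps contain the full mesh", {
  m <- gaussian_ball_map(sigma = 3, half_extent = 9)
  surf <- extract_isosurface(m, exp(-2))
  f <- tempfile(fileext = ".obj")
  write_obj(surf, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "v ")), nrow(surf$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(surf$faces))
})
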