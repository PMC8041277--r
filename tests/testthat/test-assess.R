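two_residue_complex <- function(gap = 4.9) {
  rec <- toy_structure(rbind(c(0, 0, 0), c(0, 8, 0)), chain = "A")
  lig <- toy_structure(rbind(c(gap, 0, 0), c(gap, 8, 0)), chain = "B")
  dimer_complex(rec, lig)
}

# a larger bound complex for the RMSD metrics: two facing 12-residue sheets
sheet_complex <- function() {
  g <- as.matrix(expand.grid(y = seq(0, 9, 3), z = seq(0, 6, 3)))
  rec <- toy_structure(cbind(0, g), chain = "A")
  lig <- toy_structure(cbind(4.5, g), chain = "B")
  # distant tail residues outside the 10 A interface cutoff
  rec$atoms <- rbind(rec$atoms, within(rec$atoms[1:2, ], {
    residue_number <- residue_number + 100; x <- x - 40
  }))
  dimer_complex(rec, lig)
}

test_that("contacts respect the 5 A heavy-atom threshold", {
  expect_length(native_contacts(two_residue_complex(4.9)), 2)
  expect_length(native_contacts(two_residue_complex(5.1)), 0)
})

test_that("contact sets match an exhaustive O(n^2) scan", {
  set.seed(12)
  rec <- toy_structure(matrix(stats::runif(45, 0, 12), ncol = 3), chain = "A",
                       resno = rep(1:5, each = 3))
  lig <- toy_structure(matrix(stats::runif(45, 3, 15), ncol = 3), chain = "B",
                       resno = rep(1:5, each = 3))
  cx <- dimer_complex(rec, lig)
  expect_equal(native_contacts(cx), brute_force_contacts(rec, lig))
})

test_that("fnat counts recovered native contacts over reference contacts", {
  ref <- two_residue_complex(4.0)
  expect_equal(fnat(ref, ref), 1.0)

  moved <- ref
  moved$ligand <- apply_transform(ref$ligand,
                                  rigid_transform(translation = c(50, 0, 0)))
  expect_equal(fnat(moved, ref), 0.0)

  # reference has contacts A1-B1 and A2-B2; model keeps only the first
  half <- ref
  half$ligand$atoms$y[2] <- 100
  expect_equal(fnat(half, ref), 0.5)

  none <- two_residue_complex(30)
  expect_error(fnat(ref, none), class = "memdock_degenerate_reference_error")
})

test_that("superposition matches the quaternion eigen oracle", {
  set.seed(13)
  base <- matrix(stats::rnorm(150, sd = 5), ncol = 3)
  expect_equal(superpose(base, base)$rmsd, 0, tolerance = 1e-12)
  expect_equal(superpose(base, base)$transform$rotation, diag(3),
               tolerance = 1e-9)

  for (i in 1:50) {
    mob <- matrix(stats::rnorm(150, sd = 5), ncol = 3)
    tar <- mob %*% t(random_rotation()) +
      matrix(stats::rnorm(150, sd = stats::runif(1, 0, 2)), ncol = 3)
    got <- superpose(mob, tar)
    oracle <- quaternion_superpose_oracle(mob, tar)
    expect_lt(abs(got$rmsd - oracle$rmsd), 1e-9)
  }

  rigid <- base %*% t(random_rotation()) + 3
  expect_lt(superpose(base, rigid)$rmsd, 1e-9)

  line <- cbind(1:10, 2 * (1:10), -1:-10 * 0.5)
  expect_error(superpose(line, line),
               class = "memdock_degenerate_superposition_error")
  expect_error(superpose(base[1:2, ], base[1:2, ]),
               class = "memdock_degenerate_superposition_error")
})

test_that("ligand RMSD is measured after receptor superposition only", {
  ref <- sheet_complex()
  expect_equal(ligand_rmsd(ref, ref), 0, tolerance = 1e-12)

  # moving the whole complex rigidly changes nothing
  tr <- rigid_transform(rotation = random_rotation(),
                        translation = c(5, -3, 2))
  moved <- dimer_complex(apply_transform(ref$receptor, tr),
                         apply_transform(ref$ligand, tr))
  expect_lt(ligand_rmsd(moved, ref), 1e-9)

  # pure ligand translation by (3, 4, 0) with the receptor fixed: RMSD 5
  shifted <- ref
  shifted$ligand <- apply_transform(ref$ligand,
                                    rigid_transform(translation = c(3, 4, 0)))
  expect_equal(ligand_rmsd(shifted, ref), 5.0, tolerance = 1e-9)

  bad <- ref
  bad$ligand$atoms$residue_number <- bad$ligand$atoms$residue_number + 1
  expect_error(ligand_rmsd(bad, ref), class = "memdock_correspondence_error")
})

test_that("interface RMSD selects the reference interface and ignores the rest", {
  ref <- sheet_complex()
  expect_equal(interface_rmsd(ref, ref), 0, tolerance = 1e-12)

  # grossly displacing the non-interface tail leaves the interface RMSD at 0
  tails <- ref
  far <- tails$receptor$atoms$residue_number > 100
  tails$receptor$atoms$x[far] <- tails$receptor$atoms$x[far] - 200
  expect_lt(interface_rmsd(tails, ref), 1e-9)

  # jittered interface: agree with a manual selection + quaternion fit
  set.seed(14)
  jit <- ref
  n_lig <- nrow(jit$ligand$atoms)
  jig <- matrix(stats::rnorm(3 * n_lig, sd = 0.8), ncol = 3)
  jit$ligand$atoms$x <- jit$ligand$atoms$x + jig[, 1]
  jit$ligand$atoms$y <- jit$ligand$atoms$y + jig[, 2]
  jit$ligand$atoms$z <- jit$ligand$atoms$z + jig[, 3]
  got <- interface_rmsd(jit, ref)

  iface <- memdock:::interface_residues(ref, 10)
  sel <- function(cx) {
    rbind(
      as.matrix(cx$receptor$atoms[paste(cx$receptor$atoms$chain_id,
                                        cx$receptor$atoms$residue_number,
                                        sep = ":") %in% iface$receptor &
                                    cx$receptor$atoms$atom_name == "CA",
                                  c("x", "y", "z")]),
      as.matrix(cx$ligand$atoms[paste(cx$ligand$atoms$chain_id,
                                      cx$ligand$atoms$residue_number,
                                      sep = ":") %in% iface$ligand &
                                  cx$ligand$atoms$atom_name == "CA",
                                c("x", "y", "z")]))
  }
  oracle <- quaternion_superpose_oracle(sel(jit), sel(ref))$rmsd
  expect_equal(got, oracle, tolerance = 1e-9)

  apart <- two_residue_complex(30)
  expect_error(interface_rmsd(apart, apart),
               class = "memdock_degenerate_reference_error")
})

test_that("quality metrics are invariant under a common rigid motion", {
  ref <- sheet_complex()
  model <- ref
  model$ligand <- apply_transform(ref$ligand,
                                  rigid_transform(translation = c(1.5, 0.5, 0)))
  base <- c(fnat(model, ref), ligand_rmsd(model, ref), interface_rmsd(model, ref))

  tr <- rigid_transform(rotation = random_rotation(), translation = c(-9, 4, 12))
  move <- function(cx) dimer_complex(apply_transform(cx$receptor, tr),
                                     apply_transform(cx$ligand, tr))
  mm <- move(model)
  rr <- move(ref)
  expect_equal(c(fnat(mm, rr), ligand_rmsd(mm, rr), interface_rmsd(mm, rr)),
               base, tolerance = 1e-9)
})

test_that("the CAPRI tier ladder matches an independent truth table", {
  expect_equal(classify_quality(0.05, 2.0, 1.0), "incorrect")
  expect_equal(classify_quality(0.6, 0.9, 0.9), "high")
  expect_equal(classify_quality(0.2, 8.0, 3.5), "acceptable")

  grid <- expand.grid(f = seq(0, 1, 0.05), r = seq(0, 12, 0.5),
                      ir = seq(0, 5, 0.25))
  got <- mapply(classify_quality, grid$f, grid$r, grid$ir)
  want <- mapply(capri_tier_oracle, grid$f, grid$r, grid$ir)
  expect_false(anyNA(want))
  expect_identical(got, want)

  # raising fnat alone can never demote the tier
  lv <- quality_tiers()
  for (r in c(0.5, 3, 7, 11)) {
    for (ir in c(0.5, 1.5, 3, 4.5)) {
      idx <- match(vapply(seq(0, 1, 0.05), classify_quality, "", rmsd = r,
                          irmsd = ir), lv)
      expect_true(all(diff(idx) >= 0))
    }
  }
})

test_that("case difficulty bands follow the interface deformation", {
  ref <- sheet_complex()
  set.seed(15)
  deltas <- vapply(c(0.05, 0.3, 0.8, 1.6, 3.5), function(sig) {
    unbound <- ref
    for (part in c("receptor", "ligand")) {
      n <- nrow(unbound[[part]]$atoms)
      unbound[[part]]$atoms$x <- unbound[[part]]$atoms$x + stats::rnorm(n, sd = sig)
      unbound[[part]]$atoms$y <- unbound[[part]]$atoms$y + stats::rnorm(n, sd = sig)
      unbound[[part]]$atoms$z <- unbound[[part]]$atoms$z + stats::rnorm(n, sd = sig)
    }
    cls <- classify_difficulty(ref, unbound)
    want <- if (cls$delta_interface_rmsd < 1) "easy" else
      if (cls$delta_interface_rmsd <= 2.5) "medium" else "difficult"
    expect_equal(cls$label, want)
    cls$delta_interface_rmsd
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))       # more noise, more deformation
  expect_lt(deltas[1], 1)                   # spans all three bands
  expect_gt(deltas[5], 2.5)
})

test_that("top-n reports find the first successful model", {
  dimer <- make_toy_dimer("ridge_groove", seed = 3)
  ref <- dimer_reference(dimer)
  tp <- dimer$true_pose

  mk_result <- function(poses, scores) {
    m <- do.call(rbind, lapply(poses, pose_coords))
    df <- tibble::as_tibble(as.data.frame(m))
    df$raw_score <- scores
    memdock:::new_docking_result(df, n_requested = length(poses), seed = 1)
  }
  far_pose <- function(ang) pose(tx = tp$tx + 45 * cos(ang),
                                 ty = tp$ty + 45 * sin(ang), tz = 0)

  all_far <- mk_result(lapply(seq(0, 2, length.out = 10), far_pose), 10:1)
  rep_far <- report_top_n(all_far, dimer$receptor, dimer$ligand, ref)
  expect_equal(rep_far$best_tier, "incorrect")
  expect_true(is.na(rep_far$first_success_rank))

  poses <- lapply(seq(0.2, 2.2, length.out = 10), far_pose)
  poses[[5]] <- tp  # plant the exact bound pose at rank 5
  rep_mix <- report_top_n(mk_result(poses, 10:1), dimer$receptor,
                          dimer$ligand, ref)
  expect_equal(rep_mix$first_success_rank, 5)
  expect_equal(rep_mix$reports$tier[5], "high")
  expect_lt(rep_mix$reports$ligand_rmsd[5], 1e-9)
})
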