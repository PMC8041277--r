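# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately implemented by different routes than the package code: brute
# force where the package uses spatial indices, quaternions where it uses
# SVD, direct summation where it uses separable accumulation.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element, record = "ATOM  ") {
  sprintf("%s%5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial,
          ifelse(nchar(name) < 4, paste0(" ", name), name),
          resname, chain, resno, x, y, z, element)
}

write_text_pdb <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  tf
}

# a small structure_model straight from coordinates
toy_structure <- function(xyz, chain = "A", atom_name = "CA", element = "C",
                          resno = seq_len(nrow(xyz))) {
  xyz <- matrix(xyz, ncol = 3)
  structure_model(tibble::tibble(
    chain_id = chain, residue_number = resno, residue_name = "GLY",
    atom_name = atom_name, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Horn's quaternion method for optimal superposition: an eigen route fully
# independent of the package's SVD-based Kabsch implementation.
quaternion_superpose_oracle <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  S <- t(P) %*% Q
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
                2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
                2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
              3, 3)
  fitted <- P %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

# O(n * m) brute-force nearest neighbour with lowest-index tie-break
brute_force_nearest <- function(ref, query) {
  t(apply(matrix(query, ncol = 3), 1, function(q) {
    d <- sqrt(colSums((t(ref) - q)^2))
    i <- which(d == min(d))[1]
    c(index = i, distance = d[i])
  }))
}

# O(n^2) brute-force residue contact scan over all heavy-atom pairs
brute_force_contacts <- function(rec, lig, cutoff = 5.0) {
  ra <- rec$atoms[toupper(rec$atoms$element) != "H", ]
  la <- lig$atoms[toupper(lig$atoms$element) != "H", ]
  out <- character(0)
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (d <= cutoff) {
        out <- c(out, paste0(ra$chain_id[i], ":", ra$residue_number[i], "--",
                             la$chain_id[j], ":", la$residue_number[j]))
      }
    }
  }
  sort(unique(out))
}

# Independently coded CAPRI tier truth table, written as one flat rule list
# (a different code shape than the package's ordered short-circuit ladder).
capri_tier_oracle <- function(f, r, ir) {
  incorrect <- (f < 0.1) || (r > 10 && ir > 4)
  high <- (!incorrect) && f >= 0.5 && (r <= 1 || ir <= 1)
  intermediate <- (!incorrect) && !high &&
    ((f >= 0.3 && f < 0.5 && (r <= 5 || ir <= 2)) ||
       (f >= 0.5 && r > 1 && ir > 1))
  acceptable <- (!incorrect) && !high && !intermediate &&
    ((f >= 0.1 && f < 0.3 && (r <= 10 || ir <= 4)) ||
       (f >= 0.3 && r > 5 && ir > 2))
  if (incorrect) "incorrect" else if (high) "high" else
    if (intermediate) "intermediate" else if (acceptable) "acceptable" else
      NA_character_
}

# cached docking run on the seeded ridge_groove dimer shared by the
# acceptance checks (representative count, constraint soundness, recovery)
.memdock_test_cache <- new.env(parent = emptyenv())

acceptance_dock_run <- function() {
  if (is.null(.memdock_test_cache$run)) {
    d <- make_toy_dimer("ridge_groove", seed = 1)
    .memdock_test_cache$dimer <- d
    .memdock_test_cache$run <- dock_pair(
      d$receptor, d$ligand,
      receptor_ens = make_jitter_ensemble(d$receptor, 0.3, 10, 1),
      ligand_ens = make_jitter_ensemble(d$ligand, 0.3, 10, 2),
      density = density_params(grid_spacing = 1.5),
      swarm = swarm_config(rng_seed = 7))
  }
  list(dimer = .memdock_test_cache$dimer, run = .memdock_test_cache$run)
}
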