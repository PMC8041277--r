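# CAPRI-style model quality assessment: native-contact recovery (fnat),
# ligand RMSD after receptor superposition, interface RMSD, the four-tier
# quality ladder, and the bound/unbound case-difficulty classification.

#' Bundle a receptor/ligand pair as a complex
#' @param receptor,ligand `structure_model` objects.
#' @return a named list of class `dimer_complex`.
#' @export
dimer_complex <- function(receptor, ligand) {
  stopifnot(inherits(receptor, "structure_model"),
            inherits(ligand, "structure_model"))
  structure(list(receptor = receptor, ligand = ligand),
            class = "dimer_complex")
}

residue_key <- function(atoms) paste(atoms$chain_id, atoms$residue_number, sep = ":")

heavy <- function(s) {
  a <- s$atoms
  a[toupper(a$element) != "H", , drop = FALSE]
}

cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
}

#' Residue-residue contacts across a complex interface
#'
#' A contact is any receptor-residue/ligand-residue pair with a heavy-atom
#' pair within `cutoff` Angstrom (hydrogens are ignored so that models and
#' hydrogen-free crystal references are treated symmetrically).
#'
#' @param complex a [dimer_complex()].
#' @param cutoff contact distance in Angstrom (default 5).
#' @return character vector of contact keys
#'   `"rec_chain:resno--lig_chain:resno"` (an unordered set; sorted).
#' @export
native_contacts <- function(complex, cutoff = 5.0) {
  stopifnot(inherits(complex, "dimer_complex"))
  ra <- heavy(complex$receptor)
  la <- heavy(complex$ligand)
  stopifnot(nrow(ra) > 0, nrow(la) > 0)
  d2 <- cross_dist2(as.matrix(ra[, c("x", "y", "z")]),
                    as.matrix(la[, c("x", "y", "z")]))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(character(0))
  sort(unique(paste(residue_key(ra)[hit[, 1]], residue_key(la)[hit[, 2]],
                    sep = "--")))
}

#' Fraction of native contacts reproduced by a model
#'
#' By the CAPRI convention the denominator is the number of contacts in the
#' reference (native) complex. The alternative reading, dividing by the
#' number of residues in the predicted complex, is available via
#' `denominator = "model_residues"`.
#'
#' @param model,reference [dimer_complex()] objects sharing residue
#'   numbering.
#' @param cutoff contact distance in Angstrom.
#' @param denominator `"reference_contacts"` (CAPRI, default) or
#'   `"model_residues"`.
#' @return fnat in \[0, 1\] (may exceed 1 only under `"model_residues"`).
#' @export
fnat <- function(model, reference, cutoff = 5.0,
                 denominator = c("reference_contacts", "model_residues")) {
  denominator <- match.arg(denominator)
  ref_contacts <- native_contacts(reference, cutoff)
  if (length(ref_contacts) == 0) {
    rlang::abort("reference complex has no contacts",
                 class = "memdock_degenerate_reference_error")
  }
  mod_contacts <- native_contacts(model, cutoff)
  common <- length(intersect(mod_contacts, ref_contacts))
  if (denominator == "reference_contacts") {
    common / length(ref_contacts)
  } else {
    n_res <- nrow(unique(rbind(
      model$receptor$atoms[, c("chain_id", "residue_number")],
      model$ligand$atoms[, c("chain_id", "residue_number")])))
    common / n_res
  }
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimising the RMSD between
#' `mobile` and `target` point sets in 1:1 correspondence.
#'
#' @param mobile,target N x 3 matrices, N >= 3, not collinear.
#' @return list with `transform` (a `rigid_transform` taking mobile onto
#'   target) and `rmsd` (the minimised value, Angstrom).
#' @export
superpose <- function(mobile, target) {
  mobile <- matrix(as.numeric(mobile), ncol = 3)
  target <- matrix(as.numeric(target), ncol = 3)
  stopifnot(nrow(mobile) == nrow(target))
  if (nrow(mobile) < 3) {
    rlang::abort("superposition needs at least 3 points",
                 class = "memdock_degenerate_superposition_error")
  }
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  sv_check <- svd(P)$d
  if (sv_check[2] < 1e-9 * max(sv_check[1], 1)) {
    rlang::abort("points are collinear: superposition is degenerate",
                 class = "memdock_degenerate_superposition_error")
  }
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  tr <- rigid_transform(rotation = R, translation = ct - cm, center = cm)
  list(transform = tr, rmsd = rmsd)
}

# C-alpha coordinates of a structure keyed by (chain, residue number);
# residue-set mismatches between model and reference are hard errors.
matched_ca <- function(model_s, ref_s, what = "structure") {
  mc <- model_s$atoms[model_s$atoms$atom_name == "CA", , drop = FALSE]
  rc <- ref_s$atoms[ref_s$atoms$atom_name == "CA", , drop = FALSE]
  mk <- residue_key(mc)
  rk <- residue_key(rc)
  if (length(rk) == 0 || !setequal(mk, rk) || anyDuplicated(mk) ||
      anyDuplicated(rk)) {
    rlang::abort(paste0("C-alpha residue sets of model and reference ", what,
                        " do not correspond"),
                 class = "memdock_correspondence_error")
  }
  list(model = as.matrix(mc[match(rk, mk), c("x", "y", "z")]),
       reference = as.matrix(rc[, c("x", "y", "z")]))
}

#' Ligand RMSD after receptor superposition
#'
#' Superposes the model receptor onto the reference receptor (C-alpha),
#' applies that fit to the whole model, then reports the C-alpha RMSD over
#' the ligand without further fitting.
#'
#' @param model,reference [dimer_complex()] objects sharing residue
#'   numbering.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(model, reference) {
  rec <- matched_ca(model$receptor, reference$receptor, "receptor")
  lig <- matched_ca(model$ligand, reference$ligand, "ligand")
  fit <- superpose(rec$model, rec$reference)
  moved <- transform_coords(lig$model, fit$transform)
  sqrt(mean(rowSums((moved - lig$reference)^2)))
}

# Interface residue keys (receptor side, ligand side) of a complex: residues
# with any heavy atom within cutoff of the binding partner.
interface_residues <- function(complex, cutoff = 10.0) {
  ra <- heavy(complex$receptor)
  la <- heavy(complex$ligand)
  d2 <- cross_dist2(as.matrix(ra[, c("x", "y", "z")]),
                    as.matrix(la[, c("x", "y", "z")]))
  close <- d2 <= cutoff^2
  list(receptor = unique(residue_key(ra)[rowSums(close) > 0]),
       ligand = unique(residue_key(la)[colSums(close) > 0]))
}

#' Interface RMSD
#'
#' Interface residues (any heavy atom within `interface_cutoff` of the
#' partner) are selected on the *reference*; the model's interface C-alphas
#' are then superposed onto the reference's and the minimised RMSD reported.
#'
#' @param model,reference [dimer_complex()] objects sharing residue
#'   numbering.
#' @param interface_cutoff interface selection distance in Angstrom
#'   (default 10).
#' @return RMSD in Angstrom.
#' @export
interface_rmsd <- function(model, reference, interface_cutoff = 10.0) {
  iface <- interface_residues(reference, interface_cutoff)
  if (length(iface$receptor) == 0 && length(iface$ligand) == 0) {
    rlang::abort("reference complex has an empty interface",
                 class = "memdock_degenerate_reference_error")
  }
  pick <- function(s, keys) {
    a <- s$atoms[s$atoms$atom_name == "CA" & residue_key(s$atoms) %in% keys, ,
                 drop = FALSE]
    sm <- s
    sm$atoms <- a
    sm
  }
  mod_ca <- rbind(
    matched_ca(pick(model$receptor, iface$receptor),
               pick(reference$receptor, iface$receptor), "interface")$model,
    matched_ca(pick(model$ligand, iface$ligand),
               pick(reference$ligand, iface$ligand), "interface")$model)
  ref_ca <- rbind(
    matched_ca(pick(model$receptor, iface$receptor),
               pick(reference$receptor, iface$receptor), "interface")$reference,
    matched_ca(pick(model$ligand, iface$ligand),
               pick(reference$ligand, iface$ligand), "interface")$reference)
  superpose(mod_ca, ref_ca)$rmsd
}

#' CAPRI quality tier of a model
#'
#' Tiers are applied in order, starting from incorrect:
#' * incorrect: `fnat < 0.1` OR (`rmsd > 10` AND `irmsd > 4`);
#' * otherwise the best of:
#'   * high: (`rmsd <= 1` OR `irmsd <= 1`) AND `fnat >= 0.5`;
#'   * intermediate: (`rmsd <= 5` OR `irmsd <= 2`) AND `0.3 <= fnat < 0.5`,
#'     OR `fnat >= 0.5` AND `rmsd > 1` AND `irmsd > 1`;
#'   * acceptable: (`rmsd <= 10` OR `irmsd <= 4`) AND `0.1 <= fnat < 0.3`,
#'     OR `fnat >= 0.3` AND `rmsd > 5` AND `irmsd > 2`.
#'
#' @param fnat fraction of native contacts in \[0, 1\].
#' @param rmsd ligand RMSD in Angstrom.
#' @param irmsd interface RMSD in Angstrom.
#' @return one of `"incorrect"`, `"acceptable"`, `"intermediate"`, `"high"`.
#' @export
classify_quality <- function(fnat, rmsd, irmsd) {
  stopifnot(is.finite(fnat), is.finite(rmsd), is.finite(irmsd),
            fnat >= 0, fnat <= 1, rmsd >= 0, irmsd >= 0)
  if (fnat < 0.1 || (rmsd > 10 && irmsd > 4)) return("incorrect")
  if ((rmsd <= 1 || irmsd <= 1) && fnat >= 0.5) return("high")
  if (((rmsd <= 5 || irmsd <= 2) && fnat >= 0.3 && fnat < 0.5) ||
      (fnat >= 0.5 && rmsd > 1 && irmsd > 1)) return("intermediate")
  if (((rmsd <= 10 || irmsd <= 4) && fnat >= 0.1 && fnat < 0.3) ||
      (fnat >= 0.3 && rmsd > 5 && irmsd > 2)) return("acceptable")
  rlang::abort("unclassifiable metric combination")  # unreachable by construction
}

#' Tier levels in increasing quality order
#' @return character vector of the four tiers.
#' @export
quality_tiers <- function() c("incorrect", "acceptable", "intermediate", "high")

#' Full quality report for one model against a reference
#'
#' @param model,reference [dimer_complex()] objects sharing residue
#'   numbering.
#' @param contact_cutoff contact distance for fnat (Angstrom).
#' @param interface_cutoff interface selection distance (Angstrom).
#' @return a one-row tibble: fnat, ligand_rmsd, interface_rmsd, tier.
#' @export
assess_model <- function(model, reference, contact_cutoff = 5.0,
                         interface_cutoff = 10.0) {
  f <- fnat(model, reference, cutoff = contact_cutoff)
  r <- ligand_rmsd(model, reference)
  ir <- interface_rmsd(model, reference, interface_cutoff)
  tibble::tibble(fnat = f, ligand_rmsd = r, interface_rmsd = ir,
                 tier = classify_quality(f, r, ir))
}

#' Case difficulty from bound/unbound interface deformation
#'
#' The interface (selected on the bound complex) of the unbound partners is
#' superposed onto the bound interface; the residual RMSD quantifies binding
#' flexibility. Cases are easy below 1 Angstrom, medium between 1 and
#' 2.5 Angstrom, difficult above 2.5 Angstrom.
#'
#' @param bound,unbound [dimer_complex()] objects sharing residue numbering.
#' @param interface_cutoff interface selection distance (Angstrom).
#' @return list with `delta_interface_rmsd` (Angstrom) and `label`.
#' @export
classify_difficulty <- function(bound, unbound, interface_cutoff = 10.0) {
  delta <- interface_rmsd(unbound, bound, interface_cutoff)
  label <- if (delta < 1.0) "easy" else if (delta <= 2.5) "medium" else "difficult"
  list(delta_interface_rmsd = delta, label = label)
}

#' Assess the top-ranked docking models against a reference complex
#'
#' @param result a `docking_result`.
#' @param receptor,ligand the preoriented input `structure_model`s used for
#'   docking (the ligand in its pre-pose position).
#' @param reference a [dimer_complex()] with the native pose.
#' @param n how many top models to assess (default 10).
#' @param rotation_center pose rotation centre (default origin).
#' @return an object of class `assessment_report`: a list with `reports`
#'   (tibble: rank, fnat, ligand_rmsd, interface_rmsd, tier), `best_tier`,
#'   and `first_success_rank` (lowest rank with tier at least acceptable;
#'   `NA` if none).
#' @export
report_top_n <- function(result, receptor, ligand, reference, n = 10,
                         rotation_center = c(0, 0, 0)) {
  stopifnot(inherits(result, "docking_result"), nrow(result$models) >= 1,
            inherits(reference, "dimer_complex"))
  n <- min(n, nrow(result$models))
  rows <- lapply(seq_len(n), function(r) {
    tr <- pose_to_transform(model_pose(result, r), rotation_center)
    model <- dimer_complex(receptor, apply_transform(ligand, tr))
    cbind(tibble::tibble(rank = r), assess_model(model, reference))
  })
  reports <- tibble::as_tibble(do.call(rbind, rows))
  lv <- quality_tiers()
  tier_i <- match(reports$tier, lv)
  ok <- which(tier_i >= 2)
  structure(list(
    reports = reports,
    best_tier = lv[max(tier_i)],
    first_success_rank = if (length(ok)) reports$rank[min(ok)] else NA_integer_
  ), class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("<assessment_report> %d models, best tier: %s, first success rank: %s\n",
              nrow(x$reports), x$best_tier,
              ifelse(is.na(x$first_success_rank), "none", x$first_success_rank)))
  print(x$reports)
  invisible(x)
}
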