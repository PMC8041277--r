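# Representative selection and model output. The search trace typically
# holds thousands of positive-score poses concentrated in a handful of
# basins; K-means clustering on the pose coordinates picks a diverse set of
# representatives, which are then ranked by raw score.

#' Select ranked representative poses from a search trace
#'
#' Filters the trace to poses with a strictly positive raw score. When more
#' than `k` remain, K-means (k-means++-style via multiple restarts, fixed
#' seed) is run on the range-normalised 7D pose coordinates, with the
#' periodic angle embedded on the unit circle as (cos theta, sin theta); the
#' highest-raw-score member of each non-empty cluster becomes a
#' representative. Representatives are sorted by descending raw score, ties
#' broken by earlier evaluation order.
#'
#' @param trace a `search_trace` (or its `evaluations` tibble).
#' @param k number of representatives to select (default 300).
#' @param seed integer seed for the clustering.
#' @return an object of class `docking_result`: a list with `models` (tibble:
#'   rank, tx, ty, tz, ax, ay, az, theta, raw_score) plus provenance fields.
#'   When no pose scores positive, an empty result is returned with a warning
#'   (the documented "docking failed" signal).
#' @export
select_representatives <- function(trace, k = 300, seed = 1L) {
  ev <- if (inherits(trace, "search_trace")) trace$evaluations else
    tibble::as_tibble(trace)
  stopifnot(k >= 1, nrow(ev) > 0)
  ev$.eval <- seq_len(nrow(ev))
  pos <- ev[ev$raw_score > 0, , drop = FALSE]
  # canonical pool order (score desc, then evaluation order) so the
  # clustering below is independent of how the trace happened to be stored
  pos <- pos[order(-pos$raw_score, pos$.eval), , drop = FALSE]
  pose_cols <- c("tx", "ty", "tz", "ax", "ay", "az", "theta")

  empty <- function() {
    rlang::warn("no poses with a positive score: docking failed")
    new_docking_result(pos[0, c(pose_cols, "raw_score")], k, seed)
  }
  if (nrow(pos) == 0) return(empty())

  if (nrow(pos) > k) {
    feats <- as.matrix(pos[, c("tx", "ty", "tz", "ax", "ay", "az")])
    feats <- cbind(feats, cos(pos$theta), sin(pos$theta))
    # range-normalise each feature to [0, 1]; constant features drop out
    lo <- apply(feats, 2, min)
    rg <- apply(feats, 2, max) - lo
    rg[rg < 1e-12] <- 1
    feats <- sweep(sweep(feats, 2, lo), 2, rg, "/")
    kk <- min(k, nrow(unique(feats)))
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    km <- stats::kmeans(feats, centers = kk, nstart = 10, iter.max = 300)
    # best-scoring member represents each non-empty cluster
    keep <- vapply(seq_len(kk), function(cl) {
      members <- which(km$cluster == cl)
      if (length(members) == 0) return(NA_integer_)
      members[which.max(pos$raw_score[members])]
    }, integer(1))
    keep <- keep[!is.na(keep)]
    if (length(keep) < kk) {
      rlang::warn(sprintf("%d empty cluster(s): returning %d representatives",
                          kk - length(keep), length(keep)))
    }
    pos <- pos[keep, , drop = FALSE]
  }
  ord <- order(-pos$raw_score, pos$.eval)  # ties keep evaluation order
  new_docking_result(pos[ord, c(pose_cols, "raw_score")], k, seed)
}

new_docking_result <- function(models, n_requested, seed) {
  models <- tibble::as_tibble(models)
  models$rank <- seq_len(nrow(models))
  models <- models[, c("rank", setdiff(names(models), "rank"))]
  structure(list(models = models, n_requested = n_requested, seed = seed),
            class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<docking_result> %d of %d requested models\n",
              nrow(x$models), x$n_requested))
  if (nrow(x$models) > 0) {
    cat(sprintf("  score range: %.3f (rank 1) to %.3f\n",
                x$models$raw_score[1], min(x$models$raw_score)))
  }
  invisible(x)
}

#' Pose of the model at a given rank
#' @param result a `docking_result`.
#' @param rank model rank (1 = best).
#' @return a `pose`.
#' @export
model_pose <- function(result, rank = 1) {
  stopifnot(inherits(result, "docking_result"), rank >= 1,
            rank <= nrow(result$models))
  m <- result$models[rank, ]
  pose(tx = m$tx, ty = m$ty, tz = m$tz, axis = c(m$ax, m$ay, m$az),
       theta = m$theta)
}

# Deterministic fixed-format ranking table so identical runs are
# byte-identical on disk.
format_ranking_table <- function(models) {
  header <- paste(c("rank", "tx", "ty", "tz", "ax", "ay", "az", "theta",
                    "raw_score"), collapse = "\t")
  if (nrow(models) == 0) return(header)
  rows <- sprintf("%d\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f",
                  models$rank, models$tx, models$ty, models$tz, models$ax,
                  models$ay, models$az, models$theta, models$raw_score)
  c(header, rows)
}

#' Write ranked model PDBs and the ranking table
#'
#' Applies each model pose to the ligand, writes one receptor+ligand PDB per
#' model (`model_<rank>.pdb`), and a tab-separated ranking table
#' (`ranking.tsv`: rank, pose coordinates, raw score).
#'
#' @param result a `docking_result`.
#' @param receptor,ligand preoriented `structure_model` objects.
#' @param outdir output directory (created if missing).
#' @param rotation_center centre of the pose rotation (default origin, per
#'   the preorientation convention).
#' @return invisible character vector of written file paths (table last).
#' @export
emit_models <- function(result, receptor, ligand, outdir,
                        rotation_center = c(0, 0, 0)) {
  stopifnot(inherits(result, "docking_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (r in seq_len(nrow(result$models))) {
    tr <- pose_to_transform(model_pose(result, r), rotation_center)
    posed <- apply_transform(ligand, tr)
    p <- file.path(outdir, sprintf("model_%03d.pdb", r))
    write_model_pdb(receptor, posed, p)
    paths <- c(paths, p)
  }
  tab <- file.path(outdir, "ranking.tsv")
  writeLines(format_ranking_table(result$models), tab)
  invisible(c(paths, tab))
}
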