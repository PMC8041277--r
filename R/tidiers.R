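# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline labs theme_minimal
#' @export
ggplot2::autoplot

#' @export
tidy.search_trace <- function(x, ...) x$evaluations

#' @export
glance.search_trace <- function(x, ...) {
  tibble::tibble(
    eval_count = x$eval_count,
    n_positive = sum(x$evaluations$raw_score > 0),
    n_repulsion_sites = nrow(x$repulsion_sites),
    best_raw_score = x$best_raw_score
  )
}

#' @export
tidy.docking_result <- function(x, ...) x$models

#' @export
glance.docking_result <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$models),
    n_requested = x$n_requested,
    best_score = if (nrow(x$models)) x$models$raw_score[1] else NA_real_
  )
}

#' @export
tidy.assessment_report <- function(x, ...) x$reports

#' @export
glance.assessment_report <- function(x, ...) {
  tibble::tibble(
    n_assessed = nrow(x$reports),
    best_tier = x$best_tier,
    first_success_rank = x$first_success_rank
  )
}

#' @export
autoplot.search_trace <- function(object, ...) {
  ev <- object$evaluations
  best <- ev |>
    dplyr::group_by(.data$repetition, .data$iteration) |>
    dplyr::summarise(best_raw = max(.data$raw_score), .groups = "drop")
  ggplot(best, aes(x = .data$iteration, y = .data$best_raw,
                   colour = factor(.data$repetition))) +
    geom_line() +
    labs(x = "iteration", y = "best raw score in iteration",
         colour = "repetition",
         title = "Swarm search progress") +
    theme_minimal()
}

#' @export
autoplot.docking_result <- function(object, ...) {
  ggplot(object$models, aes(x = .data$rank, y = .data$raw_score)) +
    geom_point(size = 0.8) +
    labs(x = "model rank", y = "surface-complementarity score",
         title = "Ranked representative models") +
    theme_minimal()
}

#' @export
autoplot.assessment_report <- function(object, ...) {
  ggplot(object$reports, aes(x = .data$rank, y = .data$ligand_rmsd,
                             colour = .data$tier)) +
    geom_point(size = 2) +
    geom_hline(yintercept = c(1, 5, 10), linetype = "dotted") +
    labs(x = "model rank", y = "ligand RMSD (A)",
         title = "Model quality of top-ranked poses") +
    theme_minimal()
}
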