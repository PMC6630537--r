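#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a simulation into its per-tick time course
#'
#' @param x An `inflam_sim`.
#' @param ... Unused.
#' @return The `timecourse` tibble (`t`, `dead_count`, `inflammation_score`,
#'   `pathogen_count`).
#' @export
tidy.inflam_sim <- function(x, ...) x$timecourse

#' One-row summary of a simulation run
#'
#' @param x An `inflam_sim`.
#' @param ... Unused.
#' @return A one-row tibble: strain, peak inflammation score and its tick,
#'   recovery onset tick, final score, total pathogen spawns observed.
#' @export
glance.inflam_sim <- function(x, ...) {
  tc <- x$timecourse
  tibble::tibble(
    strain = x$params$strain,
    amplitude = x$params$amplitude,
    n_steps = x$params$n_steps,
    peak_score = max(tc$inflammation_score),
    peak_tick = tc$t[which.max(tc$inflammation_score)],
    recovery_onset = recovery_onset(tc),
    final_score = tc$inflammation_score[nrow(tc)],
    max_pathogens = max(tc$pathogen_count)
  )
}

#' Tidy a TE network into its edge list
#'
#' @param x A `te_network`.
#' @param ... Unused.
#' @return The edges tibble (`macrophage`, `fibroblast`, `te`).
#' @export
tidy.te_network <- function(x, ...) x$edges

#' One-row summary of a TE network
#'
#' @param x A `te_network`.
#' @param ... Unused.
#' @return A one-row tibble with node/edge counts, density, and the window.
#' @export
glance.te_network <- function(x, ...) {
  n_m <- length(x$m_nodes)
  n_f <- length(x$f_nodes)
  tibble::tibble(
    n_macrophages = n_m,
    n_fibroblasts = n_f,
    n_edges = nrow(x$edges),
    density = if (n_m * n_f > 0) nrow(x$edges) / (n_m * n_f) else NA_real_,
    window_start = x$window_start %||% NA,
    window_end = x$window_end %||% NA
  )
}

#' Tidy per-node centralities
#'
#' @param x A `centrality_result`.
#' @param ... Unused.
#' @return A tibble `node`, `kind`, `centrality`.
#' @export
tidy.centrality_result <- function(x, ...) {
  tibble::tibble(node = x$node, kind = x$kind, centrality = x$centrality)
}

#' One-row centrality summary (Mc, Fc, Fc/Mc, lambda)
#'
#' @param x A `centrality_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.centrality_result <- function(x, ...) {
  tibble::tibble(
    mc = attr(x, "mc"), fc = attr(x, "fc"),
    fc_mc = attr(x, "fc_mc"), lambda = attr(x, "lambda")
  )
}

#' Tidy an experiment into per-trial time courses
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return The `timecourses` tibble.
#' @export
tidy.experiment_result <- function(x, ...) x$timecourses

#' Per-condition experiment summary
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return One row per strain level: peak of the mean score curve and its
#'   tick, recovery onset, final mean score, and the pathogen-SD trend over
#'   the second half of the run (when >= 2 trials).
#' @export
glance.experiment_result <- function(x, ...) {
  x$aggregates |>
    dplyr::group_by(.data$case, .data$strain) |>
    dplyr::summarise(
      peak_score = max(.data$score_mean),
      peak_tick = .data$t[which.max(.data$score_mean)],
      recovery_onset = recovery_onset(.data$score_mean),
      final_score = .data$score_mean[dplyr::n()],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pathogen_sd_trend = if (x$plan$trials >= 2) {
        vapply(.data$strain, function(s)
          as.character(pathogen_sd_trend(x, s)), character(1))
      } else {
        NA_character_
      }
    )
}
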