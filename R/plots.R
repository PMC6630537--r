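#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_segment
#'   facet_wrap labs theme_minimal scale_size_area
NULL

#' Plot an inflammation time course
#'
#' Inflammation score and pathogen count against simulation time for one run.
#'
#' @param object An `inflam_sim` from [simulate_inflammation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inflam_sim <- function(object, ...) {
  tc <- object$timecourse |>
    tidyr::pivot_longer(c("inflammation_score", "pathogen_count"),
                        names_to = "series", values_to = "value")
  ggplot(tc, aes(x = .data$t, y = .data$value)) +
    geom_line() +
    facet_wrap(~series, ncol = 1, scales = "free_y") +
    labs(x = "tick", y = NULL,
         title = sprintf("s = %.2f, A = %g, seed %d",
                         object$params$strain, object$params$amplitude,
                         object$seed)) +
    theme_minimal()
}

#' Plot a TE network
#'
#' Bipartite layout with macrophage nodes on the left column and fibroblast
#' nodes on the right; node size encodes eigenvector centrality when the
#' network has edges.
#'
#' @param object A `te_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.te_network <- function(object, ...) {
  m <- object$m_nodes
  f <- object$f_nodes
  nodes <- tibble::tibble(
    node = c(m, f),
    kind = rep(c("macrophage", "fibroblast"), c(length(m), length(f))),
    x = rep(c(0, 1), c(length(m), length(f))),
    y = c(seq_along(m) / max(1, length(m)), seq_along(f) / max(1, length(f)))
  )
  nodes$centrality <- if (nrow(object$edges) > 0) {
    eigenvector_centrality(object)$centrality
  } else {
    1 / nrow(nodes)
  }
  ed <- object$edges |>
    dplyr::left_join(nodes[nodes$kind == "macrophage", c("node", "x", "y")],
                     by = c(macrophage = "node")) |>
    dplyr::left_join(nodes[nodes$kind == "fibroblast", c("node", "x", "y")],
                     by = c(fibroblast = "node"), suffix = c("", "_f"))
  p <- ggplot(nodes, aes(x = .data$x, y = .data$y))
  if (nrow(ed) > 0) {
    p <- p + geom_segment(data = ed,
                          aes(x = .data$x, y = .data$y,
                              xend = .data$x_f, yend = .data$y_f),
                          colour = "grey70", linewidth = 0.3)
  }
  p +
    geom_point(aes(size = .data$centrality, colour = .data$kind)) +
    scale_size_area(max_size = 8) +
    labs(x = NULL, y = NULL,
         title = sprintf("TE network, %d edges", nrow(object$edges))) +
    theme_minimal()
}

#' Plot the Fc/Mc centrality time course
#'
#' @param timecourse A tibble from [centrality_timecourse()] (or the `fc_mc`
#'   element of an experiment result; curves are grouped by `strain` and
#'   `trial` when those columns are present).
#' @return A ggplot object.
#' @export
plot_fc_mc <- function(timecourse) {
  p <- if (all(c("strain", "trial") %in% names(timecourse))) {
    ggplot(timecourse,
           aes(x = .data$window_start, y = .data$fc_mc,
               group = .data$trial)) +
      geom_line(alpha = 0.6) +
      facet_wrap(~strain, labeller = ggplot2::label_both)
  } else {
    ggplot(timecourse, aes(x = .data$window_start, y = .data$fc_mc)) +
      geom_line()
  }
  p + labs(x = "window start (tick)", y = "Fc / Mc") + theme_minimal()
}

#' Plot experiment-level inflammation curves
#'
#' Mean inflammation score per strain level, with pathogen-count mean and
#' across-trial SD, from an [run_experiment()] result.
#'
#' @param object An `experiment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_result <- function(object, ...) {
  agg <- object$aggregates |>
    tidyr::pivot_longer(c("score_mean", "pathogen_mean", "pathogen_sd"),
                        names_to = "series", values_to = "value")
  ggplot(agg, aes(x = .data$t, y = .data$value,
                  colour = factor(.data$strain))) +
    geom_line() +
    facet_wrap(~series, ncol = 1, scales = "free_y") +
    labs(x = "tick", y = NULL, colour = "strain s",
         title = sprintf("Case %s", object$plan$case)) +
    theme_minimal()
}
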