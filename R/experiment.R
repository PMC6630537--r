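#' Plan a multi-trial stimulation experiment
#'
#' Case A combines pathogens (replication schedule on) with each strain level;
#' Case B applies strain alone (the pathogen amplitude is forced to 0). The
#' study design runs strain levels `s` of 0, 0.1, 0.4 and 0.8 with 10 trials
#' each; the defaults here are the reduced test-scale profile.
#'
#' @param case `"A"` (strain + pathogens) or `"B"` (strain only).
#' @param strain_levels Strain values to sweep.
#' @param trials Number of seeded trials per strain level.
#' @param seed_base First seed; trial `i` uses `seed_base + i - 1`.
#' @param params Base [sim_params()]; its `strain` and (for Case B)
#'   `amplitude` fields are overridden per run.
#' @return An `experiment_plan` object.
#' @export
experiment_plan <- function(case = c("A", "B"),
                            strain_levels = c(0, 0.1, 0.4, 0.8),
                            trials = 10, seed_base = 1,
                            params = scaled_params()) {
  case <- match.arg(case)
  stopifnot(inherits(params, "sim_params"))
  if (trials < 1) rlang::abort("`trials` must be >= 1.")
  if (any(strain_levels < 0 | strain_levels > 1)) {
    rlang::abort("strain levels must lie in [0, 1].")
  }
  if (case == "B") params$amplitude <- 0
  structure(
    list(case = case, strain_levels = strain_levels,
         trials = as.integer(trials),
         seeds = as.integer(seed_base + seq_len(trials) - 1L),
         params = params),
    class = "experiment_plan"
  )
}

#' Run a planned experiment
#'
#' For every (strain level, seed): simulates the tissue, extracts tracks,
#' computes turning angles, windowed TE networks and the Fc/Mc centrality
#' time course, and aggregates pathogen counts across trials (per-tick mean
#' and standard deviation). Fully deterministic given the plan's seed list.
#'
#' @param plan An [experiment_plan()].
#' @param window,step,bin_width,threshold Passed to
#'   [te_network_timecourse()].
#' @param compute_te Set `FALSE` to skip the communication-inference pipeline
#'   (the simulation tables are still produced).
#' @param verbose Print one line per completed run.
#' @return An `experiment_result`: list with tibbles `timecourses`
#'   (`case`, `strain`, `trial`, `seed`, `t`, `dead_count`,
#'   `inflammation_score`, `pathogen_count`), `fc_mc` (per-trial windowed
#'   `fc`, `mc`, `fc_mc`) and `aggregates` (`case`, `strain`, `t`,
#'   `score_mean`, `pathogen_mean`, `pathogen_sd`).
#' @export
run_experiment <- function(plan, window = 200, step = 100, bin_width = 0.005,
                           threshold = "upper_quartile", compute_te = TRUE,
                           verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  tcs <- list()
  fcs <- list()
  for (s in plan$strain_levels) {
    for (i in seq_along(plan$seeds)) {
      seed <- plan$seeds[i]
      params <- plan$params
      params$strain <- s
      run <- tryCatch(
        simulate_inflammation(params, seed = seed),
        error = function(e) {
          rlang::abort(sprintf(
            "simulation failed for case %s, s = %g, seed = %d: %s",
            plan$case, s, seed, conditionMessage(e)))
        }
      )
      tag <- tibble::tibble(case = plan$case, strain = s, trial = i, seed = seed)
      tcs[[length(tcs) + 1L]] <- dplyr::bind_cols(
        tag[rep(1L, nrow(run$timecourse)), ], run$timecourse)
      if (compute_te) {
        ctc <- run$tracks |>
          turning_angles() |>
          te_network_timecourse(window = window, step = step,
                                bin_width = bin_width, threshold = threshold) |>
          centrality_timecourse()
        fcs[[length(fcs) + 1L]] <- dplyr::bind_cols(
          tag[rep(1L, nrow(ctc)), ], ctc)
      }
      if (verbose) {
        message(sprintf("case %s  s = %-4g seed = %d  done", plan$case, s, seed))
      }
    }
  }
  timecourses <- dplyr::bind_rows(tcs)
  aggregates <- timecourses |>
    dplyr::group_by(.data$case, .data$strain, .data$t) |>
    dplyr::summarise(
      score_mean = mean(.data$inflammation_score),
      pathogen_mean = mean(.data$pathogen_count),
      pathogen_sd = stats::sd(.data$pathogen_count),
      .groups = "drop"
    )
  structure(
    list(plan = plan, timecourses = timecourses,
         fc_mc = if (compute_te) dplyr::bind_rows(fcs) else NULL,
         aggregates = aggregates),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> case %s, s in {%s}, %d trials (seeds %d..%d)\n",
              x$plan$case, paste(x$plan$strain_levels, collapse = ", "),
              x$plan$trials, min(x$plan$seeds), max(x$plan$seeds)))
  peaks <- x$aggregates |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(peak = max(.data$score_mean),
                     peak_t = .data$t[which.max(.data$score_mean)],
                     .groups = "drop")
  for (i in seq_len(nrow(peaks))) {
    cat(sprintf("  s = %-4g peak mean score %.3f at tick %d\n",
                peaks$strain[i], peaks$peak[i], peaks$peak_t[i]))
  }
  invisible(x)
}

#' Trend direction of a series over its second half
#'
#' Fits a least-squares line to the second half of the series and reports the
#' slope's sign: `"increasing"`, `"decreasing"`, or `"flat"` when the absolute
#' slope falls below `flat_eps` (counts per tick). Used to summarise whether
#' the across-trial pathogen-count dispersion diverges or converges toward the
#' end of the inflammation episode.
#'
#' @param x Numeric series (e.g. per-tick SD of pathogen counts).
#' @param t Time axis; defaults to the sample index.
#' @param flat_eps Absolute-slope cutoff for `"flat"`.
#' @return One of `"increasing"`, `"decreasing"`, `"flat"`, plus the fitted
#'   slope in attribute `"slope"`.
#' @examples
#' sd_trend(c(0, 1, 2, 3, 4, 5, 6, 7))       # increasing
#' sd_trend(rep(0, 10))                      # flat
#' @export
sd_trend <- function(x, t = seq_along(x), flat_eps = 1e-6) {
  if (length(x) < 4) rlang::abort("series too short for a trend over its second half.")
  half <- t >= t[1] + (t[length(t)] - t[1]) / 2
  slope <- unname(coef(lm(x[half] ~ t[half]))[2])
  if (is.na(slope)) slope <- 0
  dir <- if (abs(slope) < flat_eps) "flat" else if (slope > 0) "increasing" else "decreasing"
  attr(dir, "slope") <- slope
  dir
}

#' Pathogen-count SD trend for one experimental condition
#'
#' Extracts the across-trial standard deviation of pathogen counts for the
#' given strain level from an [run_experiment()] result and classifies its
#' trend over the second half of the run with [sd_trend()].
#'
#' @param result An `experiment_result`.
#' @param strain One of the plan's strain levels.
#' @inheritParams sd_trend
#' @return See [sd_trend()].
#' @export
pathogen_sd_trend <- function(result, strain, flat_eps = 1e-6) {
  stopifnot(inherits(result, "experiment_result"))
  if (result$plan$trials < 2) rlang::abort("at least 2 trials are needed for an SD trend.")
  agg <- dplyr::filter(result$aggregates, .data$strain == !!strain)
  if (nrow(agg) == 0) rlang::abort(sprintf("strain %g is not in the experiment.", strain))
  sd_trend(agg$pathogen_sd, agg$t, flat_eps = flat_eps)
}

#' Recovery-phase onset of an inflammation time course
#'
#' Operationalised as the tick at which the moving-average-smoothed
#' inflammation score attains its maximum (the first such tick if tied):
#' after this point the tissue is, on average, recovering.
#'
#' @param timecourse Either a tibble with columns `t` and
#'   `inflammation_score` (as in `simulate_inflammation(...)$timecourse`) or a
#'   bare numeric score series.
#' @param smooth_window Moving-average window in ticks.
#' @return The onset tick.
#' @export
recovery_onset <- function(timecourse, smooth_window = 100) {
  if (is.data.frame(timecourse)) {
    t <- timecourse$t
    x <- timecourse$inflammation_score
  } else {
    x <- timecourse
    t <- seq_along(x) - 1
  }
  sm <- as.vector(stats::filter(x, rep(1 / smooth_window, smooth_window), sides = 2))
  sm[is.na(sm)] <- -Inf
  t[which.max(sm)]
}
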