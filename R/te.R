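#' Transfer entropy between two symbol series
#'
#' The plug-in (maximum-likelihood) estimate, with history length 1 for both
#' series, of
#' \deqn{T_{X \to Y} = \sum p(y_t, y_{t-1}, x_{t-1})
#'   \log_2 \frac{p(y_t \mid y_{t-1}, x_{t-1})}{p(y_t \mid y_{t-1})}}
#' i.e. the reduction in uncertainty of the target's next symbol given the
#' source's previous symbol, beyond what the target's own past provides.
#' Probabilities are joint relative frequencies over the series; no bias
#' correction is applied and the estimate is clamped at zero. `NA` entries are
#' treated as an ordinary alphabet symbol. A degenerate (constant) source or
#' target gives exactly 0.
#'
#' @param source,target Atomic vectors of equal length `n >= 3` over a finite
#'   alphabet (integer symbols from [discretize_angles()], or anything
#'   matchable).
#' @return Transfer entropy in bits (non-negative scalar).
#' @examples
#' x <- rep(0:1, 50)
#' y <- c(0L, x[-100])   # y copies x with lag 1
#' transfer_entropy(x, y) # 1 bit
#' @export
transfer_entropy <- function(source, target) {
  n <- length(target)
  if (length(source) != n) {
    rlang::abort("`source` and `target` must have equal length.")
  }
  if (n < 3) rlang::abort("series must have length >= 3.")
  x1 <- source[-n]
  y1 <- target[-n]
  y2 <- target[-1L]
  ux <- unique(x1)
  uy <- unique(target)
  xs <- match(x1, ux, incomparables = NULL)
  ys1 <- match(y1, uy)
  ys2 <- match(y2, uy)
  kx <- length(ux)
  ky <- length(uy)
  if (kx == 1L || ky == 1L) return(0)

  N <- n - 1L
  c3 <- tabulate((ys2 - 1L) * ky * kx + (ys1 - 1L) * kx + xs, ky * ky * kx)
  cyy <- tabulate((ys2 - 1L) * ky + ys1, ky * ky)
  cyx <- tabulate((ys1 - 1L) * kx + xs, ky * kx)
  cy <- tabulate(ys1, ky)

  nz <- which(c3 > 0L)
  i <- nz - 1L
  xs_i <- (i %% kx) + 1L
  ys1_i <- ((i %/% kx) %% ky) + 1L
  ys2_i <- (i %/% (kx * ky)) + 1L
  te <- sum((c3[nz] / N) * log2(
    (c3[nz] * cy[ys1_i]) /
      (cyx[(ys1_i - 1L) * kx + xs_i] * cyy[(ys2_i - 1L) * ky + ys1_i])
  ))
  max(te, 0)
}

#' Permutation null distribution for a transfer-entropy estimate
#'
#' Recomputes the estimate `n_perm` times with the source series randomly
#' permuted (destroying any temporal coupling while keeping its marginal).
#' Useful for judging whether an observed estimate exceeds what finite-sample
#' bias alone produces.
#'
#' @inheritParams transfer_entropy
#' @param n_perm Number of shuffles.
#' @return Numeric vector of `n_perm` null transfer-entropy values (bits).
#' @export
te_permutation_null <- function(source, target, n_perm = 200) {
  vapply(seq_len(n_perm), function(i) {
    transfer_entropy(sample(source), target)
  }, numeric(1))
}

#' Pairwise transfer-entropy matrix over a time window
#'
#' Computes the transfer entropy for every (macrophage, fibroblast) pair on
#' the angle sub-series falling in `[window_start, window_end]`, after
#' discretising angles with [discretize_angles()]. By default the macrophage
#' is the source and the fibroblast the target (predicting the fibroblast's
#' next turn from its own past plus the macrophage's); `direction` switches
#' the orientation or takes the maximum of the two.
#'
#' @param angles Angle tibble from [turning_angles()] containing both kinds;
#'   every cell's series must cover the window.
#' @param window_start,window_end Inclusive tick range.
#' @param bin_width Discretisation bin width (radians).
#' @param direction `"m_to_f"` (default), `"f_to_m"`, or `"max"`.
#' @return A tibble of class `te_matrix` with columns `macrophage`,
#'   `fibroblast`, `te` (bits) and the window stored in attributes
#'   `window_start` / `window_end`.
#' @export
te_matrix <- function(angles, window_start, window_end, bin_width = 0.005,
                      direction = c("m_to_f", "f_to_m", "max")) {
  direction <- match.arg(direction)
  if (window_end <= window_start) rlang::abort("empty window: `window_end` must exceed `window_start`.")
  win <- angles |>
    dplyr::filter(.data$t >= window_start, .data$t <= window_end) |>
    discretize_angles(bin_width = bin_width) |>
    dplyr::arrange(.data$cell_id, .data$t)
  if (nrow(win) == 0) rlang::abort("no angle samples fall in the window.")

  cover <- win |>
    dplyr::count(.data$cell_id, .data$kind)
  ids <- angles |> dplyr::distinct(.data$cell_id, .data$kind)
  if (nrow(cover) < nrow(ids) || length(unique(cover$n)) != 1L) {
    rlang::abort("every cell's angle series must cover the whole window.")
  }

  sym <- split(win$symbol, win$cell_id)
  m_ids <- sort(cover$cell_id[cover$kind == "macrophage"])
  f_ids <- sort(cover$cell_id[cover$kind == "fibroblast"])
  grid <- expand.grid(macrophage = m_ids, fibroblast = f_ids,
                      KEEP.OUT.ATTRS = FALSE)
  te <- vapply(seq_len(nrow(grid)), function(i) {
    m <- sym[[as.character(grid$macrophage[i])]]
    f <- sym[[as.character(grid$fibroblast[i])]]
    switch(direction,
      m_to_f = transfer_entropy(m, f),
      f_to_m = transfer_entropy(f, m),
      max = max(transfer_entropy(m, f), transfer_entropy(f, m))
    )
  }, numeric(1))
  out <- tibble::tibble(macrophage = grid$macrophage,
                        fibroblast = grid$fibroblast, te = te)
  attr(out, "window_start") <- window_start
  attr(out, "window_end") <- window_end
  class(out) <- c("te_matrix", class(out))
  out
}

#' Edge-inclusion threshold from the TE distribution
#'
#' The edge criterion is derived from the empirical distribution of the
#' pairwise transfer-entropy values. `"upper_quartile"` keeps edges with
#' `te > Q3`; `"iqr_band"` keeps the most likely values, `Q1 < te <= Q3`
#' (accounting for asymmetry of the distribution); `"fixed"` keeps
#' `te > fixed_value`. Quartiles use the linear-interpolation convention
#' (R's default `quantile()` type 7).
#'
#' @param values Numeric vector of TE values (at least 4 for the quartile
#'   modes).
#' @param mode One of `"upper_quartile"`, `"iqr_band"`, `"fixed"`.
#' @param fixed_value Threshold in bits when `mode = "fixed"`.
#' @return A `te_threshold` object (list with `mode`, `lower`, `upper`).
#' @examples
#' select_threshold(c(1, 2, 3, 4))  # TC = Q3 = 3.25
#' @export
select_threshold <- function(values,
                             mode = c("upper_quartile", "iqr_band", "fixed"),
                             fixed_value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(fixed_value) || fixed_value < 0) {
      rlang::abort("`fixed` mode requires a non-negative `fixed_value`.")
    }
    thr <- list(mode = mode, lower = fixed_value, upper = Inf)
  } else {
    if (length(values) < 4) {
      rlang::abort("at least 4 TE values are needed to derive quartiles.")
    }
    q <- unname(quantile(values, c(0.25, 0.75), type = 7))
    thr <- if (mode == "upper_quartile") {
      list(mode = mode, lower = q[2], upper = Inf)
    } else {
      list(mode = mode, lower = q[1], upper = q[2])
    }
  }
  structure(thr, class = "te_threshold")
}

# Edge-inclusion test for a threshold policy.
keep_edge <- function(te, thr) {
  if (thr$mode == "iqr_band") te > thr$lower & te <= thr$upper else te > thr$lower
}

#' Build a TE network from a pairwise TE matrix
#'
#' Starts from the complete bipartite edge set over all macrophage and
#' fibroblast nodes and removes every edge failing the threshold criterion;
#' all nodes are retained even if isolated.
#'
#' @param tem A [te_matrix()] tibble.
#' @param threshold A `te_threshold` from [select_threshold()], or a mode
#'   string (`"upper_quartile"`, `"iqr_band"`, `"fixed"`) used to derive one
#'   from this matrix's own TE distribution.
#' @param fixed_value Passed to [select_threshold()] when `threshold` is
#'   `"fixed"`.
#' @return A `te_network`: list with `m_nodes`, `f_nodes`, `edges` (tibble
#'   `macrophage`, `fibroblast`, `te`), `threshold`, and the source window.
#' @export
build_te_network <- function(tem, threshold = "upper_quartile", fixed_value = NULL) {
  if (is.character(threshold)) {
    threshold <- select_threshold(tem$te, mode = threshold, fixed_value = fixed_value)
  }
  stopifnot(inherits(threshold, "te_threshold"))
  keep <- keep_edge(tem$te, threshold)
  structure(
    list(
      m_nodes = sort(unique(tem$macrophage)),
      f_nodes = sort(unique(tem$fibroblast)),
      edges = tibble::as_tibble(tem[keep, c("macrophage", "fibroblast", "te")]),
      threshold = threshold,
      window_start = attr(tem, "window_start"),
      window_end = attr(tem, "window_end")
    ),
    class = "te_network"
  )
}

#' @export
print.te_network <- function(x, ...) {
  cat(sprintf("<te_network> %d macrophage + %d fibroblast nodes, %d edges",
              length(x$m_nodes), length(x$f_nodes), nrow(x$edges)))
  if (!is.null(x$window_start)) {
    cat(sprintf(" (window %s-%s)", x$window_start, x$window_end))
  }
  cat("\n")
  invisible(x)
}

#' Sliding-window TE networks over a run
#'
#' Slices the angle series into windows of `window` ticks stepped by `step`,
#' computes the pairwise TE matrix in each window, derives the edge threshold
#' from that window's own TE distribution, and builds the TE network.
#'
#' @inheritParams te_matrix
#' @param window,step Window length and stride in ticks.
#' @param threshold Threshold mode passed to [build_te_network()].
#' @param fixed_value Fixed threshold in bits (for `threshold = "fixed"`).
#' @return A tibble with columns `window_start`, `window_end` and a `network`
#'   list-column of `te_network` objects.
#' @export
te_network_timecourse <- function(angles, window = 200, step = 100,
                                  bin_width = 0.005,
                                  threshold = "upper_quartile",
                                  fixed_value = NULL,
                                  direction = c("m_to_f", "f_to_m", "max")) {
  direction <- match.arg(direction)
  t0 <- min(angles$t)
  t1 <- max(angles$t)
  if (t1 - t0 + 1 < window) rlang::abort("angle series shorter than one window.")
  starts <- seq(t0, t1 - window + 1, by = step)
  nets <- lapply(starts, function(s) {
    tem <- te_matrix(angles, s, s + window - 1, bin_width = bin_width,
                     direction = direction)
    build_te_network(tem, threshold = threshold, fixed_value = fixed_value)
  })
  tibble::tibble(window_start = starts, window_end = starts + window - 1,
                 network = nets)
}
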