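#' Turning-angle series from cell tracks
#'
#' For each cell the displacement vector at time `t` is
#' `m_t = p_t - p_{t-1}`; the turning angle at `t` is the unsigned angle
#' between `m_t` and `m_{t-1}`,
#' `acos(m_t . m_{t-1} / (|m_t| |m_{t-1}|))`, in `[0, pi]`. On a Moore lattice
#' the defined angles take only the values `0, pi/4, pi/2, 3pi/4, pi`. When
#' either displacement is zero (the cell stayed put) the angle is undefined
#' and recorded as `NA` — a "no move" sentinel kept as its own symbol
#' downstream so that series from different cells stay time-aligned.
#'
#' @param tracks A tracks tibble with columns `cell_id`, `kind`, `t`, `row`,
#'   `col`, e.g. `simulate_inflammation(...)$tracks`.
#' @return A tibble `cell_id`, `kind`, `t`, `angle` with one row per interior
#'   time point (each cell loses its first two time points).
#' @examples
#' tr <- tibble::tibble(cell_id = 1, kind = "macrophage", t = 0:3,
#'                      row = c(1, 1, 1, 2), col = c(1, 2, 3, 4))
#' turning_angles(tr)
#' @export
turning_angles <- function(tracks) {
  need <- c("cell_id", "kind", "t", "row", "col")
  if (!all(need %in% names(tracks))) {
    rlang::abort(paste0("`tracks` must have columns: ", paste(need, collapse = ", ")))
  }
  short <- tracks |>
    dplyr::count(.data$cell_id) |>
    dplyr::filter(.data$n < 3)
  if (nrow(short) > 0) {
    rlang::abort("every track must have at least 3 positions to define a turning angle.")
  }
  tracks |>
    dplyr::arrange(.data$cell_id, .data$t) |>
    dplyr::group_by(.data$cell_id, .data$kind) |>
    dplyr::mutate(
      dr = .data$row - dplyr::lag(.data$row),
      dc = .data$col - dplyr::lag(.data$col),
      pdr = dplyr::lag(.data$dr),
      pdc = dplyr::lag(.data$dc),
      # one sqrt of the integer product keeps lattice cosines exact
      # (sqrt(2) * sqrt(2) != 2 in floating point, but sqrt(4) is)
      nn = sqrt((.data$dr^2 + .data$dc^2) * (.data$pdr^2 + .data$pdc^2)),
      angle = dplyr::if_else(
        .data$nn == 0,
        NA_real_,
        acos(pmin(pmax((.data$dr * .data$pdr + .data$dc * .data$pdc) /
                         .data$nn, -1), 1))
      )
    ) |>
    dplyr::slice(-(1:2)) |>
    dplyr::ungroup() |>
    dplyr::select("cell_id", "kind", "t", "angle")
}

#' Discretise angles into symbols
#'
#' Maps each defined angle to the integer bin `floor(angle / bin_width)`;
#' `NA` angles (no-move sentinels) map to the reserved symbol `-1`, which is
#' treated as an ordinary alphabet symbol by the transfer-entropy estimator
#' (staying still is informative behaviour). Any `bin_width` below `pi/4`
#' keeps the five lattice angles in five distinct symbols.
#'
#' @param angles Either a numeric vector of angles (radians, `NA` = no move)
#'   or an angle tibble from [turning_angles()].
#' @param bin_width Bin width in radians, positive. The default 0.005 sits in
#'   the middle of the binning range used to estimate the joint densities.
#' @return An integer symbol vector, or the input tibble with a `symbol`
#'   column added.
#' @export
discretize_angles <- function(angles, bin_width = 0.005) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    rlang::abort("`bin_width` must be a single positive number.")
  }
  to_symbol <- function(a) {
    out <- ifelse(is.na(a), -1L, as.integer(floor(a / bin_width)))
    as.integer(out)
  }
  if (is.data.frame(angles)) {
    dplyr::mutate(angles, symbol = to_symbol(.data$angle))
  } else {
    to_symbol(angles)
  }
}
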