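#' Advance a cytokine field one diffusion-decay step
#'
#' The two signalling cytokines (TNF and TGF) obey a diffusion equation with
#' first-order dissolution, d(phi)/dt = D * Laplacian(phi) - K * phi.
#' One call performs a single forward-Euler (FTCS) step of the 5-point-stencil
#' Laplacian with no-flux (reflecting) boundaries, followed by multiplicative
#' decay by `(1 - K * dt)`; the result is clamped at zero from below. The
#' input matrix is not modified.
#'
#' With `K = 0` the scheme conserves total mass exactly (up to floating
#' point); stability of the explicit step requires `D * dt / dx^2 <= 0.25`
#' (dx is fixed at one lattice site).
#'
#' @param field Numeric matrix of non-negative concentrations, one per site.
#' @param D Diffusion constant (sites^2 per step), `> 0` allowed down to 0.
#' @param K Dissolution constant (per step), `>= 0`.
#' @param dt Time step; the simulator always uses 1.
#' @return A matrix of the same shape, one step later.
#' @examples
#' f <- matrix(0, 5, 5); f[3, 3] <- 1
#' step_diffusion(f, D = 0.2, K = 0)
#' @export
step_diffusion <- function(field, D, K = 0, dt = 1) {
  if (!is.matrix(field) || !is.numeric(field)) {
    rlang::abort("`field` must be a numeric matrix.")
  }
  if (D < 0 || K < 0) rlang::abort("`D` and `K` must be non-negative.")
  if (D * dt > 0.25) {
    rlang::abort(sprintf(
      "explicit scheme unstable: D * dt / dx^2 = %.3f exceeds the bound 0.25",
      D * dt))
  }
  if (K * dt > 1) rlang::abort("`K * dt` must not exceed 1 (decay factor would go negative).")
  nb <- neighbor_sum(field, .neumann_offsets)
  cnt <- neighbor_count(nrow(field), ncol(field), .neumann_offsets)
  out <- field + D * dt * (nb - cnt * field)
  out <- out * (1 - K * dt)
  out[out < 0] <- 0
  out
}

#' Deposit cytokine at a single site
#'
#' Adds `amount` to the field at `(row, col)`; all other sites are unchanged.
#' Used by the secretion rule: each secretion event deposits a fixed amount at
#' the secreting cell's own site.
#'
#' @inheritParams step_diffusion
#' @param row,col 1-based site coordinates.
#' @param amount Non-negative concentration to add.
#' @return The updated matrix.
#' @export
deposit <- function(field, row, col, amount) {
  if (!is.numeric(amount) || length(amount) != 1L || is.na(amount) || amount < 0) {
    rlang::abort("`amount` must be a single non-negative number.")
  }
  if (row < 1 || row > nrow(field) || col < 1 || col > ncol(field)) {
    rlang::abort("deposit site is outside the field.")
  }
  field[row, col] <- field[row, col] + amount
  field
}
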