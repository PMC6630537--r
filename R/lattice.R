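#' Define a bounded rectangular lattice
#'
#' The tissue patch is a bounded `height` x `width` lattice of epithelial
#' sites. Coordinates are 1-based `(row, col)` pairs, row 1 at the top.
#' Boundaries are reflecting (a tissue patch, not a torus): neighbour lists
#' are clipped at the edges and the cytokine solver uses no-flux boundaries.
#'
#' @param width,height Lattice extent in sites; both must be at least 3.
#' @return A `grid_spec` object (a list with `width`, `height`, `boundary`).
#' @examples
#' g <- grid_spec(11, 11)
#' moore_neighbors(1, 1, g)
#' @export
grid_spec <- function(width, height) {
  if (!is.numeric(width) || !is.numeric(height) ||
      length(width) != 1L || length(height) != 1L ||
      width < 3 || height < 3 || width != round(width) || height != round(height)) {
    rlang::abort("`width` and `height` must be single integers >= 3.")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         boundary = "reflecting"),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d (rows x cols), %s boundary\n",
              x$height, x$width, x$boundary))
  invisible(x)
}

# Fixed neighbour orderings (clockwise from north) so that seeded runs are
# bit-reproducible. Offsets are (drow, dcol) with row increasing downwards.
.moore_offsets <- matrix(
  c(-1L, 0L,  -1L, 1L,  0L, 1L,  1L, 1L,  1L, 0L,  1L, -1L,  0L, -1L,  -1L, -1L),
  ncol = 2L, byrow = TRUE,
  dimnames = list(c("N", "NE", "E", "SE", "S", "SW", "W", "NW"), c("drow", "dcol"))
)

.neumann_offsets <- .moore_offsets[c("N", "E", "S", "W"), , drop = FALSE]

.check_site <- function(row, col, grid) {
  if (length(row) != 1L || length(col) != 1L ||
      is.na(row) || is.na(col) ||
      row < 1L || row > grid$height || col < 1L || col > grid$width) {
    rlang::abort(sprintf(
      "site (%s, %s) is outside the %d x %d grid",
      format(row), format(col), grid$height, grid$width))
  }
}

.neighbors <- function(row, col, grid, offsets) {
  .check_site(row, col, grid)
  r <- row + offsets[, "drow"]
  c <- col + offsets[, "dcol"]
  keep <- r >= 1L & r <= grid$height & c >= 1L & c <= grid$width
  tibble::tibble(row = as.integer(r[keep]), col = as.integer(c[keep]))
}

#' Neighbours of a lattice site
#'
#' `moore_neighbors()` returns the in-bounds subset of the 8 surrounding
#' sites, `neumann_neighbors()` the 4 orthogonal ones. Both return sites in a
#' fixed clockwise-from-north order (N, NE, E, SE, S, SW, W, NW and
#' N, E, S, W respectively), clipped at the lattice edges, so interior sites
#' have 8 (resp. 4) neighbours, edges 5 (3) and corners 3 (2).
#'
#' @param row,col 1-based site coordinates.
#' @param grid A [grid_spec()].
#' @return A tibble with columns `row`, `col`, one row per in-bounds neighbour.
#' @export
moore_neighbors <- function(row, col, grid) {
  .neighbors(row, col, grid, .moore_offsets)
}

#' @rdname moore_neighbors
#' @export
neumann_neighbors <- function(row, col, grid) {
  .neighbors(row, col, grid, .neumann_offsets)
}

# ---- internal fast lattice helpers ------------------------------------------

# Zero-padded shift: out[r, c] = M[r - dr, c - dc] when in bounds, else 0.
shift_mat <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(0, nr, nc)
  r_dst <- max(1L, 1L + dr):min(nr, nr + dr)
  c_dst <- max(1L, 1L + dc):min(nc, nc + dc)
  out[r_dst, c_dst] <- M[r_dst - dr, c_dst - dc]
  out
}

# Sum of M over each site's in-bounds neighbours for the given offsets.
# out[r, c] = sum over offsets of M[r + drow, c + dcol] (out-of-bounds -> 0).
neighbor_sum <- function(M, offsets) {
  out <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(offsets))) {
    out <- out + shift_mat(M, -offsets[i, 1L], -offsets[i, 2L])
  }
  out
}

# Number of in-bounds neighbours per site for the given offsets.
neighbor_count <- function(nr, nc, offsets) {
  neighbor_sum(matrix(1, nr, nc), offsets)
}

# Per-site list of neighbour linear indices (column-major), fixed order.
# Used by the per-agent movement loop.
build_neighbor_index <- function(nr, nc, offsets = .moore_offsets) {
  idx <- vector("list", nr * nc)
  for (col in seq_len(nc)) {
    for (row in seq_len(nr)) {
      r <- row + offsets[, "drow"]
      c <- col + offsets[, "dcol"]
      keep <- r >= 1L & r <= nr & c >= 1L & c <= nc
      idx[[(col - 1L) * nr + row]] <- (c[keep] - 1L) * nr + r[keep]
    }
  }
  idx
}
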