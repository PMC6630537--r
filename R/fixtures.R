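#' Synthetic lag-coupled symbol series with known transfer entropy
#'
#' Generates a pair of symbol series with analytically known information
#' flow, for calibrating the estimator and the network pipeline before
#' analysing simulated tracks. The source is i.i.d. uniform over `k` symbols;
#' at each time `t > lag` the target copies `source[t - lag]` with probability
#' `coupling`, otherwise it draws i.i.d. uniform. `coupling = 0` gives
#' independent series (true TE 0); `coupling = 1` with `lag = 1` makes the
#' target an exact lagged copy (true TE `log2(k)` bits).
#'
#' @param k Alphabet size (>= 2).
#' @param coupling Copy probability in `[0, 1]`.
#' @param lag Positive copy lag.
#' @param n Series length (>= 10).
#' @param seed Integer seed.
#' @return A list with integer vectors `source` and `target` (symbols
#'   `0:(k-1)`), and the generating spec.
#' @examples
#' pair <- generate_coupled_pair(k = 2, coupling = 1, n = 1000, seed = 1)
#' transfer_entropy(pair$source, pair$target)  # close to 1 bit
#' @export
generate_coupled_pair <- function(k = 2, coupling = 1, lag = 1, n = 1000, seed = 1) {
  if (k < 2 || k != round(k)) rlang::abort("`k` must be an integer >= 2.")
  if (coupling < 0 || coupling > 1) rlang::abort("`coupling` must lie in [0, 1].")
  if (lag < 1 || lag != round(lag)) rlang::abort("`lag` must be a positive integer.")
  if (n < 10) rlang::abort("`n` must be >= 10.")
  set.seed(seed)
  source <- sample.int(k, n, replace = TRUE) - 1L
  noise <- sample.int(k, n, replace = TRUE) - 1L
  copy <- runif(n) < coupling
  target <- noise
  idx <- (lag + 1):n
  target[idx] <- ifelse(copy[idx], source[idx - lag], noise[idx])
  list(source = source, target = as.integer(target),
       spec = list(k = as.integer(k), coupling = coupling,
                   lag = as.integer(lag), n = as.integer(n), seed = seed))
}

#' Analytic transfer entropy of the lag-1 coupled pair
#'
#' Closed form for the family produced by [generate_coupled_pair()] with
#' `lag = 1`: since the source is i.i.d., consecutive target symbols are
#' independent and the transfer entropy reduces to the mutual information of
#' the noisy copy channel,
#' `log2(k) + (c + (1-c)/k) log2(c + (1-c)/k) + (k-1) ((1-c)/k) log2((1-c)/k)`.
#'
#' @inheritParams generate_coupled_pair
#' @return True transfer entropy in bits.
#' @export
te_lagged_copy_analytic <- function(k = 2, coupling = 1) {
  if (k < 2) rlang::abort("`k` must be >= 2.")
  if (any(coupling < 0 | coupling > 1)) rlang::abort("`coupling` must lie in [0, 1].")
  p_hit <- coupling + (1 - coupling) / k
  p_miss <- (1 - coupling) / k
  xlog <- function(p) ifelse(p > 0, p * log2(p), 0)
  log2(k) + xlog(p_hit) + (k - 1) * xlog(p_miss)
}

#' Unbiased random-walk tracks (no-communication null)
#'
#' Independent unbiased Moore-lattice walks with collision avoidance: the
#' null fixture for the full inference pipeline, where any apparent
#' information exchange is finite-sample artefact. Cells alternate kind
#' (macrophage, fibroblast, ...) unless `kinds` is supplied.
#'
#' @param n_cells Number of walkers (at most one per lattice site).
#' @param n_steps Number of ticks to walk.
#' @param width,height Lattice extent.
#' @param seed Integer seed.
#' @param kinds Optional character vector of length `n_cells` with values
#'   `"macrophage"` / `"fibroblast"`.
#' @return A tracks tibble (`cell_id`, `kind`, `t`, `row`, `col`) in the same
#'   format as `simulate_inflammation(...)$tracks`.
#' @export
generate_random_walk_tracks <- function(n_cells, n_steps, width = 50, height = 50,
                                        seed = 1, kinds = NULL) {
  if (n_cells > width * height) {
    rlang::abort("grid too crowded: `n_cells` exceeds the number of sites.")
  }
  if (is.null(kinds)) {
    kinds <- rep(c("macrophage", "fibroblast"), length.out = n_cells)
  }
  if (length(kinds) != n_cells || !all(kinds %in% c("macrophage", "fibroblast"))) {
    rlang::abort("`kinds` must be length `n_cells` with values macrophage/fibroblast.")
  }
  set.seed(seed)
  nr <- as.integer(height); nc <- as.integer(width)
  pc <- get_precomp(nr, nc)
  occ <- matrix(0L, nr, nc)
  lin <- sample.int(nr * nc, n_cells)
  occ[lin] <- 1L
  rows <- matrix(0L, n_cells, n_steps + 1L)
  cols <- matrix(0L, n_cells, n_steps + 1L)
  cur <- lin
  rows[, 1L] <- ((cur - 1L) %% nr) + 1L
  cols[, 1L] <- ((cur - 1L) %/% nr) + 1L
  for (t in seq_len(n_steps)) {
    for (i in sample.int(n_cells)) {
      cand <- pc$moore_idx[[cur[i]]]
      free <- cand[occ[cand] == 0L]
      # stay is always a candidate, giving each unblocked move equal weight
      pick <- c(free, cur[i])[sample.int(length(free) + 1L, 1L)]
      if (pick != cur[i]) {
        occ[cur[i]] <- 0L
        occ[pick] <- 1L
        cur[i] <- pick
      }
    }
    rows[, t + 1L] <- ((cur - 1L) %% nr) + 1L
    cols[, t + 1L] <- ((cur - 1L) %/% nr) + 1L
  }
  tibble::tibble(
    cell_id = rep(seq_len(n_cells), each = n_steps + 1L),
    kind = rep(kinds, each = n_steps + 1L),
    t = rep(0:n_steps, times = n_cells),
    row = as.integer(t(rows)),
    col = as.integer(t(cols))
  )
}
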