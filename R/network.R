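#' Eigenvector centrality of a TE network
#'
#' Solves `A c = lambda c` for the principal eigenvector of the undirected
#' bipartite adjacency matrix by power iteration (on `A + I`, which leaves the
#' eigenvectors unchanged while breaking the +/- lambda symmetry a bipartite
#' adjacency spectrum has), to relative tolerance `tol`, then normalises the
#' entries to sum to 1 over all nodes. Isolated nodes receive centrality 0;
#' for a disconnected graph the vector is supported on the component(s)
#' achieving the largest eigenvalue.
#'
#' @param network A `te_network` from [build_te_network()].
#' @param tol Convergence tolerance on the max absolute change of the
#'   normalised vector.
#' @param max_iter Iteration cap.
#' @return A `centrality_result`: a tibble `node`, `kind`, `centrality` with
#'   attributes `mc` (mean macrophage centrality), `fc` (mean fibroblast
#'   centrality), `fc_mc` (their ratio, `NA` when `mc` is 0) and `lambda`.
#' @examples
#' tem <- tibble::tibble(macrophage = c(1, 1, 1), fibroblast = c(101, 102, 103),
#'                       te = c(1, 1, 1))
#' net <- build_te_network(structure(tem, class = c("te_matrix", class(tem))),
#'                         threshold = "fixed", fixed_value = 0)
#' eigenvector_centrality(net)
#' @export
eigenvector_centrality <- function(network, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(network, "te_network"))
  if (nrow(network$edges) == 0) {
    rlang::abort("eigenvector centrality is undefined for an edgeless network.")
  }
  m <- network$m_nodes
  f <- network$f_nodes
  n <- length(m) + length(f)
  A <- matrix(0, n, n)
  mi <- match(network$edges$macrophage, m)
  fi <- length(m) + match(network$edges$fibroblast, f)
  A[cbind(mi, fi)] <- 1
  A[cbind(fi, mi)] <- 1

  v <- rep(1 / n, n)
  lambda <- 0
  for (iter in seq_len(max_iter)) {
    w <- as.vector(A %*% v) + v  # power step on A + I
    w_norm <- sqrt(sum(w^2))
    w <- w / w_norm
    if (max(abs(w - v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  lambda <- as.vector(v %*% (A %*% v)) / sum(v^2)
  v[v < 0] <- 0
  cent <- v / sum(v)

  out <- tibble::tibble(
    node = c(m, f),
    kind = rep(c("macrophage", "fibroblast"), c(length(m), length(f))),
    centrality = cent
  )
  mc <- mean(cent[seq_along(m)])
  fc <- mean(cent[length(m) + seq_along(f)])
  attr(out, "mc") <- mc
  attr(out, "fc") <- fc
  attr(out, "fc_mc") <- if (mc > 0) fc / mc else NA_real_
  attr(out, "lambda") <- lambda
  class(out) <- c("centrality_result", class(out))
  out
}

#' Fibroblast-to-macrophage centrality ratio
#'
#' `Fc / Mc`, where `Fc` and `Mc` are the arithmetic means of the fibroblast
#' and macrophage node centralities. A high ratio indicates fibroblasts
#' dominate the communication network at that time point. When `Mc` is zero
#' (all macrophage nodes isolated) the ratio is undefined and `NA` is
#' returned rather than an error, so time courses keep their length.
#'
#' @param result A `centrality_result` from [eigenvector_centrality()].
#' @return A single number, or `NA` when undefined.
#' @export
fc_mc_ratio <- function(result) {
  stopifnot(inherits(result, "centrality_result"))
  attr(result, "fc_mc")
}

#' Fc/Mc time course over windowed TE networks
#'
#' Applies [eigenvector_centrality()] and [fc_mc_ratio()] to each window's
#' network. Windows whose network is edgeless yield `NA` for `fc`, `mc` and
#' `fc_mc` (low-communication regimes), preserved in place so the series keeps
#' its length.
#'
#' @param networks A tibble with a `network` list-column (from
#'   [te_network_timecourse()]) or a bare list of `te_network` objects.
#' @return A tibble `window_start`, `window_end`, `fc`, `mc`, `fc_mc`.
#' @export
centrality_timecourse <- function(networks) {
  if (is.data.frame(networks)) {
    nets <- networks$network
    starts <- networks$window_start
    ends <- networks$window_end
  } else {
    nets <- networks
    starts <- vapply(nets, function(n) n$window_start %||% NA_real_, numeric(1))
    ends <- vapply(nets, function(n) n$window_end %||% NA_real_, numeric(1))
  }
  if (length(nets) < 1) rlang::abort("at least one network is required.")
  res <- lapply(nets, function(net) {
    if (nrow(net$edges) == 0) {
      c(fc = NA_real_, mc = NA_real_, fc_mc = NA_real_)
    } else {
      cr <- eigenvector_centrality(net)
      c(fc = attr(cr, "fc"), mc = attr(cr, "mc"), fc_mc = attr(cr, "fc_mc"))
    }
  })
  res <- do.call(rbind, res)
  tibble::tibble(window_start = starts, window_end = ends,
                 fc = res[, "fc"], mc = res[, "mc"], fc_mc = res[, "fc_mc"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
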