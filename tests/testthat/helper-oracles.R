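# Independent oracles used to cross-check the package's estimators.

# Brute-force transfer entropy by explicit enumeration over the joint
# probability table (built with table(); marginalised with sum()), kept
# deliberately independent of the package's count-indexing implementation.
te_bruteforce <- function(x, y) {
  n <- length(y)
  y_lev <- unique(y)
  x1 <- factor(x[-n], levels = unique(x[-n]))
  y1 <- factor(y[-n], levels = y_lev)
  y2 <- factor(y[-1], levels = y_lev)
  joint <- table(y2 = y2, y1 = y1, x1 = x1, useNA = "ifany") / (n - 1)
  te <- 0
  for (a in seq_len(dim(joint)[1])) {
    for (b in seq_len(dim(joint)[2])) {
      for (cc in seq_len(dim(joint)[3])) {
        p3 <- joint[a, b, cc]
        if (p3 > 0) {
          p_cond_full <- p3 / sum(joint[, b, cc])
          p_cond_own <- sum(joint[a, b, ]) / sum(joint[, b, ])
          te <- te + p3 * log2(p_cond_full / p_cond_own)
        }
      }
    }
  }
  max(te, 0)
}

# Dense eigen-decomposition oracle for eigenvector centrality on a te_network.
centrality_oracle <- function(net) {
  m <- net$m_nodes
  f <- net$f_nodes
  n <- length(m) + length(f)
  A <- matrix(0, n, n)
  mi <- match(net$edges$macrophage, m)
  fi <- length(m) + match(net$edges$fibroblast, f)
  A[cbind(mi, fi)] <- 1
  A[cbind(fi, mi)] <- 1
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0
  list(centrality = v / sum(v), lambda = e$values[1], gap = e$values[1] - e$values[2])
}

# Build a te_matrix tibble by hand (complete bipartite value grid).
make_te_matrix <- function(m_ids, f_ids, values) {
  g <- expand.grid(macrophage = m_ids, fibroblast = f_ids, KEEP.OUT.ATTRS = FALSE)
  out <- tibble::tibble(macrophage = g$macrophage, fibroblast = g$fibroblast,
                        te = as.vector(values))
  class(out) <- c("te_matrix", class(out))
  out
}

# Random bipartite te_network with a unique dominant eigenvalue (the oracle
# comparison is only well-posed when the top eigenspace is one-dimensional).
random_bipartite_network <- function(max_nodes = 20) {
  repeat {
    n_m <- sample(1:(max_nodes %/% 2), 1)
    n_f <- sample(1:(max_nodes %/% 2), 1)
    vals <- matrix(as.numeric(runif(n_m * n_f) < 0.4), n_m, n_f)
    if (sum(vals) == 0) next
    net <- build_te_network(make_te_matrix(seq_len(n_m), 100 + seq_len(n_f), vals),
                            threshold = "fixed", fixed_value = 0)
    gap <- centrality_oracle(net)$gap
    if (gap > 1e-6) return(net)
  }
}
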