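test_that("the plug-in estimator equals brute-force enumeration on short series", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(3:20, 1)
    k <- sample(2:4, 1)
    x <- sample(0:(k - 1), n, replace = TRUE)
    y <- sample(0:(k - 1), n, replace = TRUE)
    expect_equal(transfer_entropy(x, y), te_bruteforce(x, y), tolerance = 1e-13)
  }
})

test_that("degenerate and malformed inputs are handled", {
  expect_equal(transfer_entropy(c(0, 1, 0, 1), rep(1, 4)), 0)   # constant target
  expect_equal(transfer_entropy(rep(1, 4), c(0, 1, 0, 1)), 0)   # constant source
  expect_error(transfer_entropy(1:5, 1:4), "equal length")
  expect_error(transfer_entropy(1:2, 1:2), "length >= 3")
})

test_that("a lagged copy carries its full entropy; estimates are non-negative", {
  pair <- generate_coupled_pair(k = 2, coupling = 1, lag = 1, n = 5000, seed = 21)
  expect_equal(transfer_entropy(pair$source, pair$target), 1, tolerance = 0.05)
  pair4 <- generate_coupled_pair(k = 4, coupling = 1, lag = 1, n = 20000, seed = 22)
  expect_equal(transfer_entropy(pair4$source, pair4$target), 2, tolerance = 0.05)
  set.seed(31)
  for (i in 1:20) {
    x <- sample(0:2, 50, replace = TRUE)
    y <- sample(0:2, 50, replace = TRUE)
    expect_gte(transfer_entropy(x, y), 0)
  }
})

test_that("shuffling the source destroys the measured coupling", {
  pair <- generate_coupled_pair(k = 2, coupling = 1, lag = 1, n = 4000, seed = 5)
  te_obs <- transfer_entropy(pair$source, pair$target)
  set.seed(6)
  null <- te_permutation_null(pair$source, pair$target, n_perm = 50)
  expect_lt(median(null), te_obs / 20)
})

test_that("NA no-move symbols participate as ordinary symbols", {
  set.seed(12)
  x <- sample(c(0, 0.5, NA), 500, replace = TRUE)
  y <- dplyr::lag(x)          # the target copies the source with lag 1
  sx <- discretize_angles(x)
  sy <- discretize_angles(y)
  # a 3-symbol perfect copy carries about log2(3) bits; if the NA symbol were
  # dropped instead of kept, most of that information would vanish
  expect_gt(transfer_entropy(sx, sy), 1.4)
})

test_that("the TE matrix covers all pairs and is deterministic in its inputs", {
  tr <- generate_random_walk_tracks(6, 260, width = 25, height = 25, seed = 3)
  ang <- turning_angles(tr)
  tem <- te_matrix(ang, 2, 251)
  expect_equal(nrow(tem), 3 * 3)
  expect_setequal(unique(tem$macrophage), c(1, 3, 5))
  expect_true(all(tem$te >= 0))

  # duplicated fibroblast series gives identical columns
  ang2 <- ang
  dup <- dplyr::mutate(dplyr::filter(ang, .data$cell_id == 2), cell_id = 99)
  tem2 <- te_matrix(dplyr::bind_rows(ang2, dup), 2, 251)
  expect_equal(tem2$te[tem2$fibroblast == 99], tem2$te[tem2$fibroblast == 2])

  expect_error(te_matrix(ang, 10, 10), "empty window")
  expect_error(te_matrix(ang, 5000, 6000), "no angle samples")
})

test_that("threshold selection follows the quartile conventions", {
  thr <- select_threshold(c(1, 2, 3, 4))
  expect_equal(thr$lower, 3.25)  # Q3 by linear interpolation
  expect_error(select_threshold(c(1, 2, 3)), "at least 4")
  expect_error(select_threshold(1:10, mode = "fixed"), "fixed_value")

  band <- select_threshold(c(1, 2, 3, 4), mode = "iqr_band")
  expect_equal(band$lower, 1.75)
  expect_equal(band$upper, 3.25)
})

test_that("network construction keeps nodes and applies the edge criterion", {
  tem <- make_te_matrix(1:2, 11:12, matrix(c(0.5, 0.2, 0.1, 0.9), 2, 2))
  net <- build_te_network(tem, threshold = "fixed", fixed_value = 0.3)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$macrophage, net$edges$fibroblast),
                  c("1 11", "2 12"))
  expect_equal(net$m_nodes, 1:2)
  expect_equal(net$f_nodes, 11:12)

  # threshold above the maximum: edgeless but all nodes retained
  none <- build_te_network(tem, threshold = "fixed", fixed_value = 10)
  expect_equal(nrow(none$edges), 0)
  expect_equal(length(none$m_nodes) + length(none$f_nodes), 4)

  # fixed 0 with all TE positive: complete bipartite
  all_pos <- make_te_matrix(1:3, 11:14, matrix(runif(12) + 0.1, 3, 4))
  full <- build_te_network(all_pos, threshold = "fixed", fixed_value = 0)
  expect_equal(nrow(full$edges), 12)

  # degenerate distribution: upper-quartile keeps no edges (te > Q3 never true)
  flat <- make_te_matrix(1:2, 11:12, matrix(0.4, 2, 2))
  expect_equal(nrow(build_te_network(flat, "upper_quartile")$edges), 0)
})

test_that("raising a fixed threshold never adds edges", {
  set.seed(77)
  tem <- make_te_matrix(1:5, 11:16, matrix(runif(30), 5, 6))
  counts <- vapply(seq(0, 1, by = 0.1), function(tc) {
    nrow(build_te_network(tem, threshold = "fixed", fixed_value = tc)$edges)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("windowed networks tile the run as specified", {
  tr <- generate_random_walk_tracks(4, 520, width = 25, height = 25, seed = 8)
  ang <- turning_angles(tr)
  tc <- te_network_timecourse(ang, window = 200, step = 100)
  expect_equal(tc$window_start, c(2, 102, 202, 302))
  expect_true(all(vapply(tc$network, inherits, logical(1), "te_network")))
  expect_error(te_network_timecourse(ang, window = 10000), "shorter")
})
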