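test_that("apoptosis probability is the beta CDF of normalised TNF", {
  expect_equal(apoptosis_probability(0), 0)
  expect_equal(apoptosis_probability(1), 1)     # at the reference scale
  expect_equal(apoptosis_probability(5), 1)     # saturates above it
  # uniform shapes: CDF is the identity on [0, 1]
  expect_equal(apoptosis_probability(0.3, beta_a = 1, beta_b = 1), 0.3)
  # monotone in TNF
  x <- seq(0, 2, by = 0.05)
  expect_true(all(diff(apoptosis_probability(x)) >= 0))
  expect_error(apoptosis_probability(0.5, beta_a = 0), "positive")
  expect_error(apoptosis_probability(-1), "non-negative")
})

test_that("fibrosis death probability is Nf / Nnei", {
  ep <- matrix(0L, 5, 5)
  expect_equal(fibrosis_death_probability(3, 3, ep), 0)
  ep[2, 2] <- 3L; ep[2, 3] <- 3L
  expect_equal(fibrosis_death_probability(3, 3, ep), 2 / 8)
  # corner site: 3 moore neighbours, all fibrosis
  ep2 <- matrix(0L, 5, 5)
  ep2[1, 2] <- ep2[2, 1] <- ep2[2, 2] <- 3L
  expect_equal(fibrosis_death_probability(1, 1, ep2), 1)
})

test_that("movement weights follow the cytokine field and respect blocking", {
  f <- matrix(0, 9, 9)
  w <- movement_weights(5, 5, f)
  expect_equal(nrow(w), 9)                       # 8 moves + stay
  expect_equal(sum(w$weight), 1)
  expect_true(all(abs(w$weight - 1 / 9) < 1e-9)) # unbiased when no cytokine

  # one neighbour dominates
  f[4, 5] <- 100
  w <- movement_weights(5, 5, f)
  expect_gt(w$weight[w$move == "N"], 0.99)

  # all 8 moves blocked: stay with probability 1
  blocked <- matrix(FALSE, 9, 9)
  blocked[4:6, 4:6] <- TRUE
  blocked[5, 5] <- FALSE
  w <- movement_weights(5, 5, matrix(0, 9, 9), blocked)
  expect_equal(w$weight[w$move == "stay"], 1)
  expect_equal(sum(w$weight), 1)
})

test_that("the pathogen schedule is a rectified, periodically sampled sine", {
  # negative phase of the sine: rectified to zero spawns
  expect_equal(pathogen_schedule(120, amplitude = 4, alpha = 160,
                                 replication_period = 120), 0L)
  # zero amplitude never spawns
  expect_true(all(pathogen_schedule(0:500, amplitude = 0) == 0L))
  # peak phase: t = 25, alpha = 100 puts sin at 1 -> A spawns
  expect_equal(pathogen_schedule(25, amplitude = 4, alpha = 100,
                                 replication_period = 25), 4L)
  # off-schedule ticks spawn nothing even at peak phase
  expect_equal(pathogen_schedule(25, amplitude = 4, alpha = 100,
                                 replication_period = 40), 0L)
})

test_that("inflammation score is dead count over 1000", {
  expect_equal(inflammation_score(0), 0)
  expect_equal(inflammation_score(1500), 1.5)
  expect_equal(inflammation_score(1000), 1)
  expect_error(inflammation_score(-1), "non-negative")
})

test_that("epithelial rules fire as specified on hand-built states", {
  p <- sim_params(width = 5, height = 5, n_macrophages = 0, n_fibroblasts = 1,
                  n_steps = 1, p_mitosis = 0, amplitude = 0, th = 3)
  set.seed(1)
  st <- new_simulation_state(p)

  # quiescent tissue: no TNF, no fibrosis, Pmt = 0 -> nothing changes
  st2 <- step_epithelium(st, p)
  expect_equal(st2$epithelium, st$epithelium)

  # a dead site next to the fibroblast enters healing with timer th
  fr <- st$cells$row[1]; fc <- st$cells$col[1]
  nb <- moore_neighbors(fr, fc, grid_spec(5, 5))
  st$epithelium[nb$row[1], nb$col[1]] <- 1L
  st3 <- step_epithelium(st, p)
  expect_equal(st3$epithelium[nb$row[1], nb$col[1]], 2L)
  expect_equal(st3$timer[nb$row[1], nb$col[1]], 2L)  # th minus this tick's countdown

  # certain mitosis revives an isolated dead site next tick
  p_mit <- sim_params(width = 5, height = 5, n_macrophages = 0, n_fibroblasts = 0,
                      n_steps = 1, p_mitosis = 1, amplitude = 0)
  set.seed(1)
  stm <- new_simulation_state(p_mit)
  stm$epithelium[2, 2] <- 1L
  expect_equal(step_epithelium(stm, p_mit)$epithelium[2, 2], 0L)

  # healing completion leaves exactly one fibrosis site in the healed patch
  sth <- new_simulation_state(p_mit)
  sth$epithelium[2, 2:4] <- 2L
  sth$timer[2, 2:4] <- 1L
  st4 <- step_epithelium(sth, p_mit)
  expect_equal(sum(st4$epithelium == 3L), 1)
  expect_true(all(which(st4$epithelium == 3L) %in% which(sth$epithelium == 2L)))
})

test_that("activation and secretion follow strain, pathogens and cytokine clamps", {
  p <- sim_params(width = 7, height = 7, n_macrophages = 1, n_fibroblasts = 1,
                  n_steps = 1, strain = 0, amplitude = 0)
  set.seed(3)
  st <- new_simulation_state(p)

  # no strain, no pathogens, no TNF: nothing activates or secretes
  st1 <- activation_and_secretion(st, p)
  expect_false(any(st1$cells$activated))
  expect_equal(sum(st1$tnf) + sum(st1$tgf), 0)

  # strain_act * s = 1 forces macrophage activation; with zero TGF it
  # secretes with probability 1
  p2 <- p; p2$strain <- 1; p2$strain_act <- 1
  st2 <- activation_and_secretion(st, p2)
  m <- which(st2$cells$kind == 1L)
  expect_true(st2$cells$activated[m])
  expect_equal(sum(st2$tnf), p2$secrete_amount)

  # TGF at half the saturation scale halves the secretion probability
  lin_m <- (st$cells$col[m] - 1L) * 7 + st$cells$row[m]
  st3 <- st
  st3$tgf[lin_m] <- p2$secrete_theta_tgf / 2
  hits <- vapply(1:400, function(i) {
    sum(activation_and_secretion(st3, p2)$tnf) > 0
  }, logical(1))
  expect_equal(mean(hits), 0.5, tolerance = 0.15)

  # fibroblast activates on local TNF and secretes TGF
  f <- which(st$cells$kind == 2L)
  lin_f <- (st$cells$col[f] - 1L) * 7 + st$cells$row[f]
  st4 <- st
  st4$tnf[lin_f] <- 0.01
  st4 <- activation_and_secretion(st4, p)
  expect_true(st4$cells$activated[f])
  expect_equal(st4$tgf[lin_f], p$secrete_amount)
})

test_that("pathogens walk, are phagocytosed next to macrophages, and spawn on schedule", {
  p <- sim_params(width = 5, height = 5, n_macrophages = 1, n_fibroblasts = 0,
                  n_steps = 1, amplitude = 0)
  set.seed(2)
  st <- new_simulation_state(p)
  st$cells$row[1] <- 1L; st$cells$col[1] <- 1L
  st$occ[,] <- 0L; st$occ[1, 1] <- 1L
  st$cells$activated[1] <- TRUE

  # a pathogen far from the macrophage survives
  st$pathogens <- list(id = 1L, row = 5L, col = 5L)
  st$occ[5, 5] <- 2L
  st1 <- step_pathogens(st, p)
  expect_equal(length(st1$pathogens$id), 1)

  # adjacent to the macrophage (all its moves blocked too): removed this tick
  st$pathogens <- list(id = 1L, row = 2L, col = 2L)
  st$occ[5, 5] <- 0L; st$occ[2, 2] <- 2L
  blocked <- st
  blocked$occ[1:3, 1:3] <- 2L; blocked$occ[1, 1] <- 1L
  st2 <- step_pathogens(blocked, p)
  expect_equal(length(st2$pathogens$id), 0)

  # spawning at a scheduled peak-phase tick
  p3 <- p; p3$amplitude <- 3; p3$alpha <- 100; p3$replication_period <- 25
  st$tick <- 25L
  st$pathogens <- list(id = integer(0), row = integer(0), col = integer(0))
  st$occ[st$occ == 2L] <- 0L
  st3 <- step_pathogens(st, p3)
  expect_equal(length(st3$pathogens$id), 3)
  expect_true(all(st3$occ[(st3$pathogens$col - 1) * 5 + st3$pathogens$row] == 2L))
})

test_that("an empty quiescent tissue is invariant under a tick", {
  p <- sim_params(width = 6, height = 6, n_macrophages = 0, n_fibroblasts = 0,
                  n_steps = 1, amplitude = 0, p_mitosis = 0)
  set.seed(1)
  st <- new_simulation_state(p)
  st1 <- sim_step(st, p)
  expect_equal(st1$tick, 1L)
  st1$tick <- st$tick
  expect_equal(st1, st)
})

test_that("seeded runs are reproducible and seeds matter", {
  p <- scaled_params(n_steps = 120, strain = 0.4)
  a <- simulate_inflammation(p, seed = 11)
  b <- simulate_inflammation(p, seed = 11)
  d <- simulate_inflammation(p, seed = 12)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$timecourse, b$timecourse)
  expect_false(identical(a$tracks, d$tracks))
})

test_that("occupancy, motile-count conservation and timer invariants hold", {
  p <- scaled_params(width = 20, height = 20, n_macrophages = 8,
                     n_fibroblasts = 8, n_steps = 300, strain = 0.8)
  sim <- simulate_inflammation(p, seed = 5)
  # motile cells are conserved
  expect_true(all(table(sim$tracks$t) == 16))
  # no two motile cells share a site; pathogens never share with motile cells
  for (tt in seq(0, 300, by = 10)) {
    tr <- sim$tracks[sim$tracks$t == tt, ]
    sites <- paste(tr$row, tr$col)
    expect_false(any(duplicated(sites)))
    pp <- sim$pathogen_positions[[tt + 1]]
    if (nrow(pp) > 0) {
      expect_false(any(paste(pp[, 1], pp[, 2]) %in% sites))
      expect_false(any(duplicated(paste(pp[, 1], pp[, 2]))))
    }
  }
  # track continuity: consecutive positions differ by at most one Moore step
  mv <- sim$tracks |>
    dplyr::arrange(.data$cell_id, .data$t) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(ok = all(pmax(abs(diff(row)), abs(diff(col))) <= 1))
  expect_true(all(mv$ok))
  # timers only on healing/fibrosis sites
  fs <- sim$final_state
  expect_true(all(fs$timer[!(fs$epithelium %in% c(2L, 3L))] == 0L))
  expect_true(all(fs$timer <= p$th))
})

test_that("raising strain raises the expected peak injury (directional)", {
  peaks <- sapply(c(0, 0.8), function(s) {
    median(sapply(1:6, function(seed) {
      p <- scaled_params(width = 25, height = 25, n_macrophages = 6,
                         n_fibroblasts = 6, n_steps = 400, strain = s,
                         amplitude = 0)
      max(simulate_inflammation(p, seed = seed)$timecourse$inflammation_score)
    }))
  })
  expect_gt(peaks[2], peaks[1])
  expect_equal(peaks[1], 0)  # no stimulus, no injury
})
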