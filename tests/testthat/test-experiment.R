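tiny_plan <- function(case = "A", trials = 2, strains = c(0, 0.8), seed_base = 3) {
  experiment_plan(case, strain_levels = strains, trials = trials,
                  seed_base = seed_base,
                  params = scaled_params(width = 20, height = 20,
                                         n_macrophages = 4, n_fibroblasts = 4,
                                         n_steps = 250))
}

test_that("a small experiment emits complete, reproducible tables", {
  plan <- tiny_plan()
  res <- run_experiment(plan, window = 100, step = 50)
  expect_s3_class(res, "experiment_result")
  expect_equal(sort(unique(res$timecourses$strain)), c(0, 0.8))
  expect_equal(nrow(res$timecourses), 2 * 2 * 251)
  expect_true(all(c("fc", "mc", "fc_mc") %in% names(res$fc_mc)))
  expect_equal(nrow(res$aggregates), 2 * 251)
  expect_true(all(res$aggregates$pathogen_sd >= 0))

  res2 <- run_experiment(tiny_plan(), window = 100, step = 50)
  expect_identical(res$timecourses, res2$timecourses)
  expect_identical(res$fc_mc, res2$fc_mc)
})

test_that("aggregates equal direct recomputation from the per-trial series", {
  res <- run_experiment(tiny_plan(trials = 3, strains = 0.4), compute_te = FALSE)
  direct <- res$timecourses |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(m = mean(.data$pathogen_count),
                     s = stats::sd(.data$pathogen_count),
                     sc = mean(.data$inflammation_score))
  agg <- dplyr::arrange(res$aggregates, .data$t)
  expect_equal(agg$pathogen_mean, direct$m)
  expect_equal(agg$pathogen_sd, direct$s)
  expect_equal(agg$score_mean, direct$sc)
})

test_that("case B with no strain is a true null: no pathogens, no injury", {
  plan <- experiment_plan("B", strain_levels = 0, trials = 2, seed_base = 1,
                          params = scaled_params(width = 20, height = 20,
                                                 n_macrophages = 4,
                                                 n_fibroblasts = 4,
                                                 n_steps = 200))
  expect_equal(plan$params$amplitude, 0)
  res <- run_experiment(plan, compute_te = FALSE)
  expect_true(all(res$timecourses$pathogen_count == 0))
  expect_true(all(res$timecourses$inflammation_score == 0))
})

test_that("trend classification matches least squares on the second half", {
  expect_equal(as.character(sd_trend(rep(0, 20))), "flat")
  expect_equal(as.character(sd_trend(seq(0, 5, length.out = 40))), "increasing")
  # rises in the first half, falls in the second: classified by the second half
  x <- c(seq(0, 10, length.out = 30), seq(10, 2, length.out = 30))
  tr <- sd_trend(x)
  expect_equal(as.character(tr), "decreasing")
  # slope agrees with an explicit lm fit on the second half
  t <- seq_along(x)
  half <- t >= t[1] + (t[60] - t[1]) / 2
  expect_equal(attr(tr, "slope"),
               unname(coef(lm(x[half] ~ t[half]))[2]))
  expect_error(sd_trend(1:3), "too short")
})

test_that("recovery onset finds the smoothed peak", {
  # noiseless triangle peaking at tick 300
  x <- c(seq(0, 1, length.out = 301), seq(1, 0.2, length.out = 400)[-1])
  tc <- tibble::tibble(t = seq_along(x) - 1, inflammation_score = x)
  expect_equal(recovery_onset(tc), 300, tolerance = 2)
  # smoothing ignores a one-tick spike
  y <- c(rep(0.5, 100), 5, rep(0.5, 99), seq(0.5, 1, length.out = 200),
         seq(1, 0, length.out = 300))
  expect_gt(recovery_onset(y, smooth_window = 50), 250)
})

test_that("tidy and glance summarise runs and experiments", {
  sim <- simulate_inflammation(scaled_params(width = 20, height = 20,
                                             n_macrophages = 4,
                                             n_fibroblasts = 4,
                                             n_steps = 150, strain = 0.8),
                               seed = 2)
  expect_identical(tidy(sim), sim$timecourse)
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_equal(g$peak_score, max(sim$timecourse$inflammation_score))

  res <- run_experiment(tiny_plan(trials = 2), compute_te = FALSE)
  ge <- glance(res)
  expect_equal(nrow(ge), 2)
  expect_true(all(ge$pathogen_sd_trend %in% c("increasing", "decreasing", "flat")))
})
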