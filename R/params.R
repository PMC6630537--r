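#' Simulation parameters
#'
#' Collects every tunable of the inflammation model in one validated object.
#' Defaults reproduce the full-scale study conditions: a 100 x 100 tissue
#' patch, 50 macrophages and 50 fibroblasts, 8000 ticks, pathogen schedule
#' amplitude `A = 1` with rate constant `alpha = 25`, and a uniform mechanical
#' strain `s` in `[0, 1]` applied over the whole grid. See
#' [scaled_params()] for the reduced profile used in fast test runs.
#'
#' @param width,height Grid extent in sites.
#' @param n_macrophages,n_fibroblasts Motile cell counts; motile cells are
#'   conserved over a run (no birth or death).
#' @param strain Uniform strain scalar `s` in `[0, 1]`.
#' @param n_steps Run length in ticks.
#' @param beta_a,beta_b Shape parameters of the beta CDF mapping local TNF to
#'   per-tick apoptosis probability.
#' @param tnf_ref TNF concentration at which apoptosis probability saturates
#'   at 1 (the beta CDF is evaluated at `min(tnf / tnf_ref, 1)`).
#' @param th Healing and fibrosis duration, in ticks.
#' @param p_mitosis Per-tick probability that a dead epithelial site revives
#'   by mitosis (`Pmt`).
#' @param strain_act Macrophage activation probability per tick per unit
#'   strain; the per-tick activation probability is `min(strain_act * s, 1)`.
#' @param secrete_theta_tnf,secrete_theta_tgf Saturation scales of the
#'   secretion rules: an activated macrophage secretes TNF with probability
#'   `clamp(1 - tgf_local / secrete_theta_tgf, 0, 1)` (secretion suppressed by
#'   local TGF), a fibroblast secretes TGF with probability
#'   `clamp(1 - tnf_local / secrete_theta_tnf, 0, 1)`.
#' @param secrete_amount Concentration deposited per secretion event.
#' @param amplitude Pathogen schedule amplitude `A` (count).
#' @param alpha Pathogen schedule rate constant: the spawn count at a
#'   replication tick `t` is `round(max(0, A * sin(2 * pi * t / alpha)))`.
#' @param replication_period Ticks between pathogen replication events. The
#'   default 40 is deliberately incommensurate with the default `alpha = 25`
#'   so sampled phases cycle through the sine wave rather than sitting on a
#'   zero crossing.
#' @param D,K Baseline cytokine diffusion and dissolution constants; the
#'   model assumes `D > K`.
#' @param D_tnf,D_tgf,K_tnf,K_tgf Per-cytokine overrides of `D` and `K`
#'   (`NULL` means "use the baseline"). By default TGF dissolves more slowly
#'   than TNF (`K_tgf = 0.002` vs `K_tnf = K = 0.01`), reflecting the longer
#'   biological half-life of TGF relative to TNF: the pro-inflammatory signal
#'   is sharp and short-ranged, the anti-inflammatory one accumulates and
#'   reaches further, which is what lets the tissue resolve the episode.
#' @param dt Tick length for the field solver; fixed at 1 in the simulator.
#' @param move_epsilon Small weight added to every movement candidate so that
#'   a zero cytokine field gives an unbiased random walk.
#' @param move_neighborhood Candidate move set for motile cells: `"moore"`
#'   (8 directions plus stay, the default) or `"neumann"` (4 plus stay).
#' @param fibrosis_neighborhood Neighbourhood used for the fibrosis-adjacency
#'   death rule, `"moore"` or `"neumann"`.
#' @param fibrosis_damage When fibrosis damages its neighbours:
#'   `"on_creation"` (default) draws each adjacent live cell's death once,
#'   with probability `Nf/Nnei`, at the moment the fibrosis site appears, so a
#'   scar turns on the order of one neighbouring cell dead over its lifetime;
#'   `"per_tick"` repeats the draw every tick the fibrosis site exists, which
#'   makes scarring self-sustaining (chronic-fibrosis regime).
#' @param phagocytosis_requires_activation If `TRUE` (default), only
#'   activated macrophages remove adjacent pathogens, so sustained stimuli
#'   that keep the macrophage pool activated also sustain pathogen clearance;
#'   `FALSE` lets any macrophage phagocytose.
#' @return A validated `sim_params` object (a named list).
#' @examples
#' p <- sim_params(width = 20, height = 20, n_steps = 100)
#' p$strain
#' @export
sim_params <- function(width = 100, height = 100,
                       n_macrophages = 50, n_fibroblasts = 50,
                       strain = 0, n_steps = 8000,
                       beta_a = 2, beta_b = 2, tnf_ref = 1,
                       th = 100, p_mitosis = 0.001, strain_act = 0.01,
                       secrete_theta_tnf = 5, secrete_theta_tgf = 0.5,
                       secrete_amount = 0.5,
                       amplitude = 1, alpha = 25, replication_period = 40,
                       D = 0.2, K = 0.01, dt = 1,
                       D_tnf = NULL, D_tgf = NULL,
                       K_tnf = NULL, K_tgf = 0.002,
                       move_epsilon = 1e-6,
                       move_neighborhood = c("moore", "neumann"),
                       fibrosis_neighborhood = c("moore", "neumann"),
                       fibrosis_damage = c("on_creation", "per_tick"),
                       phagocytosis_requires_activation = TRUE) {
  move_neighborhood <- match.arg(move_neighborhood)
  fibrosis_neighborhood <- match.arg(fibrosis_neighborhood)
  fibrosis_damage <- match.arg(fibrosis_damage)
  p <- list(
    width = as.integer(width), height = as.integer(height),
    n_macrophages = as.integer(n_macrophages),
    n_fibroblasts = as.integer(n_fibroblasts),
    strain = strain, n_steps = as.integer(n_steps),
    beta_a = beta_a, beta_b = beta_b, tnf_ref = tnf_ref,
    th = as.integer(th), p_mitosis = p_mitosis, strain_act = strain_act,
    secrete_theta_tnf = secrete_theta_tnf,
    secrete_theta_tgf = secrete_theta_tgf,
    secrete_amount = secrete_amount,
    amplitude = amplitude, alpha = alpha,
    replication_period = as.integer(replication_period),
    D = D, K = K, dt = dt,
    D_tnf = D_tnf %||% D, D_tgf = D_tgf %||% D,
    K_tnf = K_tnf %||% K, K_tgf = K_tgf %||% K,
    move_epsilon = move_epsilon,
    move_neighborhood = move_neighborhood,
    fibrosis_neighborhood = fibrosis_neighborhood,
    fibrosis_damage = fibrosis_damage,
    phagocytosis_requires_activation = isTRUE(phagocytosis_requires_activation)
  )
  validate_sim_params(structure(p, class = "sim_params"))
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$width < 3 || p$height < 3) rlang::abort("grid must be at least 3 x 3.")
  if (p$n_macrophages < 0 || p$n_fibroblasts < 0) {
    rlang::abort("cell counts must be non-negative.")
  }
  if (p$n_macrophages + p$n_fibroblasts > p$width * p$height) {
    rlang::abort("more motile cells than lattice sites.")
  }
  if (is.na(p$strain) || p$strain < 0 || p$strain > 1) {
    rlang::abort("`strain` must lie in [0, 1].")
  }
  if (p$n_steps < 1) rlang::abort("`n_steps` must be >= 1.")
  if (p$beta_a <= 0 || p$beta_b <= 0) {
    rlang::abort("beta shape parameters must be positive.")
  }
  if (p$tnf_ref <= 0) rlang::abort("`tnf_ref` must be positive.")
  if (p$th < 1) rlang::abort("`th` must be >= 1.")
  for (nm in c("p_mitosis")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) rlang::abort(sprintf("`%s` must lie in [0, 1].", nm))
  }
  if (p$strain_act < 0) rlang::abort("`strain_act` must be >= 0.")
  if (p$secrete_theta_tnf <= 0 || p$secrete_theta_tgf <= 0) {
    rlang::abort("secretion saturation scales must be positive.")
  }
  if (p$secrete_amount < 0) rlang::abort("`secrete_amount` must be >= 0.")
  if (p$amplitude < 0) rlang::abort("pathogen amplitude `A` must be >= 0.")
  if (p$alpha <= 0) rlang::abort("`alpha` must be positive.")
  if (p$replication_period < 1) rlang::abort("`replication_period` must be >= 1.")
  if (p$D_tnf < 0 || p$D_tgf < 0 || p$K_tnf < 0 || p$K_tgf < 0) {
    rlang::abort("`D` and `K` must be non-negative.")
  }
  if (max(p$D_tnf, p$D_tgf) * p$dt > 0.25) {
    rlang::abort(sprintf(
      "explicit diffusion scheme unstable: D * dt = %.3f exceeds 0.25",
      max(p$D_tnf, p$D_tgf) * p$dt))
  }
  if (p$D_tnf <= p$K_tnf || p$D_tgf <= p$K_tgf) {
    rlang::warn("model assumption D > K violated: cytokines will decay faster than they spread.")
  }
  p
}

#' Reduced-scale simulation profile
#'
#' The profile used throughout the test suite and worked examples: a 50 x 50
#' grid, 20 macrophages and 20 fibroblasts, 2000 ticks. The motile-cell count
#' keeps both node classes of the communication network well populated while
#' the 400-pair transfer-entropy matrix stays cheap per window; all rule
#' parameters are the full-scale defaults.
#'
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
scaled_params <- function(...) {
  args <- utils::modifyList(
    list(width = 50, height = 50, n_macrophages = 20, n_fibroblasts = 20,
         n_steps = 2000),
    list(...))
  do.call(sim_params, args)
}

#' Read simulation parameters from a YAML or JSON config file
#'
#' The file holds a flat mapping whose keys are [sim_params()] argument
#' names; omitted keys take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `sim_params` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      rlang::abort("reading JSON configs requires the jsonlite package.")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      rlang::abort("reading YAML configs requires the yaml package.")
    }
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), names(formals(sim_params)))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(sim_params, cfg)
}
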