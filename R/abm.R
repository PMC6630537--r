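#' @importFrom stats pbeta runif quantile coef lm median
NULL

# Epithelial state codes used in the state matrices.
EP_ALIVE <- 0L
EP_DEAD <- 1L
EP_HEALING <- 2L
EP_FIBROSIS <- 3L

#' Epithelial state labels
#'
#' Integer codes used in the epithelium matrix of a simulation state, in
#' order: alive (0), dead (1), healing (2), fibrosis (3).
#' @return A named integer vector.
#' @export
epithelial_states <- function() {
  c(alive = EP_ALIVE, dead = EP_DEAD, healing = EP_HEALING, fibrosis = EP_FIBROSIS)
}

# Cached per-geometry lattice tables (neighbour index lists, neighbour counts).
.precomp_cache <- new.env(parent = emptyenv())

get_precomp <- function(nr, nc) {
  key <- paste0(nr, "x", nc)
  pc <- .precomp_cache[[key]]
  if (is.null(pc)) {
    pc <- list(
      moore_idx = build_neighbor_index(nr, nc, .moore_offsets),
      neumann_idx = build_neighbor_index(nr, nc, .neumann_offsets),
      moore_cnt = neighbor_count(nr, nc, .moore_offsets),
      neumann_cnt = neighbor_count(nr, nc, .neumann_offsets)
    )
    .precomp_cache[[key]] <- pc
  }
  pc
}

#' Per-tick apoptosis probability from local TNF
#'
#' Higher local TNF increases the chance of epithelial apoptosis. The
#' likelihood is the beta cumulative distribution function with shapes
#' `(beta_a, beta_b)` evaluated at `min(tnf_local / tnf_ref, 1)`: zero at zero
#' TNF, saturating at 1 once TNF reaches the reference scale, and monotonically
#' non-decreasing in between.
#'
#' @param tnf_local Non-negative local TNF concentration(s); vectorised.
#' @param beta_a,beta_b Beta shape parameters, both positive.
#' @param tnf_ref Saturation concentration.
#' @return Probability vector of the same length as `tnf_local`.
#' @examples
#' apoptosis_probability(c(0, 0.3, 2), beta_a = 1, beta_b = 1)
#' @export
apoptosis_probability <- function(tnf_local, beta_a = 2, beta_b = 2, tnf_ref = 1) {
  if (beta_a <= 0 || beta_b <= 0) rlang::abort("beta shape parameters must be positive.")
  if (tnf_ref <= 0) rlang::abort("`tnf_ref` must be positive.")
  if (any(tnf_local < 0)) rlang::abort("`tnf_local` must be non-negative.")
  pbeta(pmin(tnf_local / tnf_ref, 1), beta_a, beta_b)
}

#' Per-tick death probability from adjacent fibrosis
#'
#' A live epithelial site dies with probability `Nf / Nnei`, where `Nf` is the
#' number of fibrosis sites in its neighbourhood and `Nnei` the total number
#' of (in-bounds) neighbours, so a site fully surrounded by fibrosis dies with
#' certainty.
#'
#' @param row,col Site coordinates (1-based).
#' @param epithelium Integer state matrix using [epithelial_states()] codes.
#' @param neighborhood `"moore"` (8 neighbours) or `"neumann"` (4).
#' @return A single probability.
#' @export
fibrosis_death_probability <- function(row, col, epithelium,
                                       neighborhood = c("moore", "neumann")) {
  neighborhood <- match.arg(neighborhood)
  grid <- grid_spec(ncol(epithelium), nrow(epithelium))
  nb <- if (neighborhood == "moore") {
    moore_neighbors(row, col, grid)
  } else {
    neumann_neighbors(row, col, grid)
  }
  nf <- sum(epithelium[cbind(nb$row, nb$col)] == EP_FIBROSIS)
  nf / nrow(nb)
}

#' Biased random-walk movement weights
#'
#' Candidate moves for a motile cell are its Moore neighbours plus "stay".
#' Each candidate's weight is proportional to the guiding cytokine value at
#' the candidate site plus a small `epsilon` (TNF guides macrophages, TGF
#' guides fibroblasts); candidates occupied by another motile cell or a
#' pathogen get weight zero, "stay" is never blocked. With a uniformly zero
#' field the walk is unbiased; with all moves blocked the cell stays put.
#'
#' @param row,col Current cell position.
#' @param field Guiding cytokine field (numeric matrix).
#' @param blocked Logical matrix, `TRUE` where a site is occupied.
#' @param epsilon Baseline weight added to every candidate.
#' @param neighborhood Candidate move set, `"moore"` or `"neumann"`.
#' @return A tibble with columns `move`, `row`, `col`, `weight` (normalised to
#'   sum 1); the last row is the "stay" candidate.
#' @export
movement_weights <- function(row, col, field, blocked = NULL, epsilon = 1e-6,
                             neighborhood = c("moore", "neumann")) {
  neighborhood <- match.arg(neighborhood)
  grid <- grid_spec(ncol(field), nrow(field))
  nb <- if (neighborhood == "moore") {
    moore_neighbors(row, col, grid)
  } else {
    neumann_neighbors(row, col, grid)
  }
  offs <- if (neighborhood == "moore") .moore_offsets else .neumann_offsets
  keep <- (row + offs[, 1]) >= 1 & (row + offs[, 1]) <= grid$height &
    (col + offs[, 2]) >= 1 & (col + offs[, 2]) <= grid$width
  w <- field[cbind(nb$row, nb$col)] + epsilon
  if (!is.null(blocked)) w[blocked[cbind(nb$row, nb$col)]] <- 0
  stay_w <- field[row, col] + epsilon
  out <- tibble::tibble(
    move = c(rownames(offs)[keep], "stay"),
    row = c(nb$row, as.integer(row)),
    col = c(nb$col, as.integer(col)),
    weight = c(w, stay_w)
  )
  tot <- sum(out$weight)
  out$weight <- if (tot > 0) out$weight / tot else c(rep(0, nrow(out) - 1L), 1)
  out
}

#' Pathogen replication schedule
#'
#' Pathogens replicate periodically, emulating inhalation with a fluctuating
#' environmental load: at ticks where `t %% replication_period == 0` the spawn
#' count is `round(max(0, A * sin(2 * pi * t / alpha)))` (negative phases of
#' the sine are rectified to zero spawns); at all other ticks it is zero.
#'
#' @param t Tick (non-negative integer); vectorised.
#' @param amplitude Schedule amplitude `A`.
#' @param alpha Rate constant (the sine period in ticks).
#' @param replication_period Ticks between replication events.
#' @return Integer spawn count(s).
#' @examples
#' pathogen_schedule(0:200, amplitude = 1, alpha = 25, replication_period = 40)
#' @export
pathogen_schedule <- function(t, amplitude = 1, alpha = 25, replication_period = 40) {
  if (any(t < 0)) rlang::abort("`t` must be non-negative.")
  out <- ifelse(
    t %% replication_period == 0,
    round(pmax(0, amplitude * sin(2 * pi * t / alpha))),
    0
  )
  as.integer(out)
}

#' Inflammation score
#'
#' The tissue-level injury readout: the number of dead epithelial sites
#' divided by 1000.
#'
#' @param dead_count Non-negative dead-site count(s); vectorised.
#' @return Numeric score(s).
#' @export
inflammation_score <- function(dead_count) {
  if (any(dead_count < 0)) rlang::abort("`dead_count` must be non-negative.")
  dead_count / 1000
}

#' Initialise a simulation state
#'
#' Builds the multi-layer state at tick 0: all epithelial sites alive, both
#' cytokine fields zero, macrophages and fibroblasts placed on distinct
#' uniformly random sites (consuming the current RNG stream), no pathogens.
#'
#' @param params A [sim_params()] object.
#' @return A `sim_state` list (epithelium, timers, `tnf`/`tgf` fields, motile
#'   cells, pathogens, occupancy, tick counter).
#' @export
new_simulation_state <- function(params) {
  nr <- params$height; nc <- params$width
  n_cells <- params$n_macrophages + params$n_fibroblasts
  occ <- matrix(0L, nr, nc)
  lin <- sample.int(nr * nc, n_cells)
  occ[lin] <- 1L
  kind <- rep(c(1L, 2L), c(params$n_macrophages, params$n_fibroblasts))
  state <- list(
    tick = 0L,
    epithelium = matrix(EP_ALIVE, nr, nc),
    timer = matrix(0L, nr, nc),
    tnf = matrix(0, nr, nc),
    tgf = matrix(0, nr, nc),
    cells = list(
      id = seq_len(n_cells),
      kind = kind,
      row = ((lin - 1L) %% nr) + 1L,
      col = ((lin - 1L) %/% nr) + 1L,
      activated = rep(FALSE, n_cells)
    ),
    pathogens = list(id = integer(0), row = integer(0), col = integer(0)),
    occ = occ,
    next_pathogen_id = 1L
  )
  structure(state, class = "sim_state")
}

# ---- per-tick sub-steps ------------------------------------------------------
# All sub-steps are pure (state in, state out) and consume the global RNG in a
# fixed order so a seeded run is bit-reproducible.

#' Activation and stochastic cytokine secretion
#'
#' Macrophages latch to the activated state when a pathogen occupies their
#' Moore neighbourhood or by a strain draw with probability
#' `min(strain_act * s, 1)`; activated macrophages secrete TNF with probability
#' `clamp(1 - tgf_local / secrete_theta_tgf, 0, 1)`. Fibroblasts latch to
#' activated when local TNF is positive and secrete TGF with probability
#' `clamp(1 - tnf_local / secrete_theta_tnf, 0, 1)`. Each secretion deposits
#' `secrete_amount` at the cell's own site.
#'
#' @param state A `sim_state`.
#' @param params A [sim_params()] object.
#' @return The updated state.
#' @export
activation_and_secretion <- function(state, params) {
  nr <- params$height
  cells <- state$cells
  n <- length(cells$id)
  if (n == 0L) return(state)
  lin <- (cells$col - 1L) * nr + cells$row

  pat_adj <- if (length(state$pathogens$id) > 0) {
    pat <- matrix(0, nr, params$width)
    pat[(state$pathogens$col - 1L) * nr + state$pathogens$row] <- 1
    neighbor_sum(pat, .moore_offsets) > 0
  } else {
    matrix(FALSE, nr, params$width)
  }

  m <- which(cells$kind == 1L)
  if (length(m) > 0) {
    p_act <- min(params$strain_act * params$strain, 1)
    strain_hit <- runif(length(m)) < p_act
    cells$activated[m] <- cells$activated[m] | pat_adj[lin[m]] | strain_hit
    act <- m[cells$activated[m]]
    if (length(act) > 0) {
      p_sec <- pmin(pmax(1 - state$tgf[lin[act]] / params$secrete_theta_tgf, 0), 1)
      sec <- act[runif(length(act)) < p_sec]
      state$tnf[lin[sec]] <- state$tnf[lin[sec]] + params$secrete_amount
    }
  }

  f <- which(cells$kind == 2L)
  if (length(f) > 0) {
    cells$activated[f] <- cells$activated[f] | (state$tnf[lin[f]] > 0)
    act <- f[cells$activated[f]]
    if (length(act) > 0) {
      p_sec <- pmin(pmax(1 - state$tnf[lin[act]] / params$secrete_theta_tnf, 0), 1)
      sec <- act[runif(length(act)) < p_sec]
      state$tgf[lin[sec]] <- state$tgf[lin[sec]] + params$secrete_amount
    }
  }

  state$cells <- cells
  state
}

# Biased random-walk movement with collision avoidance. Macrophages move
# first, then fibroblasts; within a kind the update order is shuffled by the
# seeded generator. Cells move one at a time against the live occupancy map.
move_motile_cells <- function(state, params, pc) {
  nr <- params$height
  cells <- state$cells
  occ <- state$occ
  eps <- params$move_epsilon
  idx_list <- if (params$move_neighborhood == "moore") pc$moore_idx else pc$neumann_idx
  for (kind in 1:2) {
    members <- which(cells$kind == kind)
    if (length(members) == 0L) next
    ord <- members[sample.int(length(members))]
    field <- if (kind == 1L) state$tnf else state$tgf
    for (i in ord) {
      lin <- (cells$col[i] - 1L) * nr + cells$row[i]
      cand <- idx_list[[lin]]
      w <- field[cand] + eps
      w[occ[cand] != 0L] <- 0
      stay_w <- field[lin] + eps
      tot <- sum(w) + stay_w
      if (tot <= 0) next
      u <- runif(1) * tot
      j <- findInterval(u, cumsum(c(w, stay_w))) + 1L
      if (j <= length(cand)) {
        dest <- cand[j]
        occ[lin] <- 0L
        occ[dest] <- 1L
        cells$row[i] <- ((dest - 1L) %% nr) + 1L
        cells$col[i] <- ((dest - 1L) %/% nr) + 1L
      }
    }
  }
  state$cells <- cells
  state$occ <- occ
  state
}

#' Pathogen movement, phagocytosis and replication
#'
#' Each pathogen moves to a uniformly random unblocked Moore neighbour (stays
#' if all are blocked), then any pathogen with a macrophage in its Moore
#' neighbourhood is removed (phagocytosis), then the replication schedule
#' ([pathogen_schedule()]) spawns new pathogens on uniformly random unoccupied
#' sites.
#'
#' @inheritParams activation_and_secretion
#' @return The updated state.
#' @export
step_pathogens <- function(state, params) {
  pc <- get_precomp(params$height, params$width)
  step_pathogens_(state, params, pc)
}

step_pathogens_ <- function(state, params, pc) {
  nr <- params$height; nc <- params$width
  occ <- state$occ
  pg <- state$pathogens
  n_p <- length(pg$id)
  if (n_p > 0) {
    for (i in seq_len(n_p)) {
      lin <- (pg$col[i] - 1L) * nr + pg$row[i]
      cand <- pc$moore_idx[[lin]]
      free <- cand[occ[cand] == 0L]
      if (length(free) > 0) {
        dest <- free[sample.int(length(free), 1L)]
        occ[lin] <- 0L
        occ[dest] <- 2L
        pg$row[i] <- ((dest - 1L) %% nr) + 1L
        pg$col[i] <- ((dest - 1L) %/% nr) + 1L
      }
    }
    cells <- state$cells
    hunters <- if (params$phagocytosis_requires_activation) {
      cells$kind == 1L & cells$activated
    } else {
      cells$kind == 1L
    }
    mac <- matrix(0, nr, nc)
    mac[(cells$col[hunters] - 1L) * nr + cells$row[hunters]] <- 1
    mac_adj <- neighbor_sum(mac, .moore_offsets) > 0
    plin <- (pg$col - 1L) * nr + pg$row
    eaten <- mac_adj[plin]
    if (any(eaten)) {
      occ[plin[eaten]] <- 0L
      pg <- list(id = pg$id[!eaten], row = pg$row[!eaten], col = pg$col[!eaten])
    }
  }
  n_spawn <- pathogen_schedule(state$tick, params$amplitude, params$alpha,
                               params$replication_period)
  if (n_spawn > 0) {
    free <- which(occ == 0L)
    n_spawn <- min(n_spawn, length(free))
    if (n_spawn > 0) {
      pick <- free[sample.int(length(free), n_spawn)]
      occ[pick] <- 2L
      ids <- state$next_pathogen_id + seq_len(n_spawn) - 1L
      pg <- list(
        id = c(pg$id, ids),
        row = c(pg$row, ((pick - 1L) %% nr) + 1L),
        col = c(pg$col, ((pick - 1L) %/% nr) + 1L)
      )
      state$next_pathogen_id <- state$next_pathogen_id + n_spawn
    }
  }
  state$pathogens <- pg
  state$occ <- occ
  state
}

#' Epithelial state transitions for one tick
#'
#' Applies, in order: (i) TNF-driven apoptosis draws on live sites
#' ([apoptosis_probability()]); (ii) fibrosis-adjacency death draws
#' (`Nf / Nnei`); (iii) dead sites with at least one fibroblast in their Moore
#' neighbourhood enter healing with timer `th`; (iv) healing countdown, and on
#' expiry the site revives and one uniformly random Moore neighbour becomes a
#' fibrosis site with timer `th`; (v) fibrosis countdown, reverting to alive on
#' expiry; (vi) dead sites revive with mitosis probability `p_mitosis`. Draws
#' consume the seeded generator in ascending site order.
#'
#' @inheritParams activation_and_secretion
#' @return The updated state.
#' @export
step_epithelium <- function(state, params) {
  pc <- get_precomp(params$height, params$width)
  step_epithelium_(state, params, pc)
}

step_epithelium_ <- function(state, params, pc) {
  nr <- params$height; nc <- params$width
  ep <- state$epithelium
  tm <- state$timer

  # (i) apoptosis by TNF
  alive <- which(ep == EP_ALIVE)
  if (length(alive) > 0) {
    pr <- apoptosis_probability(state$tnf[alive], params$beta_a, params$beta_b,
                                params$tnf_ref)
    die <- alive[runif(length(alive)) < pr]
    ep[die] <- EP_DEAD
  }

  # (ii) death by adjacent fibrosis (per-tick variant; the default applies
  # the damage draw once, when a fibrosis site appears — see (iv))
  offs <- if (params$fibrosis_neighborhood == "moore") .moore_offsets else .neumann_offsets
  cnt <- if (params$fibrosis_neighborhood == "moore") pc$moore_cnt else pc$neumann_cnt
  if (params$fibrosis_damage == "per_tick") {
    nf <- neighbor_sum((ep == EP_FIBROSIS) * 1, offs)
    alive <- which(ep == EP_ALIVE & nf > 0)
    if (length(alive) > 0) {
      die <- alive[runif(length(alive)) < nf[alive] / cnt[alive]]
      ep[die] <- EP_DEAD
    }
  }

  # (iii) healing starts where a fibroblast is adjacent to a dead site
  cells <- state$cells
  fsel <- cells$kind == 2L
  if (any(fsel)) {
    fb <- matrix(0, nr, nc)
    fb[(cells$col[fsel] - 1L) * nr + cells$row[fsel]] <- 1
    fb_adj <- neighbor_sum(fb, .moore_offsets) > 0
    start <- which(ep == EP_DEAD & fb_adj)
    ep[start] <- EP_HEALING
    tm[start] <- params$th
  }

  # (iv) healing countdown; on expiry the sites revive and each connected
  # neighbourhood of simultaneously healed sites designates one uniformly
  # random member as a fibrosis site
  healing <- which(ep == EP_HEALING)
  if (length(healing) > 0) {
    tm[healing] <- tm[healing] - 1L
    done <- healing[tm[healing] == 0L]
    if (length(done) > 0) {
      ep[done] <- EP_ALIVE
      for (comp in split_components(done, nr, nc)) {
        pick <- comp[sample.int(length(comp), 1L)]
        ep[pick] <- EP_FIBROSIS
        tm[pick] <- params$th
        if (params$fibrosis_damage == "on_creation") {
          # the new stiff site damages its surroundings once: each live
          # neighbour dies with probability Nf/Nnei from its own vantage
          nb <- if (params$fibrosis_neighborhood == "moore") {
            pc$moore_idx[[pick]]
          } else {
            pc$neumann_idx[[pick]]
          }
          nb <- nb[ep[nb] == EP_ALIVE]
          for (v in nb) {
            vr <- ((v - 1L) %% nr) + 1L
            vc <- ((v - 1L) %/% nr) + 1L
            rr <- vr + offs[, 1L]
            cc <- vc + offs[, 2L]
            ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
            nf_v <- sum(ep[(cc[ok] - 1L) * nr + rr[ok]] == EP_FIBROSIS)
            if (runif(1) < nf_v / sum(ok)) ep[v] <- EP_DEAD
          }
        }
      }
    }
  }

  # (v) fibrosis countdown
  fibs <- which(ep == EP_FIBROSIS & tm > 0L)
  if (length(fibs) > 0) {
    tm[fibs] <- tm[fibs] - 1L
    gone <- fibs[tm[fibs] == 0L]
    ep[gone] <- EP_ALIVE
  }

  # (vi) mitosis
  dead <- which(ep == EP_DEAD)
  if (length(dead) > 0 && params$p_mitosis > 0) {
    revive <- dead[runif(length(dead)) < params$p_mitosis]
    ep[revive] <- EP_ALIVE
  }

  state$epithelium <- ep
  state$timer <- tm
  state
}

#' Advance the simulation one tick
#'
#' Applies the model layers in fixed order: diffusion and decay of both
#' cytokine fields, activation and secretion, motile movement (macrophages
#' then fibroblasts, shuffled within kind), pathogen movement / phagocytosis /
#' replication, epithelial transitions; then increments the tick counter.
#'
#' @inheritParams activation_and_secretion
#' @return The state one tick later.
#' @export
sim_step <- function(state, params) {
  pc <- get_precomp(params$height, params$width)
  sim_step_(state, params, pc)
}

sim_step_ <- function(state, params, pc) {
  cnt <- pc$neumann_cnt
  state$tnf <- diffuse_decay(state$tnf, params$D_tnf, params$K_tnf, params$dt, cnt)
  state$tgf <- diffuse_decay(state$tgf, params$D_tgf, params$K_tgf, params$dt, cnt)
  state <- activation_and_secretion(state, params)
  state <- move_motile_cells(state, params, pc)
  state <- step_pathogens_(state, params, pc)
  state <- step_epithelium_(state, params, pc)
  state$tick <- state$tick + 1L
  state
}

# Partition a set of lattice sites (linear indices) into Moore-connected
# components; components are returned in ascending order of their first site
# so the downstream draws are reproducible.
split_components <- function(lin, nr, nc) {
  lin <- sort(lin)
  n <- length(lin)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    comp[i] <- cur
    queue <- i
    while (length(queue) > 0) {
      j <- queue[1L]
      queue <- queue[-1L]
      r <- ((lin[j] - 1L) %% nr) + 1L
      c <- ((lin[j] - 1L) %/% nr) + 1L
      rr <- r + .moore_offsets[, 1L]
      cc <- c + .moore_offsets[, 2L]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      hit <- match((cc[ok] - 1L) * nr + rr[ok], lin)
      hit <- hit[!is.na(hit)]
      new <- hit[comp[hit] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  unname(split(lin, comp))
}

# FTCS diffusion + decay with a precomputed neighbour-count matrix.
diffuse_decay <- function(field, D, K, dt, cnt) {
  out <- field + D * dt *
    (neighbor_sum(field, .neumann_offsets) - cnt * field)
  out <- out * (1 - K * dt)
  out[out < 0] <- 0
  out
}

#' Run a seeded inflammation simulation
#'
#' Initialises the tissue and advances it `n_steps` ticks, recording every
#' motile cell's position at every tick (the tracks table feeding the
#' communication-inference pipeline), the per-tick injury and pathogen counts,
#' and the pathogen positions (for occupancy audits). Identical `params` and
#' `seed` give a bit-identical result.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed for the run.
#' @return An `inflam_sim` object: a list with
#'   \describe{
#'     \item{tracks}{tibble `cell_id`, `kind` (`"macrophage"`/`"fibroblast"`),
#'       `t` (0..`n_steps`), `row`, `col`.}
#'     \item{timecourse}{tibble `t`, `dead_count`, `inflammation_score`,
#'       `pathogen_count` (one row per tick, starting at `t = 0`).}
#'     \item{pathogen_positions}{list of per-tick matrices of pathogen sites.}
#'     \item{final_state}{the `sim_state` at the last tick.}
#'     \item{params, seed}{the inputs.}
#'   }
#' @examples
#' sim <- simulate_inflammation(sim_params(width = 20, height = 20,
#'   n_macrophages = 4, n_fibroblasts = 4, n_steps = 50, strain = 0.5), seed = 1)
#' sim$timecourse
#' @export
simulate_inflammation <- function(params, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  pc <- get_precomp(params$height, params$width)
  state <- new_simulation_state(params)
  n_cells <- length(state$cells$id)
  n_t <- params$n_steps + 1L

  rows <- matrix(0L, n_cells, n_t)
  cols <- matrix(0L, n_cells, n_t)
  dead <- integer(n_t)
  n_path <- integer(n_t)
  path_pos <- vector("list", n_t)

  record <- function(k) {
    rows[, k] <<- state$cells$row
    cols[, k] <<- state$cells$col
    dead[k] <<- sum(state$epithelium == EP_DEAD)
    n_path[k] <<- length(state$pathogens$id)
    path_pos[[k]] <<- cbind(row = state$pathogens$row, col = state$pathogens$col)
  }
  record(1L)
  for (t in seq_len(params$n_steps)) {
    state <- sim_step_(state, params, pc)
    record(t + 1L)
  }

  kind_chr <- c("macrophage", "fibroblast")[state$cells$kind]
  tracks <- tibble::tibble(
    cell_id = rep(state$cells$id, each = n_t),
    kind = rep(kind_chr, each = n_t),
    t = rep(0:params$n_steps, times = n_cells),
    row = as.integer(t(rows)),
    col = as.integer(t(cols))
  )
  timecourse <- tibble::tibble(
    t = 0:params$n_steps,
    dead_count = dead,
    inflammation_score = inflammation_score(dead),
    pathogen_count = n_path
  )
  structure(
    list(tracks = tracks, timecourse = timecourse,
         pathogen_positions = path_pos, final_state = state,
         params = params, seed = as.integer(seed)),
    class = "inflam_sim"
  )
}

#' @export
print.inflam_sim <- function(x, ...) {
  tc <- x$timecourse
  cat(sprintf(
    "<inflam_sim> %d x %d grid, %d macrophages + %d fibroblasts, %d ticks (seed %d)\n",
    x$params$height, x$params$width, x$params$n_macrophages,
    x$params$n_fibroblasts, x$params$n_steps, x$seed))
  cat(sprintf("  strain s = %.2f, pathogen amplitude A = %g\n",
              x$params$strain, x$params$amplitude))
  cat(sprintf("  peak inflammation score %.3f at tick %d; final score %.3f\n",
              max(tc$inflammation_score), tc$t[which.max(tc$inflammation_score)],
              tc$inflammation_score[nrow(tc)]))
  invisible(x)
}
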