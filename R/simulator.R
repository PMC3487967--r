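#' Default simulation configuration
#'
#' Nested list of every model parameter, fully overridable via
#' [load_config()] or the `overrides` argument.  Geometry and timing follow
#' the reference setting: a 200 x 200 lattice of 20 um spacing (a 4-5 mm
#' tissue slice), 1 h steps, a parent vessel column near the left boundary
#' carrying 6 sprout tips, and a small cluster of tumor cells placed
#' center-right.  Field coefficients are expressed in lattice units per hour
#' and are documented stand-ins ordered so that diffusivity ranks
#' oxygen > glucose > VEGF >= TGFalpha; the drug field is in uM.  See the
#' methods vignette for every default and its rationale.
#'
#' @param overrides nested named list merged over the defaults.
#' @return object of class `sim_config`.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    lattice = list(L = 200L, spacing_um = 20, dt = 1),
    horizon = 150,
    treatment_on = FALSE,
    seed = 1L,
    pathway = list(params = list(), initial = list(),
                   rtol = 1e-6, atol = 1e-9, rate_table = ""),
    thresholds = list(glucose_active = 0.5, glucose_dead = 0.4,
                      sigma_plc = 0.011, sigma_mode = "fixed",
                      thr1 = 0.5, thr2 = 0.125, psi = 0.7),
    tki = list(km = 0.033, blood = 1.5),
    pathway_input = list(tgf_scale = 1),
    fields = list(
      glucose     = list(D = 24, r = 0.5, p = 1.6, ublood = 1, U = 0.05,
                         init = 1, dip_amp = 0.1, dip_width = 12),
      oxygen      = list(D = 32, q = 6, ublood = 1, U = 0.08, init = 1),
      tgfa        = list(D = 12, q = 0.1, S = 0.25, delta = 0.02, init = 0),
      vegf        = list(D = 16, q = 0.1, S = 0.5, delta = 0.005, init = 0,
                         halo_amp = 0.1, halo_width = 50),
      fibronectin = list(beta = 0.005, gamma = 0.05, init = 0.3),
      tki         = list(D = 24, q = 5, U = 0.01, delta = 0.001, init = 0)),
    vessel = list(parent_col = 3L, n_tips = 6L, alpha = 5, kv = 1,
                  lambda = 0.05, mode = "generalized", branch_age = 18),
    tumor = list(n_cells = 40L, center_i = 65L, center_j = 100L,
                 radius = 5),
    neighborhood = "moore")
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "sim_config")
}

# recursive merge rejecting unknown keys
merge_config <- function(base, over, path = "") {
  for (nm in names(over)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", paste0(path, nm))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(over[[nm]]))
        stop("configuration key ", paste0(path, nm), " must be a mapping")
      base[[nm]] <- merge_config(base[[nm]], over[[nm]],
                                 paste0(path, nm, "$"))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$lattice$L < 10) stop("lattice$L must be >= 10")
  if (cfg$lattice$dt <= 0) stop("lattice$dt must be > 0")
  if (cfg$horizon %% cfg$lattice$dt != 0)
    stop("horizon must be a multiple of dt")
  if (!cfg$thresholds$sigma_mode %in% c("fixed", "population"))
    stop("thresholds$sigma_mode must be 'fixed' or 'population'")
  if (!cfg$vessel$mode %in% c("literal", "generalized"))
    stop("vessel$mode must be 'literal' or 'generalized'")
  with(cfg$thresholds, {
    if (glucose_dead >= glucose_active)
      stop("glucose_dead must be < glucose_active")
    if (psi <= 0 || psi >= 1) stop("psi must be in (0,1)")
  })
  invisible(cfg)
}

build_spec <- function(cfg) {
  if (nzchar(cfg$pathway$rate_table)) {
    reactions <- read_rate_table(cfg$pathway$rate_table)
    base <- default_pathway()
    p <- base$params; ini <- base$initial
    p[names(cfg$pathway$params)] <- unlist(cfg$pathway$params)
    ini[names(cfg$pathway$initial)] <- unlist(cfg$pathway$initial)
    pathway_spec(base$species, reactions, p, ini)
  } else {
    default_pathway(params = unlist(cfg$pathway$params),
                    initial = unlist(cfg$pathway$initial))
  }
}

build_fields <- function(cfg) {
  L <- cfg$lattice$L
  fc <- cfg$fields
  qG <- 2 * pi * fc$glucose$r * fc$glucose$p   # q_G = 2 pi r p_G
  list(
    glucose = make_field("glucose", glucose_start(cfg), L,
                         D = fc$glucose$D, q = qG,
                         ublood = fc$glucose$ublood, U = fc$glucose$U),
    oxygen = make_field("oxygen", fc$oxygen$init, L, D = fc$oxygen$D,
                        q = fc$oxygen$q, ublood = fc$oxygen$ublood,
                        U = fc$oxygen$U),
    tgfa = make_field("tgfa", fc$tgfa$init, L, D = fc$tgfa$D,
                      q = fc$tgfa$q, S = fc$tgfa$S, delta = fc$tgfa$delta),
    vegf = make_field("vegf", vegf_halo(cfg), L, D = fc$vegf$D,
                      q = fc$vegf$q, S = fc$vegf$S, delta = fc$vegf$delta),
    fibronectin = make_field("fibronectin", fc$fibronectin$init, L,
                             S = fc$fibronectin$beta,
                             U = fc$fibronectin$gamma),
    tki = make_field("tki", fc$tki$init, L, D = fc$tki$D, q = fc$tki$q,
                     ublood = cfg$tki$blood, U = fc$tki$U,
                     delta = fc$tki$delta))
}

# initial glucose profile: the uniform background minus a tumor-centered
# Gaussian dip approximating the quasi-steady depletion left by avascular
# growth before the simulated window (floored at 0.05)
glucose_start <- function(cfg) {
  L <- cfg$lattice$L
  fc <- cfg$fields$glucose
  if (is.null(fc$dip_amp) || fc$dip_amp <= 0) return(matrix(fc$init, L, L))
  d2 <- outer((seq_len(L) - cfg$tumor$center_i)^2,
              (seq_len(L) - cfg$tumor$center_j)^2, `+`)
  pmax(fc$init - fc$dip_amp * exp(-d2 / (2 * fc$dip_width^2)), 0.05)
}

# initial VEGF profile: a pre-angiogenic Gaussian halo centered on the tumor
# cluster (the angiogenic switch precedes the simulated window), on top of a
# uniform background `init`
vegf_halo <- function(cfg) {
  L <- cfg$lattice$L
  fc <- cfg$fields$vegf
  if (fc$halo_amp <= 0) return(matrix(fc$init, L, L))
  d2 <- outer((seq_len(L) - cfg$tumor$center_i)^2,
              (seq_len(L) - cfg$tumor$center_j)^2, `+`)
  fc$init + fc$halo_amp * exp(-d2 / (2 * fc$halo_width^2))
}

#' Initialize a simulation state
#'
#' Seeds the RNG, places the parent vessel with its sprout tips, scatters the
#' initial tumor cluster (uniformly over a disc, one cell per site) with ages
#' drawn uniformly from [0, 24) h, builds the fields at their initial
#' profiles, and takes the hour-0 census.  Each cell's pathway state is the
#' reference initial condition integrated forward by the cell's age under
#' reference ligand exposure, so cell-cycle phases are desynchronized
#' consistently with the random ages.
#'
#' @param config a [default_config()] object.
#' @return a `sim_state` list (clock, fields, population, vessels, masks,
#'   census accumulator, event counters).
#' @export
initialize_simulation <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  L <- config$lattice$L
  spec <- build_spec(config)
  fields <- build_fields(config)

  tip_rows <- as.integer(round(seq(L / 7, L * 6 / 7,
                                   length.out = config$vessel$n_tips)))
  vessels <- new_vessel_network(L, config$vessel$parent_col, tip_rows,
                                hour = 0, alpha = config$vessel$alpha,
                                kv = config$vessel$kv,
                                lambda = config$vessel$lambda)

  # tumor cluster: unique sites in a disc
  tc <- config$tumor
  ii <- seq(max(1, tc$center_i - tc$radius), min(L, tc$center_i + tc$radius))
  jj <- seq(max(1, tc$center_j - tc$radius), min(L, tc$center_j + tc$radius))
  cand <- expand.grid(i = ii, j = jj)
  cand <- cand[(cand$i - tc$center_i)^2 + (cand$j - tc$center_j)^2 <=
                 tc$radius^2, ]
  if (tc$n_cells > 0L && any(vessels$ec[cbind(cand$i, cand$j)] == 1L))
    stop("tumor cluster overlaps the vasculature")
  if (nrow(cand) < tc$n_cells)
    stop("tumor cluster spec does not fit: ", nrow(cand),
         " usable sites for ", tc$n_cells, " cells")
  pick <- cand[sample.int(nrow(cand), tc$n_cells), ]
  ages <- runif(tc$n_cells, 0, 24)

  pop <- new_cell_pop(spec)
  occ <- matrix(0L, L, L)
  tab_ref <- compile_pathway(spec, clamp = "TGFa")
  Y0 <- matrix(rep(unname(spec$initial), tc$n_cells), ncol =
                 length(spec$species), byrow = TRUE)
  # stagger cell-cycle phase by integrating each cell for its age
  for (c in seq_len(tc$n_cells)) {
    out <- pathway_integrate_cpp(Y0[c, , drop = FALSE], tab_ref, ages[c],
                                 config$pathway$rtol, config$pathway$atol,
                                 1e6)
    conc <- setNames(as.numeric(out$y[1, ]), spec$species)
    mp <- out$dy[1, match("PLCg", spec$species)]
    thr0 <- config$thresholds
    ph <- phenotype_switch(fields$glucose$grid[pick$i[c], pick$j[c]],
                           phenotype_thresholds(thr0$glucose_active,
                                                thr0$glucose_dead,
                                                thr0$sigma_plc, thr0$thr1,
                                                thr0$thr2, thr0$psi), mp)
    if (ph == "dead") ph <- "quiescent"   # the seeded cluster starts viable
    pop <- pop_add(pop, pick$i[c], pick$j[c], ages[c], conc, mp, phen = ph)
    occ[pick$i[c], pick$j[c]] <- c
  }

  state <- list(clock = 0, config = config, spec = spec,
                fields = fields, pop = pop, occ = occ, vessels = vessels,
                masks = NULL, census = list(),
                binding = tki_binding(spec$initial[["EGFR"]],
                                      config$tki$km),
                events = list(migration_events = 0L, divisions = 0L,
                              reactivated = 0L, blocked_divisions = 0L,
                              deaths = 0L))
  state$masks <- refresh_masks(state)
  state$census[[1]] <- take_census(state, divisions = 0L, moves = 0L,
                                   reactivated = 0L, blocked = 0L)
  class(state) <- "sim_state"
  state
}

refresh_masks <- function(state) {
  L <- state$config$lattice$L
  x_tum <- matrix(0L, L, L)
  live <- which(state$pop$alive)
  if (length(live))
    x_tum[cbind(state$pop$i[live], state$pop$j[live])] <- 1L
  occupancy_masks(state$vessels$ec, x_tum)
}

take_census <- function(state, divisions, moves, reactivated, blocked) {
  pop <- state$pop
  live <- pop$alive
  data.frame(
    hour = state$clock,
    total = length(pop$i),
    live = sum(live),
    active = sum(live & pop$phen %in% c("migratory", "proliferative",
                                        "active")),
    migratory = sum(live & pop$phen == "migratory"),
    proliferative = sum(live & pop$phen == "proliferative"),
    quiescent = sum(live & pop$phen == "quiescent"),
    dead = sum(!pop$alive),
    ec = ec_count(state$vessels),
    n_tips = nrow(state$vessels$tips),
    mean_plc = if (any(live)) mean(pop$plc[live]) else NA_real_,
    divisions = divisions, migration_events = moves,
    reactivated = reactivated, blocked_divisions = blocked)
}

#' Advance the simulation by one agent step
#'
#' Executes the four scales in the fixed order: (1) field updates (drug field
#' only under treatment), (2) per-cell pathway integration with local
#' TGF\eqn{\alpha} and drug-adjusted effective EGFR, (3) phenotype switching,
#' migration and division in randomized agent order, (4) tip-EC migration,
#' branching and anastomosis in randomized tip order, then mask refresh and
#' census.
#'
#' @param state a `sim_state`.
#' @return the advanced state.
#' @export
sim_step <- function(state) {
  cfg <- state$config
  dt <- cfg$lattice$dt
  state$fields <- stage_fields(state$fields, state$masks, cfg$treatment_on,
                               dt)
  state <- stage_molecular(state, dt)
  state <- stage_cellular(state)
  state <- stage_tissue(state)
  state$clock <- state$clock + dt
  state$masks <- refresh_masks(state)
  state$census[[length(state$census) + 1L]] <-
    take_census(state, state$last_divisions, state$last_moves,
                state$last_reactivated, state$last_blocked)
  state
}

stage_fields <- function(fields, masks, treatment_on, dt) {
  step_all_fields(fields, masks, treatment_on, dt)
}

stage_molecular <- function(state, dt) {
  cfg <- state$config
  live <- which(state$pop$alive)
  if (!length(live)) return(state)
  sites <- cbind(state$pop$i[live], state$pop$j[live])
  tgf <- state$fields$tgfa$grid[sites] * cfg$pathway_input$tgf_scale
  tki <- if (cfg$treatment_on) state$fields$tki$grid[sites] else
    rep(0, length(live))
  egfr_eff <- effective_egfr(state$binding, tki)
  Y <- state$pop$path[live, , drop = FALSE]
  Y[, "TGFa"] <- tgf
  Y[, "EGFR"] <- pmin(Y[, "EGFR"], egfr_eff)
  tab <- compile_pathway(state$spec, clamp = "TGFa")
  out <- pathway_integrate_cpp(Y, tab, dt, cfg$pathway$rtol,
                               cfg$pathway$atol, 1e6)
  bad <- which(out$status != 0L)
  if (length(bad))
    stop("pathway integrator failed at hour ", state$clock,
         " for cell(s) ", paste(live[bad], collapse = ", "))
  state$pop$path[live, ] <- out$y
  state$pop$plc[live] <- out$dy[, match("PLCg", state$spec$species)]
  state$pop$age[live] <- state$pop$age[live] + dt
  state
}

stage_cellular <- function(state) {
  cfg <- state$config
  thr <- cfg$thresholds
  sigma <- if (thr$sigma_mode == "population") {
    lv <- state$pop$alive
    if (any(lv)) mean(state$pop$plc[lv]) else thr$sigma_plc
  } else thr$sigma_plc
  thresholds <- phenotype_thresholds(thr$glucose_active, thr$glucose_dead,
                                     sigma, thr$thr1, thr$thr2, thr$psi)
  spec <- state$spec
  G <- state$fields$glucose$grid
  Fg <- state$fields$fibronectin$grid
  L <- cfg$lattice$L
  cyc <- c("CDh1", "CDh1i", "cycCDK", "Mass")
  cycle_reset <- spec$initial[cyc]
  newborn <- spec$initial
  newborn_plc <- plc_rate_of(spec, newborn, clamp = "TGFa")

  divisions <- 0L; moves <- 0L; reactivated <- 0L; blocked <- 0L
  live <- which(state$pop$alive)
  order <- if (length(live) > 1) sample(live) else live
  for (id in order) {
    if (!state$pop$alive[id]) next
    i <- state$pop$i[id]; j <- state$pop$j[id]
    was_quiescent <- state$pop$phen[id] == "quiescent"
    ph <- phenotype_switch(G[i, j], thresholds, state$pop$plc[id])
    if (ph == "dead") {
      state$pop$alive[id] <- FALSE
      state$pop$phen[id] <- "dead"
      state$events$deaths <- state$events$deaths + 1L
      next
    }
    if (ph == "quiescent") { state$pop$phen[id] <- "quiescent"; next }
    if (was_quiescent) reactivated <- reactivated + 1L
    nb <- lattice_neighbors(i, j, L, type = cfg$neighborhood)
    nbdf <- list(glucose = G[nb], fibronectin = Fg[nb],
                 free = state$occ[nb] == 0L & state$vessels$ec[nb] == 0L)
    if (ph == "migratory") {
      state$pop$phen[id] <- "migratory"
      k <- offspring_site_choice(nbdf, thresholds$psi)
      if (!is.na(k)) {
        res <- cell_migrate(state$pop, state$occ, id, nb[k, ])
        state$pop <- res$pop; state$occ <- res$occ
        moves <- moves + 1L
      }
    } else {
      state$pop$phen[id] <- "proliferative"
      if (state$pop$path[id, "CDh1"] < thresholds$thr1 &&
          state$pop$path[id, "cycCDK"] > thresholds$thr2) {
        k <- offspring_site_choice(nbdf, thresholds$psi)
        if (is.na(k)) {
          state$pop$phen[id] <- "quiescent"   # crowded: wait for space
          blocked <- blocked + 1L
        } else {
          res <- cell_divide(state$pop, state$occ, id, nb[k, ], newborn,
                             newborn_plc, cycle_reset)
          state$pop <- res$pop; state$occ <- res$occ
          divisions <- divisions + 1L
        }
      }
    }
  }
  state$events$migration_events <- state$events$migration_events + moves
  state$events$divisions <- state$events$divisions + divisions
  state$events$reactivated <- state$events$reactivated + reactivated
  state$events$blocked_divisions <- state$events$blocked_divisions + blocked
  state$last_divisions <- divisions; state$last_moves <- moves
  state$last_reactivated <- reactivated; state$last_blocked <- blocked
  state
}

stage_tissue <- function(state) {
  cfg <- state$config
  net <- state$vessels
  x_tum <- state$masks$x_tum
  # act on the tips that exist at stage start, in randomized order;
  # daughters born this step are not re-processed
  ids <- net$tips$tip_id
  if (length(ids) > 1) ids <- sample(ids)
  for (tid in ids) {
    idx <- match(tid, net$tips$tip_id)
    if (is.na(idx)) next                       # retired by an earlier branch
    dist <- tip_migration_distribution(c(net$tips$i[idx], net$tips$j[idx]),
                                       state$fields$vegf,
                                       state$fields$fibronectin, net)
    net <- branch_or_migrate(net, idx, dist, x_tum, state$clock,
                             mode = cfg$vessel$mode)
  }
  state$vessels <- anastomosis(net)
  state
}

#' Run a full simulation
#'
#' @param config a [default_config()] object.
#' @param progress print an INFO line every `progress` hours (0 = quiet).
#' @return list with the final `state`, the per-hour census data frame
#'   `metrics`, and cumulative event counters `events`.
#' @export
run_simulation <- function(config = default_config(), progress = 0) {
  state <- initialize_simulation(config)
  nsteps <- config$horizon / config$lattice$dt
  for (s in seq_len(nsteps)) {
    state <- sim_step(state)
    if (progress > 0 && state$clock %% progress == 0) {
      cen <- state$census[[length(state$census)]]
      message(sprintf("hour %4.0f: live %d active %d quiescent %d dead %d ec %d",
                      cen$hour, cen$live, cen$active, cen$quiescent,
                      cen$dead, cen$ec))
    }
  }
  list(state = state,
       metrics = do.call(rbind, state$census),
       events = state$events)
}
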