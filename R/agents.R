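#' Phenotype thresholds
#'
#' @param glucose_active glucose level above which a cell is active.
#' @param glucose_dead glucose level below which a cell dies
#'   (must be < `glucose_active`).
#' @param sigma_plc migration-potential threshold \eqn{\sigma_{PLC\gamma}}
#'   (concentration/h); a cell with MP strictly greater migrates.
#' @param thr1,thr2 cell-cycle division thresholds on CDh1 and cycCDK.
#' @param psi search precision \eqn{\psi \in (0,1)} weighting the
#'   deterministic glucose/fibronectin score against N(0,1) noise in
#'   offspring/migration site choice.
#' @return object of class `phenotype_thresholds`.
#' @export
phenotype_thresholds <- function(glucose_active, glucose_dead, sigma_plc,
                                 thr1, thr2, psi = 0.7) {
  stopifnot(glucose_dead < glucose_active, psi > 0, psi < 1,
            thr1 > 0, thr2 > 0)
  structure(list(glucose_active = glucose_active, glucose_dead = glucose_dead,
                 sigma_plc = sigma_plc, thr1 = thr1, thr2 = thr2, psi = psi),
            class = "phenotype_thresholds")
}

#' Phenotype switch of a tumor-cell agent
#'
#' Hourly decision rules: glucose below the dead threshold kills the cell;
#' glucose between the dead and active thresholds sends it to (reversible)
#' quiescence; an active cell with migration potential strictly above
#' \eqn{\sigma_{PLC\gamma}} takes the migratory phenotype, otherwise the
#' proliferative track.  Vectorized over cells.
#'
#' @param glucose_local glucose concentration(s) at the cell site(s).
#' @param thresholds a [phenotype_thresholds()].
#' @param mp migration potential(s), d[PLC\eqn{\gamma}]/dt.
#' @return character vector in
#'   `c("dead", "quiescent", "migratory", "proliferative")`.
#' @export
phenotype_switch <- function(glucose_local, thresholds, mp) {
  stopifnot(inherits(thresholds, "phenotype_thresholds"))
  out <- ifelse(glucose_local < thresholds$glucose_dead, "dead",
         ifelse(glucose_local < thresholds$glucose_active, "quiescent",
         ifelse(mp > thresholds$sigma_plc, "migratory", "proliferative")))
  out
}

#' Moore / von Neumann neighborhood of a lattice site
#'
#' @param i,j site indices (1-based).
#' @param L lattice size; off-grid neighbors are dropped.
#' @param type `"moore"` (8 neighbors, default) or `"vonneumann"` (4).
#' @return two-column integer matrix of neighbor coordinates.
#' @export
lattice_neighbors <- function(i, j, L, type = c("moore", "vonneumann")) {
  type <- match.arg(type)
  if (type == "moore") {
    di <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dj <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  } else {
    di <- c(-1L, 1L, 0L, 0L)
    dj <- c(0L, 0L, -1L, 1L)
  }
  ni <- i + di; nj <- j + dj
  keep <- ni >= 1L & ni <= L & nj >= 1L & nj <= L
  cbind(i = ni[keep], j = nj[keep])
}

# fibronectin floor avoiding division by zero in the attractiveness score
F_FLOOR <- 1e-6

#' Choose the most attractive free neighbor site
#'
#' Scores every neighbor `j` as
#' \eqn{P_j = \psi G_j / F_j + (1-\psi)\epsilon_j} with
#' \eqn{\epsilon_j \sim N(0,1)} i.i.d., and returns the index of the
#' highest-scoring FREE site, or `NA` when no neighbor is free (the parent
#' then turns quiescent until space appears).  Fibronectin is floored at
#' 1e-6 to avoid division by zero.
#'
#' @param neighbors data frame or list with elements `glucose`,
#'   `fibronectin`, `free` (parallel vectors over the neighbor sites).
#' @param psi search precision in (0,1).
#' @param eps optional fixed noise vector (length = rows of `neighbors`);
#'   drawn from the RNG stream when `NULL`.
#' @return integer row index into `neighbors`, or `NA_integer_`.
#' @export
offspring_site_choice <- function(neighbors, psi, eps = NULL) {
  stopifnot(psi > 0, psi <= 1)
  g <- neighbors$glucose; f <- neighbors$fibronectin; free <- neighbors$free
  n <- length(g)
  if (n == 0L || !any(free)) return(NA_integer_)
  if (is.null(eps)) eps <- rnorm(n)
  stopifnot(length(eps) == n)
  score <- psi * g / pmax(f, F_FLOOR) + (1 - psi) * eps
  score[!free] <- -Inf
  which.max(score)
}

# ---- cell population container ------------------------------------------
# Column-oriented store: one row per agent ever created (dead rows persist).
# `path` holds one pathway concentration vector per cell, `plc` the cached
# PLCgamma rate (migration potential).  Occupancy is tracked separately as an
# integer matrix (0 = free, else the cell id), one live cell per site.

#' Create an empty cell population
#'
#' @param spec the [pathway_spec()] whose species dimension the per-cell
#'   state matrix uses.
#' @return object of class `cell_pop`.
#' @export
new_cell_pop <- function(spec) {
  structure(list(i = integer(0), j = integer(0), age = numeric(0),
                 phen = character(0), alive = logical(0),
                 path = matrix(numeric(0), 0, length(spec$species),
                               dimnames = list(NULL, spec$species)),
                 plc = numeric(0)),
            class = "cell_pop")
}

#' @rdname new_cell_pop
#' @param pop a `cell_pop`.
#' @param i,j lattice site.
#' @param age hours since birth.
#' @param conc named pathway concentration vector.
#' @param plc cached PLC\eqn{\gamma} rate.
#' @param phen phenotype label.
#' @export
pop_add <- function(pop, i, j, age, conc, plc, phen = "proliferative") {
  pop$i <- c(pop$i, as.integer(i)); pop$j <- c(pop$j, as.integer(j))
  pop$age <- c(pop$age, age); pop$phen <- c(pop$phen, phen)
  pop$alive <- c(pop$alive, TRUE)
  pop$path <- rbind(pop$path, conc[colnames(pop$path)])
  pop$plc <- c(pop$plc, plc)
  pop
}

#' Cell division: place an offspring on a free site
#'
#' The offspring starts with age 0 and the configured newborn pathway state;
#' the parent's cell-cycle species are reset so its clock restarts.  Placing
#' onto an occupied site is a contract violation and errors.
#'
#' @param pop a [new_cell_pop()] population.
#' @param occ integer occupancy matrix (0 = free, else cell id).
#' @param parent_id index of the dividing cell.
#' @param site integer `c(i, j)` target (must be free).
#' @param newborn_conc named pathway concentrations for the offspring.
#' @param newborn_plc offspring PLC\eqn{\gamma} rate.
#' @param cycle_reset named vector of parent species to reset
#'   (cell-cycle block).
#' @return list with updated `pop` and `occ`.
#' @export
cell_divide <- function(pop, occ, parent_id, site, newborn_conc, newborn_plc,
                        cycle_reset) {
  if (occ[site[1], site[2]] != 0L)
    stop("division target site is occupied (contract violation)")
  pop <- pop_add(pop, site[1], site[2], 0, newborn_conc, newborn_plc,
                 phen = "proliferative")
  pop$path[parent_id, names(cycle_reset)] <- cycle_reset
  occ[site[1], site[2]] <- length(pop$i)
  list(pop = pop, occ = occ)
}

#' Cell migration: move one lattice site
#'
#' @inheritParams cell_divide
#' @param id index of the migrating cell.
#' @return list with updated `pop` and `occ`.
#' @export
cell_migrate <- function(pop, occ, id, site) {
  if (occ[site[1], site[2]] != 0L)
    stop("migration target site is occupied (contract violation)")
  occ[pop$i[id], pop$j[id]] <- 0L
  pop$i[id] <- as.integer(site[1]); pop$j[id] <- as.integer(site[2])
  occ[site[1], site[2]] <- id
  list(pop = pop, occ = occ)
}
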