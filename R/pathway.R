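#' Per-cell pathway state
#'
#' Holds the concentration vector of every species of a [pathway_spec()] plus
#' the current PLC\eqn{\gamma} rate of change (the migration potential).
#'
#' @param spec a [pathway_spec()].
#' @param conc named concentrations; defaults to the spec's reference
#'   initial condition.
#' @return object of class `pathway_state`.
#' @export
pathway_state <- function(spec, conc = spec$initial) {
  if (!setequal(names(conc), spec$species))
    stop("state species do not match the pathway spec")
  conc <- conc[spec$species]
  if (any(conc < 0)) stop("concentrations must be >= 0")
  st <- structure(list(conc = conc, plc_gamma_rate = NA_real_),
                  class = "pathway_state")
  st$plc_gamma_rate <- plc_rate_of(spec, conc)
  st
}

plc_rate_of <- function(spec, conc, clamp = character(0)) {
  dy <- pathway_deriv_cpp(unname(conc), compile_pathway(spec, clamp))
  dy[match("PLCg", spec$species)]
}

#' TKI-receptor binding constants
#'
#' Michaelis-Menten description of tyrosine-kinase-inhibitor binding to EGFR:
#' with binding/unbinding rates \eqn{k_b}, \eqn{k_u} much faster than the
#' phenotypic time scale, the occupied receptor fraction at local drug
#' concentration `Tki` is `Tki / (km + Tki)` with `km ~ kb/ku`.
#'
#' @param egfr0 initial (total) EGFR concentration, >= 0.
#' @param km Michaelis constant, > 0 (same units as the drug field).
#' @return object of class `tki_binding`.
#' @export
tki_binding <- function(egfr0, km) {
  stopifnot(is.numeric(egfr0), egfr0 >= 0, is.numeric(km), km > 0)
  structure(list(egfr0 = egfr0, km = km), class = "tki_binding")
}

#' Effective EGFR under receptor blockade
#'
#' `egfr0 - egfr0 * tki / (km + tki)`: the receptor pool left unoccupied by
#' drug, in `[0, egfr0]`, strictly decreasing in the local drug level.
#'
#' @param binding a [tki_binding()].
#' @param tki_local local drug concentration, >= 0 (vectorized).
#' @return effective receptor concentration(s).
#' @export
effective_egfr <- function(binding, tki_local) {
  stopifnot(inherits(binding, "tki_binding"))
  if (any(tki_local < 0)) stop("tki_local must be >= 0")
  binding$egfr0 - binding$egfr0 * tki_local / (binding$km + tki_local)
}

# impose the extracellular inputs on a raw concentration vector:
# ligand level is driven by the local field; the free receptor pool is capped
# at the drug-adjusted effective amount (quasi-steady-state blockade).
# Specs lacking the ligand/receptor species (reduced test networks) are
# left untouched.
apply_inputs <- function(spec, conc, tgf_local, egfr_eff) {
  if (!is.null(tgf_local) && "TGFa" %in% spec$species)
    conc[["TGFa"]] <- tgf_local
  if (!is.null(egfr_eff) && "EGFR" %in% spec$species)
    conc[["EGFR"]] <- min(conc[["EGFR"]], egfr_eff)
  conc
}

default_tgf <- function(spec, state)
  if ("TGFa" %in% spec$species) state$conc[["TGFa"]] else NULL
default_egfr <- function(spec)
  if ("EGFR" %in% spec$species) spec$initial[["EGFR"]] else NULL

#' Pathway derivatives at a given state
#'
#' Evaluates d[X_i]/dt (production minus consumption over all rate-law terms)
#' for every species, with the ligand species clamped to the imposed local
#' TGF\eqn{\alpha} level and the free receptor capped at `egfr_eff`.
#'
#' @param spec a [pathway_spec()].
#' @param state a [pathway_state()].
#' @param tgf_local imposed local ligand concentration (>= 0).
#' @param egfr_eff effective receptor pool (>= 0); defaults to no blockade.
#' @return named rate vector (concentration per hour).
#' @export
pathway_derivatives <- function(spec, state, tgf_local = default_tgf(spec, state),
                                egfr_eff = default_egfr(spec)) {
  stopifnot(inherits(state, "pathway_state"),
            is.null(tgf_local) || tgf_local >= 0,
            is.null(egfr_eff) || egfr_eff >= 0)
  if (!setequal(names(state$conc), spec$species))
    stop("state species do not match the pathway spec")
  conc <- apply_inputs(spec, state$conc[spec$species], tgf_local, egfr_eff)
  clamp <- if (is.null(tgf_local)) character(0) else "TGFa"
  dy <- pathway_deriv_cpp(unname(conc), compile_pathway(spec, clamp = clamp))
  setNames(dy, spec$species)
}

#' Advance a cell's pathway by one agent step
#'
#' Integrates the network ODEs over `dt` hours with an adaptive embedded
#' Runge-Kutta 4(5) method (absolute tolerance 1e-9, relative 1e-6 by
#' default), substepping freely inside the agent step.  The ligand species is
#' clamped to `tgf_local`; the free receptor is capped at `egfr_eff` before
#' integration.  Concentrations are kept >= 0 (clamping is counted in the
#' `n_clamped` attribute of the result).
#'
#' @inheritParams pathway_derivatives
#' @param dt step length in hours, > 0.
#' @param rtol,atol integrator tolerances.
#' @return a new [pathway_state()] with `plc_gamma_rate` refreshed.
#' @export
integrate_pathway <- function(spec, state, dt,
                              tgf_local = default_tgf(spec, state),
                              egfr_eff = default_egfr(spec),
                              rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(state, "pathway_state"), dt > 0,
            is.null(tgf_local) || tgf_local >= 0,
            is.null(egfr_eff) || egfr_eff >= 0)
  conc <- apply_inputs(spec, state$conc[spec$species], tgf_local, egfr_eff)
  clamp <- if (is.null(tgf_local)) character(0) else "TGFa"
  tab <- compile_pathway(spec, clamp = clamp)
  out <- pathway_integrate_cpp(matrix(unname(conc), nrow = 1), tab, dt,
                               rtol, atol, 1e6)
  if (out$status[1] != 0L)
    stop("pathway integrator failed to converge over dt = ", dt, " h")
  newc <- setNames(as.numeric(out$y[1, ]), spec$species)
  st <- structure(list(conc = newc,
                       plc_gamma_rate = out$dy[1, match("PLCg", spec$species)]),
                  class = "pathway_state")
  attr(st, "n_clamped") <- out$n_clamped
  st
}

#' Migration potential of a cell
#'
#' The migration potential is the current rate of change of the
#' PLC\eqn{\gamma} concentration, d[PLC\eqn{\gamma}]/dt.
#'
#' @param state a [pathway_state()].
#' @return rate (concentration per hour).
#' @export
migration_potential <- function(state) {
  stopifnot(inherits(state, "pathway_state"))
  state$plc_gamma_rate
}

#' Division readiness of the cell-cycle switch
#'
#' A cell is ready to divide iff [CDh1] < `thr1` AND [cycCDK] > `thr2`,
#' both strict (equality does not trigger division).
#'
#' @param state a [pathway_state()].
#' @param thr1,thr2 positive thresholds.
#' @return logical.
#' @export
division_ready <- function(state, thr1, thr2) {
  stopifnot(inherits(state, "pathway_state"), thr1 > 0, thr2 > 0)
  unname(state$conc[["CDh1"]] < thr1 && state$conc[["cycCDK"]] > thr2)
}
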