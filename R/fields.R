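#' Lattice concentration field
#'
#' One extracellular concentration grid together with its reaction-diffusion
#' coefficients.  All fields except fibronectin obey
#' \deqn{\partial u/\partial t = D \Delta u + X_{ves} q (u_{blood} - u)
#'       + X_{tum} (S - U) - \delta u}
#' with zero-flux (homogeneous Neumann) boundaries; fibronectin has no
#' diffusion and is handled by [fibronectin_step()].
#'
#' Units: lattice units (site spacing = 1) and hours; concentrations are
#' non-dimensional except the drug field, which is in \eqn{\mu}M.
#'
#' @param name one of `"glucose"`, `"oxygen"`, `"tgfa"`, `"vegf"`,
#'   `"fibronectin"`, `"tki"`.
#' @param grid L x L non-negative matrix, or a single value replicated on an
#'   `L x L` grid.
#' @param L lattice size (needed when `grid` is scalar).
#' @param D diffusivity (site^2/h; 0 for fibronectin).
#' @param q vessel permeability (h^-1); for glucose compose it as
#'   `2*pi*r*p` from vessel radius and wall permeability.
#' @param ublood blood concentration (0 for species not carried by blood).
#' @param S secretion rate per tumor-occupied site (for fibronectin this slot
#'   holds `beta`, the per-vessel-site production rate).
#' @param U uptake rate per tumor-occupied site (for fibronectin this slot
#'   holds `gamma`, the first-order uptake coefficient).
#' @param delta first-order decay rate.
#' @return object of class `field`.
#' @export
make_field <- function(name, grid = 0, L = NULL, D = 0, q = 0, ublood = 0,
                       S = 0, U = 0, delta = 0) {
  name <- match.arg(name, c("glucose", "oxygen", "tgfa", "vegf",
                            "fibronectin", "tki"))
  if (!is.matrix(grid)) {
    stopifnot(!is.null(L), length(grid) == 1)
    grid <- matrix(grid, L, L)
  }
  if (any(grid < 0)) stop("field values must be >= 0")
  stopifnot(D >= 0, q >= 0, delta >= 0)
  structure(list(name = name, grid = grid, D = D, q = q, ublood = ublood,
                 S = S, U = U, delta = delta),
            class = "field")
}

#' Occupancy masks
#'
#' Indicator grids marking vessel-occupied (`x_ves`) and tumor-occupied
#' (`x_tum`) lattice sites; both enter the PDE source terms and are refreshed
#' every simulation step.
#'
#' @param x_ves,x_tum L x L 0/1 integer matrices.
#' @return object of class `occupancy_masks`.
#' @export
occupancy_masks <- function(x_ves, x_tum) {
  stopifnot(is.matrix(x_ves), is.matrix(x_tum),
            all(dim(x_ves) == dim(x_tum)),
            all(x_ves %in% c(0L, 1L)), all(x_tum %in% c(0L, 1L)))
  structure(list(x_ves = matrix(as.integer(x_ves), nrow(x_ves)),
                 x_tum = matrix(as.integer(x_tum), nrow(x_tum))),
            class = "occupancy_masks")
}

#' Advance a diffusing field one agent step
#'
#' Explicit forward Euler with the 5-point Laplacian and mirrored ghost
#' cells; substeps are chosen automatically to satisfy the stability bound
#' `dt_sub <= dx^2/(4 D)`.  Values are clamped at zero (count in attribute
#' `n_clamped`).
#'
#' @param field a [make_field()] object (not fibronectin).
#' @param masks an [occupancy_masks()].
#' @param dt step in hours, > 0.
#' @param dt_sub_max optional cap on the substep (used by convergence tests).
#' @return the advanced `field`, with attributes `n_substeps`, `n_clamped`.
#' @export
rd_step <- function(field, masks, dt, dt_sub_max = 0) {
  stopifnot(inherits(field, "field"), inherits(masks, "occupancy_masks"),
            dt > 0)
  if (field$name == "fibronectin")
    stop("use fibronectin_step() for the non-diffusing matrix field")
  if (!all(dim(field$grid) == dim(masks$x_ves)))
    stop("mask shape does not match grid shape")
  out <- rd_step_cpp(field$grid, masks$x_ves, masks$x_tum,
                     field$D, field$q, field$ublood, field$S, field$U,
                     field$delta, dt, 1.0, dt_sub_max)
  field$grid <- out$u
  attr(field, "n_substeps") <- out$n_substeps
  attr(field, "n_clamped") <- out$n_clamped
  field
}

#' Advance the fibronectin field one agent step
#'
#' Per-site update `F <- F + dt * (X_ves * beta - X_tum * gamma * F)`:
#' endothelial cells lay down matrix, tumor cells degrade it; no diffusion.
#'
#' @inheritParams rd_step
#' @export
fibronectin_step <- function(field, masks, dt) {
  stopifnot(inherits(field, "field"), field$name == "fibronectin", dt > 0)
  g <- field$grid + dt * (masks$x_ves * field$S -
                          masks$x_tum * field$U * field$grid)
  field$grid <- pmax(g, 0)
  field
}

#' Advance all extracellular fields one agent step
#'
#' Updates glucose, oxygen, TGF\eqn{\alpha}, VEGF and fibronectin, and the
#' drug field iff `treatment_on`.
#'
#' @param fields named list of [make_field()] objects (`glucose`, `oxygen`,
#'   `tgfa`, `vegf`, `fibronectin`, `tki`).
#' @param masks an [occupancy_masks()].
#' @param treatment_on logical; when `FALSE` the drug field is left untouched.
#' @param dt step in hours.
#' @return the updated named list.
#' @export
step_all_fields <- function(fields, masks, treatment_on, dt) {
  for (nm in c("glucose", "oxygen", "tgfa", "vegf"))
    fields[[nm]] <- rd_step(fields[[nm]], masks, dt)
  fields$fibronectin <- fibronectin_step(fields$fibronectin, masks, dt)
  if (isTRUE(treatment_on))
    fields$tki <- rd_step(fields$tki, masks, dt)
  fields
}
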