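# Shared fixtures for the test suite.  Everything is built in code; no data
# files beyond the shipped default rate table.

# one-species decay network dX/dt = -k X
decay_spec <- function(k = 0.5, x0 = 1) {
  pathway_spec(
    species = "X",
    reactions = data.frame(reaction = "dec", rate_param = "k",
                           factors = "X:1", mm_species = "", mm_k = "",
                           stoich = "X:-1", stringsAsFactors = FALSE),
    params = c(k = k), initial = c(X = x0),
    aliases = c(X1 = "X"))
}

# production/decay network with analytic fixed point X* = kp / kd
birth_death_spec <- function(kp = 0.3, kd = 0.6) {
  pathway_spec(
    species = "X",
    reactions = data.frame(
      reaction = c("prod", "dec"), rate_param = c("kp", "kd"),
      factors = c("", "X:1"), mm_species = c("", ""), mm_k = c("", ""),
      stoich = c("X:1", "X:-1"), stringsAsFactors = FALSE),
    params = c(kp = kp, kd = kd), initial = c(X = kp / kd),
    aliases = c(X1 = "X"))
}

# independent term-by-term evaluation of the default network's rate laws,
# written out by hand (kept deliberately separate from the table compiler)
default_rhs_oracle <- function(y, p) {
  with(as.list(c(y, p)), {
    r_bind   <- k1 * TGFa * EGFR
    r_unbind <- ku * Cplx
    r_phos   <- k2 * Cplx^2
    r_dephos <- V4 * pEGFR / (K4 + pEGFR)
    r_act    <- k3 * pEGFR * PLCgi
    r_rel    <- k5 * PLCg
    r_grow   <- kg * Mass
    r_crowd  <- kg2 * Mass^2
    r_syn    <- kc1 * Mass
    r_deg    <- kc2 * cycCDK
    r_degc   <- kc2p * CDh1 * cycCDK
    r_cact   <- kc3 * CDh1i / (J3 + CDh1i)
    r_cinact <- kc4 * cycCDK * CDh1 / (J4 + CDh1)
    c(TGFa  = -r_bind + r_unbind + r_dephos,
      EGFR  = -r_bind + r_unbind + r_dephos,
      Cplx  = r_bind - r_unbind - 2 * r_phos,
      pEGFR = 2 * r_phos - r_dephos,
      PLCgi = -r_act + r_rel,
      PLCg  = r_act - r_rel,
      CDh1  = r_cact - r_cinact,
      CDh1i = -r_cact + r_cinact,
      cycCDK = r_syn - r_deg - r_degc,
      Mass  = r_grow - r_crowd)
  })
}

# classical fixed-step RK4 in plain R: the tight-tolerance reference
# integrator used as an oracle against the compiled adaptive kernel
rk4_reference <- function(y0, rhs, t_end, n_steps) {
  h <- t_end / n_steps
  y <- y0
  for (s in seq_len(n_steps)) {
    k1 <- rhs(y); k2 <- rhs(y + h / 2 * k1)
    k3 <- rhs(y + h / 2 * k2); k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# empty masks of a given size
empty_masks <- function(L) occupancy_masks(matrix(0L, L, L), matrix(0L, L, L))

# small simulation config for fast whole-pipeline tests
small_config <- function(...) {
  default_config(modifyList(list(
    lattice = list(L = 40L), horizon = 10,
    tumor = list(n_cells = 12L, center_i = 24L, center_j = 20L, radius = 3),
    vessel = list(n_tips = 3L)), list(...)))
}
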