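test_that("effective_egfr follows Michaelis-Menten occupancy", {
  b <- tki_binding(egfr0 = 0.3, km = 0.033)
  expect_identical(effective_egfr(b, 0), 0.3)
  expect_equal(effective_egfr(b, 0.033), 0.15)
  expect_lt(effective_egfr(b, 1e6 * 0.033), 0.3 * 1e-6)
  expect_error(effective_egfr(b, -1), "tki_local")

  # strictly decreasing in the drug level and bounded in [0, egfr0]
  tki <- c(0, 10^seq(-4, 3, length.out = 50))
  eff <- effective_egfr(b, tki)
  expect_true(all(diff(eff) < 0))
  expect_true(all(eff >= 0 & eff <= 0.3))
})

test_that("pathway derivatives match hand-written rate laws", {
  # single-reaction mass action: dX/dt = -k X
  sp <- decay_spec(k = 0.1, x0 = 2)
  d <- pathway_derivatives(sp, pathway_state(sp))
  expect_equal(unname(d["X"]), -0.2)

  # fixed point of a birth/death network
  bd <- birth_death_spec(kp = 0.3, kd = 0.6)
  expect_equal(unname(pathway_derivatives(bd, pathway_state(bd))["X"]), 0)

  # default network at reference and at perturbed states versus an
  # independent term-by-term evaluation
  spec <- default_pathway()
  st <- pathway_state(spec)
  got <- pathway_derivatives(spec, st, tgf_local = NULL, egfr_eff = NULL)
  expect_equal(got, default_rhs_oracle(spec$initial, spec$params),
               tolerance = 1e-12)
  set.seed(11)
  for (rep in 1:5) {
    y <- setNames(runif(length(spec$species), 0, 1), spec$species)
    st <- pathway_state(spec, y)
    got <- pathway_derivatives(spec, st, tgf_local = NULL, egfr_eff = NULL)
    expect_equal(got, default_rhs_oracle(y, spec$params), tolerance = 1e-12)
  }
})

test_that("derivatives clamp the driven ligand and cap the receptor", {
  spec <- default_pathway()
  st <- pathway_state(spec)
  d <- pathway_derivatives(spec, st, tgf_local = 0.7, egfr_eff = 0.05)
  expect_identical(unname(d["TGFa"]), 0)
  y <- spec$initial; y[["TGFa"]] <- 0.7; y[["EGFR"]] <- 0.05
  expect_equal(d[setdiff(spec$species, "TGFa")],
               default_rhs_oracle(y, spec$params)[setdiff(spec$species,
                                                          "TGFa")],
               tolerance = 1e-12)
})

test_that("integrate_pathway hits closed forms and a reference integrator", {
  # pure decay: X(1) = exp(-0.5) within integrator tolerance
  sp <- decay_spec(k = 0.5, x0 = 1)
  st <- integrate_pathway(sp, pathway_state(sp), 1)
  expect_equal(unname(st$conc["X"]), exp(-0.5), tolerance = 1e-6)

  # fixed point is invariant under any dt
  bd <- birth_death_spec()
  for (dt in c(0.1, 1, 7)) {
    st <- integrate_pathway(bd, pathway_state(bd), dt)
    expect_equal(unname(st$conc["X"]), 0.5, tolerance = 1e-8)
  }

  # default network, one agent step, vs tight fixed-step RK4 in plain R
  spec <- default_pathway()
  rhs <- function(y) default_rhs_oracle(setNames(y, spec$species),
                                        spec$params)
  ref <- rk4_reference(unname(spec$initial), rhs, 1, 4000)
  st <- integrate_pathway(spec, pathway_state(spec), 1,
                          tgf_local = NULL, egfr_eff = NULL,
                          rtol = 1e-8, atol = 1e-10)
  expect_equal(unname(st$conc), unname(ref), tolerance = 1e-4)
})

test_that("integrated concentrations stay non-negative", {
  spec <- default_pathway()
  set.seed(7)
  for (rep in 1:10) {
    y <- setNames(runif(length(spec$species), 0, 2), spec$species)
    st <- integrate_pathway(spec, pathway_state(spec, y), 1)
    expect_true(all(st$conc >= 0))
  }
})

test_that("migration_potential is the stored PLCgamma rate", {
  st <- structure(list(conc = c(PLCg = 1), plc_gamma_rate = 0.03),
                  class = "pathway_state")
  expect_identical(migration_potential(st), 0.03)

  # at a PLCgamma equilibrium the potential vanishes
  spec <- default_pathway()
  tab_hours <- 4   # receptor module equilibrates fast
  st0 <- integrate_pathway(spec, pathway_state(spec), tab_hours)
  # finite-difference oracle: (PLCg(t+d) - PLCg(t)) / d
  d <- 1e-3
  st1 <- integrate_pathway(spec, st0, d, rtol = 1e-10, atol = 1e-12)
  fd <- (st1$conc[["PLCg"]] - st0$conc[["PLCg"]]) / d
  expect_equal(migration_potential(st0), fd, tolerance = 1e-3)
})

test_that("division readiness uses strict inequalities", {
  mk <- function(cdh1, cdk) {
    spec <- default_pathway()
    y <- spec$initial; y[["CDh1"]] <- cdh1; y[["cycCDK"]] <- cdk
    pathway_state(spec, y)
  }
  thr1 <- 0.5; thr2 <- 0.125
  expect_false(division_ready(mk(thr1, 10 * thr2), thr1, thr2))  # equality
  expect_false(division_ready(mk(0.5 * thr1, thr2), thr1, thr2)) # equality
  expect_true(division_ready(mk(0.5 * thr1, 2 * thr2), thr1, thr2))
  expect_false(division_ready(mk(0.5 * thr1, 0.5 * thr2), thr1, thr2))
  expect_false(division_ready(mk(2 * thr1, 2 * thr2), thr1, thr2))
})

test_that("pathway_spec validates its invariants", {
  expect_error(decay_spec(k = -1), "finite and >= 0")
  bad <- data.frame(reaction = "r", rate_param = "k", factors = "Y:1",
                    mm_species = "", mm_k = "", stoich = "X:-1")
  expect_error(pathway_spec("X", bad, c(k = 1), c(X = 1)),
               "undeclared species")
  orphan <- data.frame(reaction = "r", rate_param = "k", factors = "X:1",
                       mm_species = "", mm_k = "", stoich = "X:-1")
  expect_error(pathway_spec(c("X", "Z"), orphan, c(k = 1), c(X = 1, Z = 0)),
               "never referenced")
})

test_that("the shipped rate table reproduces the built-in default network", {
  path <- system.file("extdata", "pathway_default.tsv", package = "glioabm")
  reread <- read_rate_table(path)
  spec <- default_pathway()
  expect_equal(reread, spec$reactions, ignore_attr = TRUE)
})
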