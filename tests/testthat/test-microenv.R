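test_that("one explicit substep matches the hand-applied 5-point stencil", {
  # D = 0.5, q = delta = 0 -> stability bound 0.9/(4*0.5) = 0.45, so dt = 0.4
  # runs as a single substep
  g <- matrix(0, 3, 3); g[2, 2] <- 1
  f <- make_field("glucose", g, D = 0.5)
  out <- rd_step(f, empty_masks(3), dt = 0.4)
  expect_identical(attr(out, "n_substeps"), 1L)

  # hand computation with cell-centered zero-flux ghost cells
  mi <- function(k) if (k < 1) 1 else if (k > 3) 3 else k
  lap <- function(u, i, j)
    u[mi(i - 1), j] + u[mi(i + 1), j] + u[i, mi(j - 1)] + u[i, mi(j + 1)] -
      4 * u[i, j]
  expected <- g
  for (i in 1:3) for (j in 1:3)
    expected[i, j] <- g[i, j] + 0.4 * 0.5 * lap(g, i, j)
  expect_equal(out$grid, expected, tolerance = 1e-15)
})

test_that("zero-flux diffusion conserves mass and obeys the max principle", {
  set.seed(3)
  g <- matrix(runif(15 * 15), 15, 15)
  f <- make_field("oxygen", g, D = 2)
  masks <- empty_masks(15)
  cur <- f
  for (s in 1:100) cur <- rd_step(cur, masks, dt = 1)
  expect_equal(sum(cur$grid), sum(g), tolerance = 1e-10)
  expect_lte(max(cur$grid), max(g) + 1e-12)
  expect_gte(min(cur$grid), min(g) - 1e-12)
})

test_that("rd_step agrees with the matrix exponential of the semi-discrete system", {
  skip_if_not_installed("Matrix")
  L <- 5
  set.seed(5)
  g <- matrix(runif(L * L), L, L)
  xves <- matrix(0L, L, L); xves[2, 3] <- 1L
  D <- 1; q <- 0.8; delta <- 0.3
  # dense generator of du/dt = D Lap u - q Xves u - delta u (ublood = 0)
  n <- L * L
  A <- matrix(0, n, n)
  idx <- function(i, j) (j - 1) * L + i
  mir <- function(k) if (k < 1) 1 else if (k > L) L else k
  for (i in 1:L) for (j in 1:L) {
    r <- idx(i, j)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      A[r, idx(mir(i + d[1]), mir(j + d[2]))] <-
        A[r, idx(mir(i + d[1]), mir(j + d[2]))] + D
    }
    A[r, r] <- A[r, r] - 4 * D - delta - q * xves[i, j]
  }
  t_end <- 0.02
  ref <- as.numeric(Matrix::expm(A * t_end) %*% as.vector(g))

  f <- make_field("tgfa", g, D = D, q = q, ublood = 0, delta = delta)
  masks <- occupancy_masks(xves, matrix(0L, L, L))
  cur <- f
  for (s in 1:20) cur <- rd_step(cur, masks, dt = t_end / 20,
                                 dt_sub_max = 1e-6)
  expect_equal(as.vector(cur$grid), ref, tolerance = 1e-6)
})

test_that("transvascular and uptake source terms have the stated signs", {
  L <- 7
  g <- matrix(0.5, L, L)
  xves <- matrix(0L, L, L); xves[4, 4] <- 1L
  xtum <- matrix(0L, L, L); xtum[2, 2] <- 1L
  f <- make_field("glucose", g, D = 1, q = 2, ublood = 1, U = 0.3)
  out <- rd_step(f, occupancy_masks(xves, xtum), dt = 0.05)
  expect_gt(out$grid[4, 4], 0.5)   # below blood level: influx
  expect_lt(out$grid[2, 2], 0.5)   # tumor uptake
})

test_that("fibronectin updates per site without diffusion", {
  L <- 4
  f <- make_field("fibronectin", matrix(1, L, L), S = 0.05, U = 0.1)
  xves <- matrix(0L, L, L); xves[1, 1] <- 1L
  xtum <- matrix(0L, L, L); xtum[2, 2] <- 1L
  out <- fibronectin_step(f, occupancy_masks(xves, xtum), dt = 1)
  expect_equal(out$grid[1, 1], 1.05)   # vessel site: +beta
  expect_equal(out$grid[2, 2], 0.9)    # tumor site: -gamma*F
  expect_equal(out$grid[3, 3], 1)      # untouched elsewhere
})

test_that("step_all_fields honors the treatment switch and empty masks", {
  L <- 9
  cfg <- small_config()
  fields <- list(
    glucose = make_field("glucose", 1, L, D = 2),
    oxygen = make_field("oxygen", 1, L, D = 3),
    tgfa = make_field("tgfa", 0.2, L, D = 1),
    vegf = make_field("vegf", 0.2, L, D = 1),
    fibronectin = make_field("fibronectin", 0.3, L, S = 0.01, U = 0.01),
    tki = make_field("tki", 0, L, D = 2, q = 1, ublood = 1))
  masks <- empty_masks(L)

  # no sources, uniform fields: everything is invariant; drug field stays 0
  out <- step_all_fields(fields, masks, treatment_on = FALSE, dt = 1)
  for (nm in names(out)) expect_equal(out[[nm]]$grid, fields[[nm]]$grid)
  expect_true(all(out$tki$grid == 0))

  # with treatment on and a vessel, the drug enters
  xves <- matrix(0L, L, L); xves[3, 3] <- 1L
  out2 <- step_all_fields(fields, occupancy_masks(xves, matrix(0L, L, L)),
                          treatment_on = TRUE, dt = 1)
  expect_gt(max(out2$tki$grid), 0)
})

test_that("field constructors validate their inputs", {
  expect_error(make_field("glucose", matrix(-1, 2, 2)), ">= 0")
  expect_error(make_field("nope", 1, 4), "arg")
  f <- make_field("fibronectin", 1, 4)
  expect_error(rd_step(f, empty_masks(4), 1), "fibronectin_step")
  g <- make_field("glucose", 1, 4, D = 1)
  expect_error(rd_step(g, empty_masks(5), 1), "shape")
})
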