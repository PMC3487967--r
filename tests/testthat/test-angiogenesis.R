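# minimal network with tips at chosen positions on an empty lattice
mknet <- function(L = 12, tips = list(c(6, 6)), hour = 0, alpha = 1, kv = 1,
                  lambda = 0) {
  net <- new_vessel_network(L, parent_col = 2L,
                            tip_rows = seq_along(tips), hour = hour,
                            alpha = alpha, kv = kv, lambda = lambda)
  for (k in seq_along(tips)) {
    old <- c(net$tips$i[k], net$tips$j[k])
    net$ec[old[1], old[2]] <- 0L; net$ec_sprout[old[1], old[2]] <- 0L
    net$tips$i[k] <- tips[[k]][1]; net$tips$j[k] <- tips[[k]][2]
    net$ec[tips[[k]][1], tips[[k]][2]] <- 1L
    net$ec_sprout[tips[[k]][1], tips[[k]][2]] <- net$tips$sprout[k]
  }
  net
}
no_tum <- function(L = 12) matrix(0L, L, L)

test_that("tip migration distribution reproduces the worked example", {
  L <- 9
  V <- matrix(0, L, L); Fg <- matrix(0, L, L)
  V[5, 6] <- 0.1   # only the upward neighbor differs
  d <- tip_migration_distribution(c(5, 5), V, Fg,
                                  list(alpha = 1, kv = 1, lambda = 0))
  expect_equal(d$p_raw, c(0.1, 0, 0, 0, 0.025))
  expect_equal(d$p_norm, c(0.8, 0, 0, 0, 0.2))
  expect_equal(d$breaks, c(0.8, 0.8, 0.8, 0.8, 1))
})

test_that("uniform fields give the degenerate stay-put distribution", {
  V <- matrix(0.4, 8, 8); Fg <- matrix(0.3, 8, 8)
  d <- tip_migration_distribution(c(4, 4), V, Fg,
                                  list(alpha = 2, kv = 1, lambda = 0.5))
  expect_equal(d$p_norm, c(0, 0, 0, 0, 1))
})

test_that("equal positive direction weights normalize to 1/5 each", {
  L <- 9; Fg <- matrix(0, L, L)
  Fg[4, 5] <- Fg[6, 5] <- Fg[5, 4] <- Fg[5, 6] <- 0.2
  d <- tip_migration_distribution(c(5, 5), matrix(0, L, L), Fg,
                                  list(alpha = 1, kv = 1, lambda = 1))
  expect_equal(d$p_norm, rep(0.2, 5))
})

test_that("distribution is a probability vector with P5 = mean(P1..P4)", {
  set.seed(9)
  for (rep in 1:20) {
    L <- 10
    V <- matrix(runif(L * L), L, L); Fg <- matrix(runif(L * L), L, L)
    tip <- c(sample(L, 1), sample(L, 1))
    d <- tip_migration_distribution(tip, V, Fg,
                                    list(alpha = 2, kv = 0.5, lambda = 0.3))
    expect_true(all(d$p_raw >= 0))
    expect_equal(d$p_raw[5], mean(d$p_raw[1:4]))
    expect_equal(sum(d$p_norm), 1, tolerance = 1e-12)
    expect_true(all(diff(c(0, d$breaks)) >= 0))
    expect_equal(d$breaks[5], 1, tolerance = 1e-12)
  }
})

test_that("branching requires age > 18 h strictly and the stated draws", {
  dist <- structure(list(p_raw = c(0.2, 0.2, 0.3, 0.2, 0.1),
                         p_norm = c(0.2, 0.2, 0.3, 0.2, 0.1),
                         breaks = c(0.2, 0.4, 0.7, 0.9, 1)),
                    class = "migration_distribution")
  draws <- list(r1 = 0.3, r2 = 0.5, r = 0.95)  # r1 in I2, r2 in I3, r in I4

  # sprout age exactly 18 h: no branch (and r not in I3 -> no move)
  net <- mknet(tips = list(c(6, 6)))
  out <- branch_or_migrate(net, 1, dist, no_tum(), hour = 18, draws = draws)
  expect_equal(nrow(out$tips), 1)
  expect_equal(ec_count(out), ec_count(net))

  # age > 18: branch places daughters below (j-1) and right (i+1)
  out <- branch_or_migrate(net, 1, dist, no_tum(), hour = 19, draws = draws)
  expect_equal(nrow(out$tips), 2)
  expect_setequal(paste(out$tips$i, out$tips$j), c("6 5", "7 6"))
  expect_equal(ec_count(out), ec_count(net) + 2)
  # daughters start fresh sprouts (ages reset at the branch hour)
  births <- out$sprouts$birth[match(out$tips$sprout, out$sprouts$id)]
  expect_true(all(births == 19))
})

test_that("literal migration moves right iff r falls in I3", {
  dist <- structure(list(p_raw = c(0.2, 0.2, 0.3, 0.2, 0.1),
                         p_norm = c(0.2, 0.2, 0.3, 0.2, 0.1),
                         breaks = c(0.2, 0.4, 0.7, 0.9, 1)),
                    class = "migration_distribution")
  net <- mknet(tips = list(c(6, 6)))
  out <- branch_or_migrate(net, 1, dist, no_tum(), hour = 5,
                           draws = list(r = 0.5))
  expect_equal(c(out$tips$i[1], out$tips$j[1]), c(7, 6))
  expect_equal(ec_count(out), ec_count(net) + 1)

  out2 <- branch_or_migrate(net, 1, dist, no_tum(), hour = 5,
                            draws = list(r = 0.95))
  expect_equal(c(out2$tips$i[1], out2$tips$j[1]), c(6, 6))
})

test_that("generalized migration includes the stay interval", {
  dist <- structure(list(p_raw = c(0.2, 0.2, 0.3, 0.2, 0.1),
                         p_norm = c(0.2, 0.2, 0.3, 0.2, 0.1),
                         breaks = c(0.2, 0.4, 0.7, 0.9, 1)),
                    class = "migration_distribution")
  net <- mknet(tips = list(c(6, 6)))
  # r in I5 -> stationary, network unchanged
  out <- branch_or_migrate(net, 1, dist, no_tum(), hour = 5,
                           mode = "generalized", draws = list(r = 0.95))
  expect_equal(out$tips, net$tips)
  expect_equal(ec_count(out), ec_count(net))
  # r in I1 -> up (j+1)
  out <- branch_or_migrate(net, 1, dist, no_tum(), hour = 5,
                           mode = "generalized", draws = list(r = 0.1))
  expect_equal(c(out$tips$i[1], out$tips$j[1]), c(6, 7))
})

test_that("moves blocked by tumor sites are skipped and counted", {
  dist <- structure(list(p_raw = c(0, 0, 1, 0, 0.25),
                         p_norm = c(0, 0, 0.8, 0, 0.2),
                         breaks = c(0, 0, 0.8, 0.8, 1)),
                    class = "migration_distribution")
  net <- mknet(tips = list(c(6, 6)))
  xt <- no_tum(); xt[7, 6] <- 1L
  out <- branch_or_migrate(net, 1, dist, xt, hour = 5, draws = list(r = 0.5))
  expect_equal(c(out$tips$i[1], out$tips$j[1]), c(6, 6))
  expect_equal(out$n_blocked, net$n_blocked + 1L)
})

test_that("anastomosis merges colliding sprouts with one surviving tip", {
  dist_right <- structure(list(p_raw = c(0, 0, 1, 0, 0.25),
                               p_norm = c(0, 0, 0.8, 0, 0.2),
                               breaks = c(0, 0, 0.8, 0.8, 1)),
                          class = "migration_distribution")
  dist_left <- structure(list(p_raw = c(0, 0, 0, 1, 0.25),
                              p_norm = c(0, 0, 0, 0.8, 0.2),
                              breaks = c(0, 0, 0, 0.8, 1)),
                         class = "migration_distribution")
  # two tips stepping into the same free site in one step
  net <- mknet(tips = list(c(5, 6), c(7, 6)))
  net <- branch_or_migrate(net, 1, dist_right, no_tum(), hour = 2,
                           draws = list(r = 0.5))
  net <- branch_or_migrate(net, 2, dist_left, no_tum(), hour = 2,
                           mode = "generalized", draws = list(r = 0.5))
  expect_equal(nrow(net$tips), 2)
  net <- anastomosis(net)
  expect_equal(nrow(net$tips), 1)
  expect_equal(length(unique(net$tips$sprout)), 1)

  # tip meeting an existing vessel: sprouts merge, EC count unchanged
  net2 <- mknet(tips = list(c(5, 6), c(7, 6)))
  ecs <- ec_count(net2)
  net2 <- branch_or_migrate(net2, 1, dist_right, no_tum(), hour = 2,
                            draws = list(r = 0.5))  # (5,6) -> (6,6)
  net2 <- branch_or_migrate(net2, 1, dist_right, no_tum(), hour = 3,
                            draws = list(r = 0.5))  # (6,6) -> (7,6): on EC
  expect_equal(ec_count(net2), ecs + 1)   # only the intermediate site added
  expect_equal(net2$tips$sprout[1], net2$tips$sprout[2])
  expect_gte(net2$n_merged, 1L)

  # no contacts: unchanged
  net3 <- mknet(tips = list(c(5, 5)))
  expect_equal(anastomosis(net3)$tips, net3$tips)
})

test_that("chemotaxis drives expected displacement toward the VEGF source", {
  # monotone VEGF ramp rising with i (toward the tumor), no haptotaxis
  L <- 11
  V <- matrix(rep(seq(0, 1, length.out = L), each = 1), L, L, byrow = FALSE)
  Fg <- matrix(0.3, L, L)
  d <- tip_migration_distribution(c(6, 6), V, Fg,
                                  list(alpha = 2, kv = 1, lambda = 0))
  # analytic expectation of the i-displacement under the normalized law
  exp_di <- d$p_norm[3] - d$p_norm[4]
  expect_gt(exp_di, 0)
  set.seed(21)
  r <- runif(2e4)
  k <- findInterval(r, c(0, d$breaks), rightmost.closed = TRUE)
  di <- c(0, 0, 1, -1, 0)[k]
  mc <- mean(di)
  se <- sd(di) / sqrt(length(di))
  expect_lt(abs(mc - exp_di), 4 * se)
  expect_gt(mc, 0)
})

test_that("EC count never decreases over a stochastic run", {
  cfg <- small_config()
  res <- run_simulation(cfg)
  expect_true(all(diff(res$metrics$ec) >= 0))
})
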