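# Replicator dynamics: fixed points, conservation, invasions, selection.

test_that("vertices and neutral games are fixed points of the dynamics", {
  set.seed(5)
  g <- matrix_game(matrix(stats::runif(9), 3, 3))
  for (k in 1:3) {
    x <- numeric(3); x[k] <- 1
    expect_equal(replicator_rhs(x, g), stats::setNames(rep(0, 3),
                                                       g$strategies[[1]]))
  }
  neutral <- payoff_game(list(matrix(2, 2, 2), matrix(2, 2, 2)),
                         strategies = rep(list(c("a", "b")), 2),
                         symmetric = TRUE)
  expect_equal(unname(replicator_rhs(c(0.3, 0.7), neutral)), c(0, 0))
})

test_that("the rhs matches the explicit 2x2 replicator formula", {
  A <- rbind(c(2, 1), c(3, 0.5))
  g <- matrix_game(A, labels = c("C", "D"))
  x <- c(0.3, 0.7)
  f <- as.vector(A %*% x)
  phi <- sum(f * x)
  expect_equal(unname(replicator_rhs(x, g)), (f - phi) * x)
  # components always sum to zero analytically
  set.seed(3)
  for (i in 1:10) {
    x <- stats::runif(2); x <- x / sum(x)
    expect_equal(sum(replicator_rhs(x, g)), 0, tolerance = 1e-12)
  }
})

test_that("trajectories conserve the simplex and find known equilibria", {
  sd <- canonical_snowdrift()
  tr <- integrate_replicator(c(0.9, 0.1), sd, t_max = 300)
  expect_true(all(abs(rowSums(tr$states) - 1) <= 1e-8))
  expect_true(tr$converged)
  # interior fixed point of the 2x2 game: x_C* = (P-S)/(R-S-T+P)
  A <- sd$payoffs[[1]]
  xstar <- (A[2, 2] - A[1, 2]) / (A[1, 1] - A[1, 2] - A[2, 1] + A[2, 2])
  expect_equal(unname(tr$equilibrium["C"]), xstar, tolerance = 1e-6)

  pd <- canonical_pd()
  tr2 <- integrate_replicator(c(0.99, 0.01), pd, t_max = 400)
  expect_true(tr2$converged)
  expect_equal(unname(tr2$equilibrium["D"]), 1, tolerance = 1e-6)

  # starting at a vertex stays at the vertex
  tr3 <- integrate_replicator(c(1, 0), pd, t_max = 50)
  expect_true(all(tr3$states[, "C"] == 1 | abs(tr3$states[, "C"] - 1) < 1e-10))
})

test_that("invasions converge to initial-condition-independent equilibria", {
  sd <- canonical_snowdrift()
  up <- invade(sd, residents = "C", invaders = "D", invasion_fraction = 0.01,
               t_max = 400)
  down <- invade(sd, residents = "D", invaders = "C",
                 invasion_fraction = 0.01, t_max = 400)
  expect_true(up$converged && down$converged)
  expect_lt(max(abs(up$equilibrium - down$equilibrium)), 1e-4)

  # a dominant invader fixates regardless of the invasion fraction
  pd <- canonical_pd()
  for (f in c(0.005, 0.05, 0.2)) {
    tr <- invade(pd, residents = "C", invaders = "D", invasion_fraction = f,
                 t_max = 500)
    expect_equal(unname(tr$equilibrium["D"]), 1, tolerance = 1e-5)
  }

  # neutral game: frequencies stay where they started
  neutral <- payoff_game(list(matrix(1, 2, 2), matrix(1, 2, 2)),
                         strategies = rep(list(c("r", "i")), 2),
                         symmetric = TRUE)
  tr <- invade(neutral, "r", "i", invasion_fraction = 0.05, t_max = 100)
  expect_equal(unname(tr$states[nrow(tr$states), "i"]), 0.05,
               tolerance = 1e-8)
})

test_that("strict symmetric Nash vertices resist rare invasions", {
  set.seed(42)
  tried <- 0
  for (rep in 1:12) {
    g <- random_game(2, 3)
    # symmetrize so the game describes one population
    A <- g$payoffs[[1]]
    g <- payoff_game(list(A, t(A)), strategies = g$strategies,
                     symmetric = TRUE)
    res <- find_nash_ilp(g, tie_tol = 0)
    eqs <- res$equilibria
    for (i in seq_len(nrow(eqs))) {
      if (eqs[i, 1] != eqs[i, 2]) next  # monomorphic (symmetric) only
      k <- match(eqs[i, 1], g$strategies[[1]])
      # strictness: the diagonal entry beats every deviation strictly
      if (any(A[-k, k] >= A[k, k] - 1e-9)) next
      others <- setdiff(g$strategies[[1]], eqs[i, 1])
      tr <- invade(g, residents = eqs[i, 1], invaders = others,
                   invasion_fraction = 1e-3, t_max = 300)
      expect_equal(unname(tr$equilibrium[eqs[i, 1]]), 1, tolerance = 1e-4)
      tried <- tried + 1
    }
  }
  expect_gt(tried, 3)
})

test_that("invasion scenario presets partition the four genotypes", {
  sc <- invasion_scenario("two_step")
  expect_setequal(c(sc$residents, sc$invaders), c("11", "01", "10", "00"))
  expect_setequal(sc$invaders, c("10", "00"))
  expect_error(invade(canonical_pd(), "C", "X", 0.01),
               class = "fbagames_input_error")
  expect_error(invade(canonical_pd(), "C", "D", 0.7),
               class = "fbagames_input_error")
})

test_that("selection coefficients behave as the fitness-difference ratio", {
  # equal payoffs: s = 0 at any frequency ratio
  neutral <- payoff_game(list(matrix(2, 2, 2), matrix(2, 2, 2)),
                         strategies = rep(list(c("WT", "MT")), 2),
                         symmetric = TRUE)
  expect_equal(selection_coefficient(neutral, 0.3), 0)
  expect_equal(selection_coefficient(neutral, 7), 0)

  # rare-mutant limit: s -> (a_MT,WT - a_WT,WT) / a_WT,WT
  A <- rbind(WT = c(2, 1.5), MT = c(3, 0.2))
  colnames(A) <- c("WT", "MT")
  g <- matrix_game(A)
  s_rare <- selection_coefficient(g, 1e-9)
  expect_equal(s_rare, (A["MT", "WT"] - A["WT", "WT"]) / A["WT", "WT"],
               tolerance = 1e-6)

  # s crosses zero exactly at the interior equilibrium ratio
  sd <- canonical_snowdrift()  # interior at x_C = 0.5, ratio 1
  expect_lt(abs(selection_coefficient(sd, 1)), 1e-12)
  expect_gt(selection_coefficient(sd, 0.5), 0)  # D rare: invades
  expect_lt(selection_coefficient(sd, 2), 0)    # D common: declines
  # negative frequency dependence: s decreases with the ratio
  ss <- vapply(c(0.2, 0.5, 1, 2, 5), function(r) {
    selection_coefficient(sd, r)
  }, numeric(1))
  expect_true(all(diff(ss) < 0))

  expect_error(selection_coefficient(random_game(2, 3), 1),
               class = "fbagames_input_error")
})
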