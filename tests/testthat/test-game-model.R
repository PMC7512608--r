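test_that("composite Ising+Potts payoff matrix has the block structure", {
  g <- ising_potts_game(1)
  expect_equal(g$n, 5)
  expect_equal(g$A[1, 1], 1)
  expect_equal(g$A[1, 2], -1)
  expect_equal(g$A[3, 3], 1)
  expect_equal(g$A[3, 4], -0.5)
  expect_equal(g$A[1, 3], 0)
  expect_equal(g$A[2, 5], 0)
  expect_true(g$symmetric)
  expect_equal(g$V, g$A)

  g2 <- ising_potts_game(1.5)
  expect_equal(g2$A[4, 4], 1.5)
  expect_equal(g2$A[4, 5], -0.75)
})

test_that("builder matrices are pure coordination type (zero row/col sums)", {
  for (alpha in c(0, 0.5, 1, 1.15, 2)) {
    A <- ising_potts_game(alpha)$A
    expect_equal(rowSums(A), rep(0, 5), tolerance = 1e-12)
    expect_equal(colSums(A), rep(0, 5), tolerance = 1e-12)
    expect_equal(A, t(A))
  }
  for (n in c(2, 4, 7)) {
    A <- coordination_game(n)$A
    expect_equal(rowSums(A), rep(0, n), tolerance = 1e-12)
  }
  expect_equal(rowSums(potts_game(1, 3)$A), rep(0, 3), tolerance = 1e-12)
})

test_that("degenerate and invalid builder inputs behave as specified", {
  # alpha = 0: Potts block identically zero, equals the 5-strategy
  # elementary coordination game
  expect_equal(ising_potts_game(0)$A, coordination_game(5)$A)
  expect_equal(ising_potts_game(0)$A[3:5, 3:5], matrix(0, 3, 3))
  # n = 2 elementary coordination is the bare Ising block
  expect_equal(coordination_game(2)$A, matrix(c(1, -1, -1, 1), 2, 2))
  # neutral strategies provide zero payoff in every match-up
  A4 <- coordination_game(4)$A
  expect_equal(A4[3, ], rep(0, 4))
  expect_equal(A4[, 4], rep(0, 4))

  expect_error(ising_potts_game(-0.5), "nonnegative")
  expect_error(coordination_game(1), ">= 2")
  expect_error(potts_game(0), "positive")
})

test_that("player income sums the payoff against the four neighbors", {
  g <- ising_potts_game(1)
  uni <- lattice_state(4, g, init = "uniform:1")
  expect_equal(player_payoff(uni, c(2, 2), g), 4)

  # strategy-1 player surrounded by Potts players earns nothing
  s <- matrix(3L, 4, 4); s[2, 2] <- 1L
  expect_equal(player_payoff(lattice_state(4, g, init = s), c(2, 2), g), 0)

  # neighbors (1, 1, 2, 2) cancel
  s <- matrix(5L, 4, 4)
  s[2, 2] <- 1L; s[1, 2] <- 1L; s[3, 2] <- 1L; s[2, 1] <- 2L; s[2, 3] <- 2L
  expect_equal(player_payoff(lattice_state(4, g, init = s), c(2, 2), g), 0)

  expect_error(player_payoff(uni, c(0, 1), g), "out of range")
})

test_that("total potential counts each undirected edge once", {
  g <- ising_potts_game(1)
  for (L in c(2, 4, 6)) {
    uni <- lattice_state(L, g, init = "uniform:1")
    expect_equal(total_potential(uni, g), 2 * L * L)
  }
  g15 <- ising_potts_game(1.5)
  uni3 <- lattice_state(4, g15, init = "uniform:3")
  expect_equal(total_potential(uni3, g15), 3 * 16)
  # 2 x 2 torus: doubled bonds, 8 edges
  expect_equal(total_potential(lattice_state(2, g, init = "uniform:1"), g), 8)
})

test_that("average payoff is exactly twice the average potential", {
  g <- ising_potts_game(1)
  uni <- lattice_state(4, g, init = "uniform:1")
  pp <- payoff_potential(uni, g)
  expect_equal(pp$payoff_per_player, 4)
  expect_equal(pp$potential_per_player, 2)

  cb <- make_fixture("checkerboard", L = 4)
  pp <- payoff_potential(cb, g)
  expect_equal(pp$payoff_per_player, -4)
  expect_equal(pp$potential_per_player, -2)

  for (seed in 1:5) {
    st <- lattice_state(6, g, init = "random", seed = seed)
    pp <- payoff_potential(st, g)
    expect_equal(pp$payoff_per_player, 2 * pp$potential_per_player)
    # cross-check against the per-site income sum
    tot <- sum(vapply(1:6, function(r) {
      sum(vapply(1:6, function(c) player_payoff(st, c(r, c), g), numeric(1)))
    }, numeric(1)))
    expect_equal(tot, 2 * total_potential(st, g))
  }
})

test_that("adding a constant to all payoffs leaves the dynamics unchanged", {
  g <- ising_potts_game(1)
  g_shift <- game_spec(g$A + 3.7)
  a <- mc_step(lattice_state(8, g, "random", seed = 11), g, 0.8,
               steps = 20, seed = 42)
  b <- mc_step(lattice_state(8, g_shift, "random", seed = 11), g_shift, 0.8,
               steps = 20, seed = 42)
  expect_identical(a$sites, b$sites)
})

test_that("games serialize to JSON and back", {
  g <- ising_potts_game(1.05)
  path <- withr::local_tempfile(fileext = ".json")
  game_to_json(g, path)
  g2 <- game_from_json(path)
  expect_equal(g2$A, g$A)
  expect_equal(g2$alpha, 1.05)
  expect_equal(g2$labels, g$labels)
  # alpha-only serialization reconstructs the composite game
  g3 <- game_from_json('{"alpha": 0.5}')
  expect_equal(g3$A, ising_potts_game(0.5)$A)
})

test_that("asymmetric payoff matrices are simulable but refuse Phi machinery", {
  A <- matrix(c(1, -1, 0, 1), 2, 2)
  g <- game_spec(A)
  expect_false(g$symmetric)
  expect_null(g$V)
  st <- lattice_state(4, g, "random", seed = 1)
  expect_error(total_potential(st, g), "symmetric")
  expect_error(mf_stationary(g, 1), "potential")
  expect_error(pair_stationary(g, 1), "potential")
  expect_no_error(mc_step(st, g, 1))
})
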