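test_that("logit choice probabilities follow the exponential rule", {
  # site surrounded by four strategy-1 neighbors: candidate incomes
  # (4, -4, 0, 0, 0)
  s <- matrix(1L, 3, 3)
  st <- lattice_state(3, game5, init = s)
  p <- logit_probabilities(st, c(2, 2), game5, K = 1)
  w <- exp(c(4, -4, 0, 0, 0))
  expect_equal(p, w / sum(w), tolerance = 1e-12)
  expect_equal(sum(p), 1)

  # high noise: uniform choice
  p_hot <- logit_probabilities(st, c(2, 2), game5, K = 1e6)
  expect_equal(p_hot, rep(0.2, 5), tolerance = 1e-5)

  # low noise: strict best response, and no overflow
  p_cold <- logit_probabilities(st, c(2, 2), game5, K = 0.01)
  expect_true(all(is.finite(p_cold)))
  expect_gt(p_cold[1], 0.999)

  expect_error(logit_probabilities(st, c(2, 2), game5, K = 0), "positive")
  expect_error(logit_probabilities(st, c(2, 2), game5, K = -1), "positive")
})

test_that("probabilities are invariant under a constant payoff shift", {
  st <- lattice_state(4, game5, init = "random", seed = 3)
  shifted <- game_spec(game5$A - 2.25)
  for (site in list(c(1, 1), c(2, 3), c(4, 4))) {
    expect_equal(logit_probabilities(st, site, game5, 0.7),
                 logit_probabilities(st, site, shifted, 0.7),
                 tolerance = 1e-12)
  }
})

test_that("Monte Carlo steps are reproducible and absorbing at low noise", {
  a <- mc_step(lattice_state(8, game5, "random", seed = 5), game5, 1.2,
               steps = 15, seed = 77)
  b <- mc_step(lattice_state(8, game5, "random", seed = 5), game5, 1.2,
               steps = 15, seed = 77)
  expect_identical(a$sites, b$sites)

  # deep in the ordered phase the uniform state is effectively absorbing
  uni <- lattice_state(8, game5, init = "uniform:1")
  out <- mc_step(uni, game5, K = 0.01, steps = 20, seed = 1)
  expect_identical(out$sites, uni$sites)
})

test_that("exact enumeration reproduces the hand-computed 2x2 partition sum", {
  # 16 configurations fall in three potential classes: U = 8 (2 uniform),
  # U = 0 (12 mixed), U = -8 (2 antiphase)
  K <- 2
  Z <- 2 * exp(8 / K) + 12 + 2 * exp(-8 / K)
  U_mean <- (16 * exp(8 / K) - 16 * exp(-8 / K)) / Z
  ex <- boltzmann_exact(ising2, K = K, L = 2)
  expect_equal(ex$potential_per_player, U_mean / 4, tolerance = 1e-12)
  expect_equal(ex$payoff_per_player, U_mean / 2, tolerance = 1e-12)
  expect_equal(ex$log_Z, log(Z), tolerance = 1e-12)
  expect_equal(ex$rho_1, 0.5, tolerance = 1e-12)
})

test_that("exact enumeration tends to the uniform distribution at high noise", {
  ex <- boltzmann_exact(game5, K = 1e8, L = 2)
  expect_equal(unlist(ex[paste0("rho_", 1:5)]), rep(0.2, 5),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(boltzmann_exact(game5, K = 1, L = 5), "exceeds")
})

test_that("long-run MC frequencies match exact enumeration on 3x3 lattices", {
  # n = 2 Ising block at K = 2
  obs <- function(cfg) abs(rowMeans(cfg == 1) - rowMeans(cfg == 2))
  ex <- boltzmann_exact(ising2, K = 2, L = 3, observable = obs)
  set.seed(42)
  st <- mc_step(lattice_state(3, ising2, "random"), ising2, 2, steps = 1000)
  n_samp <- 40000
  m_abs <- numeric(n_samp); U <- numeric(n_samp)
  for (t in seq_len(n_samp)) {
    st <- mc_step(st, ising2, 2, steps = 1)
    rho <- tabulate(st$sites, 2) / 9
    m_abs[t] <- abs(rho[1] - rho[2])
    U[t] <- total_potential(st, ising2) / 9
  }
  expect_lt(abs(mean(m_abs) - ex$observable), 3 * series_se(m_abs))
  expect_lt(abs(mean(U) - ex$potential_per_player), 3 * series_se(U))

  # n = 3 Potts block at K = 1, via a color-symmetric order parameter
  # (per-color frequencies do not equilibrate: color tunneling is rare)
  ex3 <- boltzmann_exact(potts3, K = 1, L = 3, observable = function(cfg)
    (3 * apply(cfg, 1, function(x) max(tabulate(x, 3))) / 9 - 1) / 2)
  set.seed(43)
  st <- mc_step(lattice_state(3, potts3, "random"), potts3, 1, steps = 1000)
  mp <- numeric(n_samp)
  for (t in seq_len(n_samp)) {
    st <- mc_step(st, potts3, 1, steps = 1)
    mp[t] <- (3 * max(tabulate(st$sites, 3)) / 9 - 1) / 2
  }
  expect_lt(abs(mean(mp) - ex3$observable), 3 * series_se(mp))
})

test_that("the logit rule satisfies detailed balance for potential games", {
  for (seed in 1:3) {
    st <- make_fixture("random", L = 4, seed = seed)
    for (site in list(c(1, 1), c(3, 2))) {
      chk <- detailed_balance_check(game5, K = 0.9, st, site)
      expect_true(chk$applicable)
      expect_lt(chk$max_abs_log_ratio, 1e-10)
    }
  }
  # n = 2 block
  st2 <- lattice_state(4, ising2, "random", seed = 9)
  chk <- detailed_balance_check(ising2, K = 2.5, st2, c(2, 2))
  expect_lt(chk$max_abs_log_ratio, 1e-10)
  # negative control: asymmetric matrix is flagged inapplicable
  bad <- game_spec(matrix(c(1, -1, 0.5, 1), 2, 2))
  chk_bad <- detailed_balance_check(bad, K = 1, st2, c(2, 2))
  expect_false(chk_bad$applicable)
})

test_that("run_simulation averages, records trajectories, and degrades cleanly", {
  # deep ordered phase keeps the prepared strategy
  sim <- run_simulation(game5, K = 0.2, L = 16, t_relax = 100, t_sample = 100,
                        init = "uniform:1", seed = 2)
  expect_gt(sim$freq$rho[1], 0.99)
  expect_equal(sum(sim$freq$rho), 1, tolerance = 1e-12)
  expect_equal(sim$summary$payoff_per_player,
               2 * sim$summary$potential_per_player)

  # t_sample = 0: instantaneous frequencies, no averaging
  sim0 <- run_simulation(game5, K = 1, L = 8, t_relax = 10, t_sample = 0,
                         seed = 3)
  expect_equal(sum(sim0$freq$rho), 1)
  expect_true(all(is.na(sim0$freq$se)))

  # log-spaced trajectory covers the run and conserves probability
  simt <- run_simulation(game5, K = 1, L = 16, t_relax = 200, t_sample = 200,
                         init = "random", seed = 4, record = "log")
  expect_gt(nrow(simt$trajectory), 10)
  rho_cols <- as.matrix(simt$trajectory[paste0("rho_", 1:5)])
  expect_equal(rowSums(rho_cols), rep(1, nrow(rho_cols)), tolerance = 1e-12)
  expect_equal(max(simt$trajectory$t_mcs), 400)
  sm <- smooth_trajectory(simt$trajectory)
  expect_equal(dim(sm), dim(simt$trajectory))
})

test_that("high-noise frequencies approach 1/n", {
  # the limit is 1/n as K grows; at K = 5 a small real correlation excess
  # of the Ising pair over the Potts strategies remains
  sim <- run_simulation(game5, K = 5, L = 32, t_relax = 300, t_sample = 1500,
                        seed = 8)
  expect_true(all(abs(sim$freq$rho - 0.2) < 0.005))
})
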