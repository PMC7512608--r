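test_that("order parameters pick out the ordered phases", {
  op <- order_parameters(c(1, 0, 0, 0, 0))
  expect_equal(op$m_ising, 1); expect_equal(op$m_potts, 0)
  op <- order_parameters(c(0, 0, 1, 0, 0))
  expect_equal(op$m_ising, 0); expect_equal(op$m_potts, 1)
  op <- order_parameters(rep(0.2, 5))
  expect_equal(op$m_ising, 0); expect_equal(op$m_potts, 0)
  # relabeling maps any within-family permutation to the convention
  op <- order_parameters(c(0.1, 0.6, 0.05, 0.2, 0.05))
  expect_equal(op$m_ising, 0.5)
  expect_equal(op$m_potts, 0.2 - 0.05)
  expect_equal(relabel_frequencies(c(0.1, 0.3, 0.1, 0.3, 0.2)),
               c(0.3, 0.1, 0.3, 0.2, 0.1))
  # data frame input, several rows
  df <- tibble::tibble(rho_1 = c(1, 0.2), rho_2 = c(0, 0.2),
                       rho_3 = c(0, 0.2), rho_4 = c(0, 0.2),
                       rho_5 = c(0, 0.2))
  expect_equal(order_parameters(df)$m_ising, c(1, 0))
})

test_that("power-law fits recover their own generating parameters", {
  set.seed(100)
  cases <- expand.grid(beta = c(1 / 8, 1 / 9, 0.075), K_c = c(1.0, 1.2))
  for (i in seq_len(nrow(cases))) {
    beta <- cases$beta[i]; K_c <- cases$K_c[i]
    K <- seq(0.85 * K_c, 0.995 * K_c, length.out = 14)
    m <- 1.2 * ((K_c - K) / K_c)^beta
    d <- data.frame(K = K, m = m * (1 + rnorm(length(m), 0, 1e-3)))
    fit <- fit_power_law(d, n_boot = 100)
    est <- setNames(fit$estimate$estimate, fit$estimate$term)
    expect_lt(abs(est["beta"] - beta), 0.01)
    expect_lt(abs(est["K_c"] - K_c), 0.002)
  }
})

test_that("fitting the exact Ising magnetization curve returns beta near 1/8", {
  Kc <- 2 / log(1 + sqrt(2))
  K <- seq(2.17, 2.2665, length.out = 14)
  d <- data.frame(K = K, m = onsager_magnetization(K))
  fit <- fit_power_law(d, n_boot = 50)
  est <- setNames(fit$estimate$estimate, fit$estimate$term)
  expect_lt(abs(est["beta"] - 0.125), 0.005)
  expect_lt(abs(est["K_c"] - Kc), 0.005)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$nobs, fit$n_window)
})

test_that("power-law fitting refuses hopeless inputs", {
  expect_error(fit_power_law(data.frame(K = 1:3, m = c(1, 2, 3))), "at least")
})

test_that("Binder cumulant has the textbook limits", {
  # ordered phase: m concentrates at +/- m0, so <m^4> = <m^2>^2
  mom_ord <- tibble::tibble(L = 16, K = 1, m2 = 0.81, m4 = 0.81^2)
  expect_equal(binder_cumulant(mom_ord)$U, 2 / 3)
  # Gaussian disordered phase: <m^4> = 3 <m^2>^2
  mom_dis <- tibble::tibble(L = 16, K = 9, m2 = 0.01, m4 = 3 * 0.01^2)
  expect_equal(binder_cumulant(mom_dis)$U, 0)
})

test_that("binder_crossing interpolates the sign change of the difference", {
  K <- seq(2.2, 2.34, by = 0.02)
  # synthetic curves crossing at 2.269
  U16 <- 0.61 - 0.8 * (K - 2.269)
  U32 <- 0.61 - 2.0 * (K - 2.269)
  mom <- dplyr::bind_rows(
    tibble::tibble(L = 16, K = K, m2 = 1, m4 = 3 * (1 - U16)),
    tibble::tibble(L = 32, K = K, m2 = 1, m4 = 3 * (1 - U32))
  )
  cr <- binder_crossing(mom)
  expect_true(cr$found)
  expect_equal(cr$K_c, 2.269, tolerance = 1e-6)
  # parallel curves never cross
  mom$m4[mom$L == 32] <- 3 * (1 - (U16 - 0.05))
  expect_false(binder_crossing(mom)$found)
})

test_that("entropy/payoff curves report the documented phase structure", {
  tbl <- entropy_payoff_curves(game5, K_values = c(0.2, 0.9), L = 48,
                               t_relax = 800, t_sample = 800, seed = 10)
  expect_true(all(!tbl$escaped))
  expect_equal(tbl$payoff_per_player, 2 * tbl$potential_per_player,
               tolerance = 1e-12)
  # entropy contribution vanishes at low noise
  low <- dplyr::filter(tbl, K == 0.2)
  expect_true(all(low$KS < 0.05))
  # below the transition the Ising phase is the less ordered, higher-entropy one
  near <- dplyr::filter(tbl, K == 0.9)
  expect_gt(near$entropy[near$phase == "ising"],
            near$entropy[near$phase == "potts"])
  # minority structure: Potts phase splits its minorities 2 + 2,
  # the Ising phase 3 + 1
  pr <- relabel_frequencies(as.numeric(
    near[near$phase == "potts", paste0("rho_", 1:5)]))
  # the two Ising minorities sit above the two losing Potts minorities
  expect_gt(min(pr[1:2]), max(pr[4:5]))
  ir <- relabel_frequencies(as.numeric(
    near[near$phase == "ising", paste0("rho_", 1:5)]))
  # in the Ising phase the three Potts minorities are equal and exceed the
  # discoordinated Ising strategy
  expect_gt(min(ir[3:5]), ir[2])
})

test_that("trajectory recording feeds the domain-growth plot", {
  sim <- run_simulation(game5, K = 0.9, L = 24, t_relax = 100, t_sample = 0,
                        init = "random", seed = 6, record = "log")
  p <- ggplot2::autoplot(sim)
  expect_s3_class(p, "ggplot")
})
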