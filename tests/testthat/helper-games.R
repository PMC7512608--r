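# shared fixtures: games and small helpers used across the suite

game5 <- ising_potts_game(1)
ising2 <- coordination_game(2)
potts3 <- potts_game(1, 3)

# batch-mean standard error for a correlated scalar series
series_se <- function(x, n_batches = 20) {
  idx <- cut(seq_along(x), n_batches, labels = FALSE)
  b <- tapply(x, idx, mean)
  sd(b) / sqrt(length(b))
}

# sample a scalar observable of the frequency vector over t_sample MCS
sample_observable <- function(game, K, L, fn, t_relax, t_sample, seed,
                              init = "random") {
  set.seed(seed)
  st <- lattice_state(L, game, init = init)
  st <- mc_step(st, game, K, steps = t_relax)
  out <- numeric(t_sample)
  for (t in seq_len(t_sample)) {
    st <- mc_step(st, game, K, steps = 1)
    rho <- tabulate(st$sites, nbins = game$n) / (L * L)
    out[t] <- fn(rho, st)
  }
  out
}
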