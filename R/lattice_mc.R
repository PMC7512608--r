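#' Create a lattice state
#'
#' An `L x L` periodic square lattice of strategy labels in `1..n`, the
#' playing field of the spatial game. Initial conditions: `"random"` (uniform
#' over all `n` strategies), `"uniform:i"` (every player uses strategy `i`;
#' the canonical prepared Ising-ordered state is `"uniform:1"`, the prepared
#' Potts-ordered state `"uniform:3"`), or a custom integer matrix.
#'
#' @param L linear lattice size.
#' @param game a [game_spec()] (only `n` is used) or an integer strategy count.
#' @param init `"random"`, `"uniform:i"`, or an `L x L` integer matrix.
#' @param seed optional integer seed applied via [set.seed()] before drawing a
#'   random initial state.
#' @return An object of class `lattice_state`: a list with `sites` (integer
#'   matrix) and `n`.
#' @examples
#' lattice_state(8, ising_potts_game(1), init = "uniform:3")
#' @export
lattice_state <- function(L, game, init = "random", seed = NULL) {
  n <- if (inherits(game, "game_spec")) game$n else as.integer(game)
  if (is.matrix(init)) {
    sites <- init
    storage.mode(sites) <- "integer"
    if (nrow(sites) != L || ncol(sites) != L) {
      stop("custom `init` must be an L x L matrix", call. = FALSE)
    }
  } else if (identical(init, "random")) {
    if (!is.null(seed)) set.seed(seed)
    sites <- matrix(sample.int(n, L * L, replace = TRUE), L, L)
  } else if (grepl("^uniform:[0-9]+$", init)) {
    k <- as.integer(sub("^uniform:", "", init))
    if (k < 1 || k > n) stop("uniform strategy out of 1..n", call. = FALSE)
    sites <- matrix(k, L, L)
  } else {
    stop("unknown `init`: ", init, call. = FALSE)
  }
  if (any(sites < 1L | sites > n)) {
    stop("strategy labels must lie in 1..n", call. = FALSE)
  }
  structure(list(sites = sites, n = n), class = "lattice_state")
}

lattice_sites <- function(state) {
  if (inherits(state, "lattice_state")) state$sites else {
    s <- as.matrix(state); storage.mode(s) <- "integer"; s
  }
}

#' @export
print.lattice_state <- function(x, ...) {
  L <- nrow(x$sites)
  cnt <- as.integer(cpp_strategy_counts(x$sites, x$n))
  cat(sprintf("<lattice_state> %d x %d, n = %d; counts: %s\n",
              L, L, x$n, paste(cnt, collapse = " ")))
  invisible(x)
}

#' Logit choice distribution at one site
#'
#' Probability that the player at `site` adopts each of the `n` candidate
#' strategies, proportional to `exp(u(s') / K)` where `u(s')` is the income
#' the candidate strategy would earn against the current four neighbors. The
#' current strategy is included in the normalization. Computed with
#' max-shifted exponentials, so small `K` cannot overflow.
#'
#' @inheritParams player_payoff
#' @param K noise level (temperature), must be positive.
#' @return Numeric vector of `n` probabilities summing to 1.
#' @export
logit_probabilities <- function(state, site, game, K) {
  check_K(K)
  s <- lattice_sites(state)
  nb <- neighbor_strategies(s, site[1], site[2])
  u <- rowSums(game$A[, nb, drop = FALSE])
  w <- exp((u - max(u)) / K)
  w / sum(w)
}

check_K <- function(K) {
  if (!is.numeric(K) || length(K) != 1 || is.na(K) || K <= 0) {
    stop("noise level `K` must be a single positive number", call. = FALSE)
  }
  invisible(K)
}

#' Advance the lattice by whole Monte Carlo steps
#'
#' One Monte Carlo step (MCS) performs `N = L^2` single-site logit updates at
#' independently drawn random sites (with replacement), so each player gets
#' one revision opportunity on average. Reproducible through R's RNG: call
#' [set.seed()] (or pass `seed`) before a run.
#'
#' @param state a [lattice_state()].
#' @param game a [game_spec()].
#' @param K noise level (> 0).
#' @param steps number of MCS to perform.
#' @param seed optional integer seed applied before updating.
#' @return The evolved `lattice_state`.
#' @export
mc_step <- function(state, game, K, steps = 1, seed = NULL) {
  check_K(K)
  if (!is.null(seed)) set.seed(seed)
  state$sites <- cpp_mc_sweeps(state$sites, game$A, K, as.integer(steps))
  state
}

measure_state <- function(state, game) {
  N <- length(state$sites)
  rho <- as.numeric(cpp_strategy_counts(state$sites, state$n)) / N
  U <- if (game$symmetric) cpp_total_potential(state$sites, game$V) / N else NA_real_
  list(rho = rho, potential = U, payoff = 2 * U)
}

#' Run a logit-rule Monte Carlo simulation
#'
#' Relaxes for `t_relax` MCS, then measures strategy frequencies and the
#' per-player payoff/potential every MCS for `t_sample` MCS and averages.
#' With `t_sample = 0` the final instantaneous frequencies are reported.
#' Optionally records a log-spaced trajectory (for domain-growth studies)
#' covering both the relaxation and sampling stages.
#'
#' @inheritParams mc_step
#' @param L linear lattice size.
#' @param t_relax,t_sample relaxation and sampling times in MCS.
#' @param init initial condition, see [lattice_state()].
#' @param seed integer seed for reproducibility.
#' @param record `"none"` or `"log"` (log-spaced trajectory points).
#' @param n_batches batches used for Monte Carlo standard errors of the
#'   sampled frequencies.
#' @return A list of class `sim_result`:
#' \describe{
#'   \item{freq}{tibble with one row per strategy: `strategy`, `rho`, `se`.}
#'   \item{summary}{one-row tibble: `K`, `L`, `payoff_per_player`,
#'     `potential_per_player`, `t_relax`, `t_sample`.}
#'   \item{trajectory}{tibble `t_mcs`, `rho_1..rho_n`, `payoff_per_player`,
#'     `potential_per_player` (empty when `record = "none"`).}
#'   \item{state}{final [lattice_state()].}
#' }
#' @examples
#' \donttest{
#' run_simulation(ising_potts_game(1), K = 5, L = 16,
#'                t_relax = 50, t_sample = 50, seed = 1)
#' }
#' @export
run_simulation <- function(game, K, L = 64, t_relax = 1e4, t_sample = 1e4,
                           init = "random", seed = NULL, record = "none",
                           n_batches = 20) {
  check_K(K)
  if (!is.null(seed)) set.seed(seed)
  state <- lattice_state(L, game, init = init)
  n <- game$n

  rec_times <- integer(0)
  if (identical(record, "log")) {
    tmax <- t_relax + t_sample
    rec_times <- unique(c(0L, as.integer(round(
      exp(seq(0, log(max(tmax, 1)), length.out = 60L))
    )), as.integer(tmax)))
    rec_times <- sort(rec_times[rec_times <= tmax])
  }
  traj <- list()
  record_point <- function(t, m) {
    traj[[length(traj) + 1L]] <<- c(t_mcs = t, setNames(m$rho, paste0("rho_", 1:n)),
                                    payoff_per_player = m$payoff,
                                    potential_per_player = m$potential)
  }
  if (length(rec_times) && 0L %in% rec_times) {
    record_point(0L, measure_state(state, game))
  }

  t_now <- 0L
  advance_to <- function(t_target) {
    while (t_now < t_target) {
      nxt <- rec_times[rec_times > t_now & rec_times <= t_target]
      step_to <- if (length(nxt)) min(nxt) else t_target
      state$sites <<- cpp_mc_sweeps(state$sites, game$A, K, step_to - t_now)
      t_now <<- step_to
      if (step_to %in% rec_times) record_point(step_to, measure_state(state, game))
    }
  }

  advance_to(as.integer(t_relax))

  if (t_sample > 0) {
    rho_acc <- matrix(0, as.integer(t_sample), n)
    U_acc <- numeric(as.integer(t_sample))
    for (i in seq_len(as.integer(t_sample))) {
      advance_to(t_now + 1L)
      m <- measure_state(state, game)
      rho_acc[i, ] <- m$rho
      U_acc[i] <- m$potential
    }
    rho <- colMeans(rho_acc)
    se <- batch_se(rho_acc, n_batches)
    U <- mean(U_acc)
  } else {
    m <- measure_state(state, game)
    rho <- m$rho
    se <- rep(NA_real_, n)
    U <- m$potential
  }

  traj_tbl <- if (length(traj)) {
    tibble::as_tibble(do.call(rbind, traj))
  } else {
    tibble::tibble()
  }
  structure(list(
    freq = tibble::tibble(strategy = seq_len(n), rho = rho, se = se),
    summary = tibble::tibble(K = K, L = L, payoff_per_player = 2 * U,
                             potential_per_player = U,
                             t_relax = t_relax, t_sample = t_sample),
    trajectory = traj_tbl,
    state = state
  ), class = "sim_result")
}

batch_se <- function(x, n_batches) {
  x <- as.matrix(x)
  nb <- min(n_batches, nrow(x))
  idx <- cut(seq_len(nrow(x)), nb, labels = FALSE)
  bm <- apply(x, 2, function(col) tapply(col, idx, mean))
  apply(as.matrix(bm), 2, function(col) sd(col) / sqrt(length(col)))
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>\n")
  print(x$summary)
  print(x$freq)
  invisible(x)
}

#' Smooth a recorded trajectory with a proportional window
#'
#' Averages each recorded observable over the recorded points falling in
#' `[(1 - half_width) t, (1 + half_width) t]`, the standard smoothing for
#' log-spaced domain-growth curves.
#'
#' @param trajectory a trajectory tibble from [run_simulation()].
#' @param half_width relative half-width of the window (default 0.05).
#' @return A tibble of the same shape.
#' @export
smooth_trajectory <- function(trajectory, half_width = 0.05) {
  t <- trajectory$t_mcs
  out <- trajectory
  num <- setdiff(names(trajectory), "t_mcs")
  for (i in seq_along(t)) {
    w <- which(t >= (1 - half_width) * t[i] & t <= (1 + half_width) * t[i])
    out[i, num] <- as.list(colMeans(trajectory[w, num, drop = FALSE]))
  }
  out
}

#' Exact Boltzmann expectations by full enumeration
#'
#' Enumerates all `n^(L^2)` strategy configurations of a tiny periodic
#' lattice, weights each by `exp(U(s) / K)`, and returns exact stationary
#' expectations — the oracle against which the Monte Carlo engine is tested.
#' Only potential games (symmetric `A`) have a Boltzmann stationary state.
#'
#' @inheritParams run_simulation
#' @param L linear size of the tiny lattice.
#' @param observable optional function taking an integer configuration matrix
#'   (rows = configurations, `L^2` columns, column-major site order) and
#'   returning one number per row; its exact expectation is reported in an
#'   `observable` column.
#' @param max_configs refuse enumerations larger than this.
#' @return One-row tibble: `rho_1..rho_n`, `potential_per_player`,
#'   `payoff_per_player`, `log_Z` and optionally `observable`.
#' @export
boltzmann_exact <- function(game, K, L, observable = NULL, max_configs = 1e7) {
  check_K(K)
  if (!game$symmetric) {
    stop("Boltzmann enumeration requires a potential game (symmetric A)",
         call. = FALSE)
  }
  n <- game$n
  M <- L * L
  n_cfg <- n^M
  if (n_cfg > max_configs) {
    stop(sprintf("enumeration of %d^%d = %.3g configurations exceeds the %g guard",
                 n, M, n_cfg, max_configs), call. = FALSE)
  }
  edges <- torus_edges(L)
  V <- game$V

  chunk <- 2e5
  starts <- seq(0, n_cfg - 1, by = chunk)
  Uall <- numeric(n_cfg)
  for (s0 in starts) {
    ids <- s0:min(s0 + chunk - 1, n_cfg - 1)
    cfg <- decode_configs(ids, n, M)
    U <- numeric(length(ids))
    for (e in seq_len(nrow(edges))) {
      U <- U + V[cbind(cfg[, edges[e, 1]], cfg[, edges[e, 2]])]
    }
    Uall[ids + 1] <- U
  }
  Umax <- max(Uall)
  w <- exp((Uall - Umax) / K)
  Z <- sum(w)
  p <- w / Z

  rho <- numeric(n)
  obs <- 0
  for (s0 in starts) {
    ids <- s0:min(s0 + chunk - 1, n_cfg - 1)
    cfg <- decode_configs(ids, n, M)
    pw <- p[ids + 1]
    for (i in seq_len(n)) {
      rho[i] <- rho[i] + sum(pw * rowSums(cfg == i)) / M
    }
    if (!is.null(observable)) obs <- obs + sum(pw * observable(cfg))
  }
  Upp <- sum(p * Uall) / M
  out <- tibble::tibble(
    !!!setNames(as.list(rho), paste0("rho_", seq_len(n))),
    potential_per_player = Upp,
    payoff_per_player = 2 * Upp,
    log_Z = log(Z) + Umax / K
  )
  if (!is.null(observable)) out$observable <- obs
  out
}

# 2N directed-down/right edges of the L x L torus = all 2N undirected bonds
# (for L = 2 this correctly doubles each bond, matching the 4-neighbor sum).
torus_edges <- function(L) {
  idx <- matrix(seq_len(L * L), L, L)
  down <- rbind(idx[-1, , drop = FALSE], idx[1, , drop = FALSE])
  right <- cbind(idx[, -1, drop = FALSE], idx[, 1, drop = FALSE])
  rbind(cbind(as.vector(idx), as.vector(down)),
        cbind(as.vector(idx), as.vector(right)))
}

decode_configs <- function(ids, n, M) {
  cfg <- matrix(0L, length(ids), M)
  x <- ids
  for (j in seq_len(M)) {
    cfg[, j] <- as.integer(x %% n) + 1L
    x <- x %/% n
  }
  cfg
}

#' Detailed-balance diagnostic for the logit rule
#'
#' For a potential game the logit rule satisfies
#' `p(s) w(s -> s') = p(s') w(s' -> s)` for every single-site flip, because
#' the income change of the revising player equals the change in the total
#' potential. This check evaluates the balance ratio for every candidate flip
#' at `site` using potential differences and reports the worst deviation.
#'
#' @inheritParams logit_probabilities
#' @return A list with `applicable` (FALSE for asymmetric games),
#'   `max_abs_log_ratio`, and a tibble `flips` of per-flip diagnostics.
#' @export
detailed_balance_check <- function(game, K, state, site) {
  check_K(K)
  if (!game$symmetric) {
    return(list(applicable = FALSE, max_abs_log_ratio = NA_real_,
                flips = tibble::tibble()))
  }
  s <- lattice_sites(state)
  st <- if (inherits(state, "lattice_state")) state else lattice_state(nrow(s), game, init = s)
  n <- game$n
  cur <- s[site[1], site[2]]
  w_fwd <- logit_probabilities(st, site, game, K)
  res <- purrr::map_dfr(seq_len(n), function(k) {
    s2 <- st
    s2$sites[site[1], site[2]] <- k
    # w(s' -> s) from the flipped state; neighbors unchanged so w is the same
    w_bwd <- logit_probabilities(s2, site, game, K)
    dU <- total_potential(s2, game) - total_potential(st, game)
    log_ratio <- dU / K - (log(w_fwd[k]) - log(w_bwd[cur]))
    tibble::tibble(from = cur, to = k, delta_U = dU, log_ratio_deviation = log_ratio)
  })
  list(applicable = TRUE,
       max_abs_log_ratio = max(abs(res$log_ratio_deviation)),
       flips = res)
}
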