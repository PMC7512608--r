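#' Construct / validate a pair state
#'
#' A `pair_state` is the symmetric joint distribution `p2(i, j)` of the
#' strategies at the two ends of a randomly chosen nearest-neighbor edge
#' (normalized over ordered pairs, so `sum(p2) = 1` and `p2 = t(p2)`). Its
#' marginal `p1(i) = sum_j p2(i, j)` gives the strategy frequencies.
#'
#' @param p2 numeric `n x n` matrix of joint probabilities.
#' @return An object of class `pair_state` (the validated matrix).
#' @export
pair_state <- function(p2) {
  p2 <- as.matrix(p2)
  if (nrow(p2) != ncol(p2) || any(p2 < -1e-12)) {
    stop("`p2` must be a square nonnegative matrix", call. = FALSE)
  }
  if (abs(sum(p2) - 1) > 1e-8) stop("`p2` must sum to 1", call. = FALSE)
  if (max(abs(p2 - t(p2))) > 1e-8) stop("`p2` must be symmetric", call. = FALSE)
  structure((p2 + t(p2)) / 2, class = "pair_state")
}

pair_marginal <- function(p2) rowSums(unclass(p2))

#' Pair-approximation thermodynamic potential per site
#'
#' Two-site cluster-variation estimate on the square lattice:
#' `Phi / N = 2 sum p2 A - 2 K sum p2 log p2 + 3 K sum p1 log p1`
#' with the marginal `p1` obtained from the compatibility conditions. For an
#' independent pair distribution `p2 = p1 p1'` this reduces exactly to the
#' mean-field [mf_phi()] of the marginal (Bethe entropy identity).
#'
#' @param pair a [pair_state()] (or plain symmetric matrix).
#' @param game a [game_spec()] with symmetric `A`.
#' @param K noise level (> 0).
#' @return `Phi` per site (payoff units).
#' @export
pair_phi <- function(pair, game, K) {
  check_K(K)
  p2 <- unclass(pair)
  p1 <- rowSums(p2)
  xlx <- function(x) { nz <- x > 0; sum(x[nz] * log(x[nz])) }
  2 * sum(p2 * game$A) - 2 * K * xlx(p2) + 3 * K * xlx(p1)
}

# Precomputed neighborhood tables for the pair-approximation flow: all n^4
# ordered 4-neighbor configurations, their per-strategy counts, and the logit
# choice matrix W (config x candidate) at noise K.
pair_tables <- function(game, K) {
  n <- game$n
  cfg <- as.matrix(expand.grid(j1 = 1:n, j2 = 1:n, j3 = 1:n, j4 = 1:n))
  A <- game$A
  u <- t(A[, cfg[, 1]] + A[, cfg[, 2]] + A[, cfg[, 3]] + A[, cfg[, 4]])
  u <- u / K
  u <- u - apply(u, 1, max)
  W <- exp(u)
  W <- W / rowSums(W)
  Cmat <- vapply(1:n, function(b) rowSums(cfg == b), numeric(nrow(cfg)))
  list(n = n, cfg = cfg, W = W, C = Cmat)
}

# Time derivative of p2 under single-site logit dynamics closed at the pair
# level: a focal site in strategy i sees 4 neighbors drawn iid from the
# conditional p2(.|i) and flips to k with the logit probability of that
# neighborhood; each flip rewrites the 4 edges at the focal site (the focal
# edge seen from both ends plus the side edges), collected here over all
# ordered configurations. Conserves normalization and symmetry exactly.
pair_rate <- function(p2, tab) {
  n <- tab$n
  p1 <- rowSums(p2)
  G <- matrix(0, n, n)
  for (i in 1:n) {
    if (p1[i] <= 0) next
    cond <- p2[i, ] / p1[i]
    P <- cond[tab$cfg[, 1]] * cond[tab$cfg[, 2]] *
         cond[tab$cfg[, 3]] * cond[tab$cfg[, 4]]
    G <- G + p1[i] * crossprod(tab$W, P * tab$C)
  }
  (G + t(G)) / 4 - 2 * p2
}

#' One explicit-Euler step of the pair-approximation dynamics
#'
#' Advances the pair distribution by `dt` along the pair-closed master
#' equation for single-site logit flips. The step is rejected and `dt` halved
#' (internally) if any probability would leave `[0, 1]`.
#'
#' @inheritParams pair_phi
#' @param dt time step.
#' @return The evolved [pair_state()] with attribute `dt_used`.
#' @export
pair_dynamics_step <- function(pair, game, K, dt = 0.1) {
  tab <- pair_tables(game, K)
  p2 <- unclass(pair)
  dp <- pair_rate(p2, tab)
  while (TRUE) {
    p2_new <- p2 + dt * dp
    if (all(p2_new >= 0) && all(p2_new <= 1)) break
    dt <- dt / 2
    if (dt < 1e-12) stop("pair dynamics step underflow", call. = FALSE)
  }
  out <- pair_state(p2_new)
  attr(out, "dt_used") <- dt
  out
}

pair_seed <- function(game, start, eps = 0.02) {
  n <- game$n
  p1 <- switch(start,
    uniform = rep(1 / n, n),
    ising = { v <- rep(eps, n); v[1] <- 1 - (n - 1) * eps; v },
    potts = { v <- rep(eps, n); v[min(3, n)] <- 1 - (n - 1) * eps; v },
    stop("unknown start: ", start, call. = FALSE)
  )
  pair_state(outer(p1, p1))
}

# Integrate the pair flow to a fixed point (adaptive explicit Euler).
pair_converge <- function(game, K, p2, tol = 1e-10, dt0 = 0.2,
                          max_steps = 2e5) {
  tab <- pair_tables(game, K)
  p2 <- unclass(p2)
  dt <- dt0
  for (it in seq_len(max_steps)) {
    dp <- pair_rate(p2, tab)
    res <- max(abs(dp))
    if (res < tol) {
      return(list(p2 = pair_state(p2), converged = TRUE, residual = res,
                  steps = it))
    }
    repeat {
      p2_new <- p2 + dt * dp
      if (all(p2_new >= 0) && all(p2_new <= 1)) break
      dt <- dt / 2
      if (dt < 1e-12) stop("pair dynamics step underflow", call. = FALSE)
    }
    p2 <- (p2_new + t(p2_new)) / 2
    p2 <- p2 / sum(p2)
    dt <- min(dt * 1.05, 0.4)
  }
  list(p2 = pair_state(p2), converged = FALSE, residual = res,
       steps = max_steps)
}

pair_branch_label <- function(p2, game, tol = 1e-3) {
  mf_branch_label(pair_marginal(p2), game, tol = tol)
}

# Stationarity residual of Phi(2) under symmetric, normalized perturbations:
# at a constrained extremum 2 A - 2 K (log p2 + 1) + (3K/2)(log p1_a +
# log p1_b + 2) must be constant over the support of p2.
pair_phi_stationarity <- function(p2, game, K) {
  p2 <- unclass(p2)
  p1 <- rowSums(p2)
  h <- 2 * game$A - 2 * K * (log(p2) + 1) +
    (3 * K / 2) * (outer(log(p1), log(p1), `+`) + 2)
  supp <- p2 > 1e-12
  lambda <- sum(h[supp] * p2[supp]) / sum(p2[supp])
  max(abs(h[supp] - lambda))
}

# Numerical Jacobian of the pair flow on the symmetric-normalized tangent
# space; a fixed point is dynamically stable when no eigenvalue is positive.
pair_flow_stable <- function(p2, game, K, tol = 1e-8, h = 1e-7) {
  p2 <- unclass(p2)
  n <- nrow(p2)
  tab <- pair_tables(game, K)
  # raw basis: elementary symmetric matrices, projected onto total-sum zero
  E <- vapply(seq_len(n * (n + 1) / 2), function(idx) {
    k <- 0
    for (a in 1:n) for (b in a:n) {
      k <- k + 1
      if (k == idx) {
        D <- matrix(0, n, n); D[a, b] <- D[b, a] <- 1
        return(as.vector(D))
      }
    }
  }, numeric(n * n))
  E <- sweep(E, 2, colSums(E) / (n * n))
  qrE <- qr(E)
  Q <- qr.Q(qrE)[, seq_len(qrE$rank), drop = FALSE]
  base <- pair_rate(p2, tab)
  M <- vapply(seq_len(ncol(Q)), function(j) {
    D <- matrix(Q[, j], n, n)
    as.vector(pair_rate(p2 + h * D, tab) - base) / h
  }, numeric(n * n))
  ev <- eigen(crossprod(Q, M), only.values = TRUE)$values
  max(Re(ev)) < tol
}

#' Stationary pair-approximation solutions at one noise level
#'
#' Integrates the pair-approximation equations of motion from a set of
#' ordered and disordered initial states, deduplicates the fixed points,
#' evaluates `Phi(2)`, verifies `Phi(2)` stationarity as a post-condition,
#' and classifies dynamical stability. Metastable ordered branches are fixed
#' points of the flow, which is what gives access to the first-order
#' transition between them.
#'
#' @inheritParams pair_phi
#' @param starts character vector among `"ising"`, `"potts"`, `"uniform"`.
#' @param tol convergence tolerance on `max |dp2/dt|`.
#' @param max_steps Euler step budget per start.
#' @return A tibble: `branch`, `rho_1..rho_n`, `phi_per_site`,
#'   `phi_stationarity`, `stable`, `converged`, `residual`, plus the pair
#'   matrices in the list column `p2`.
#' @export
pair_stationary <- function(game, K, starts = c("ising", "potts", "uniform"),
                            tol = 1e-10, max_steps = 2e5) {
  if (!game$symmetric) stop("pair solver requires a potential game", call. = FALSE)
  if (is.null(game$alpha) || game$alpha == 0) {
    starts <- setdiff(starts, "potts")
  }
  sols <- purrr::map(starts, function(s0) {
    pair_converge(game, K, pair_seed(game, s0), tol = tol,
                  max_steps = max_steps)
  })
  keep <- list()
  for (s in sols) {
    dup <- any(vapply(keep, function(k) {
      max(abs(unclass(k$p2) - unclass(s$p2))) < 1e-6
    }, logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- s
  }
  purrr::map_dfr(keep, function(s) {
    p1 <- pair_marginal(s$p2)
    tibble::tibble(
      branch = pair_branch_label(s$p2, game),
      !!!setNames(as.list(p1), paste0("rho_", seq_along(p1))),
      phi_per_site = pair_phi(s$p2, game, K),
      phi_stationarity = pair_phi_stationarity(s$p2, game, K),
      stable = pair_flow_stable(unclass(s$p2), game, K),
      converged = s$converged,
      residual = s$residual,
      p2 = list(unclass(s$p2))
    )
  }) |> dplyr::arrange(dplyr::desc(.data$phi_per_site))
}

pair_branch_exists <- function(game, K, branch, tol = 1e-9,
                               max_steps = 1.5e5) {
  s <- pair_converge(game, K, pair_seed(game, branch, eps = 0.01),
                     tol = tol, max_steps = max_steps)
  pair_branch_label(s$p2, game, tol = 3e-3) == branch_target_label(game, branch)
}

#' Pair-approximation endpoint of an ordered branch
#'
#' Largest `K` at which the ordered branch survives as a fixed point of the
#' pair-approximation flow, by bisection (the continuous order-disorder
#' transition of the pair-approximated model).
#'
#' @inheritParams mf_branch_endpoint
#' @return The endpoint `K`.
#' @export
pair_branch_endpoint <- function(game, branch = "ising", K_lo = 0.5,
                                 K_hi = 4, tol = 2e-3) {
  if (!pair_branch_exists(game, K_lo, branch)) {
    stop("branch does not exist at K_lo", call. = FALSE)
  }
  if (pair_branch_exists(game, K_hi, branch)) {
    stop("branch still exists at K_hi; widen the bracket", call. = FALSE)
  }
  while (K_hi - K_lo > tol) {
    K_mid <- (K_lo + K_hi) / 2
    if (pair_branch_exists(game, K_mid, branch)) K_lo <- K_mid else K_hi <- K_mid
  }
  (K_lo + K_hi) / 2
}

#' Pair-approximation first-order Potts-Ising transition
#'
#' `K` at which the `Phi(2)` values of the tracked Potts and Ising fixed
#' points cross, by bisection after a coarse scan.
#'
#' @inheritParams mf_potts_ising_crossing
#' @param game a composite [ising_potts_game()].
#' @return A one-row tibble `K_PI`, `found`.
#' @export
pair_potts_ising_crossing <- function(game, tol = 1e-3,
                                      K_grid = seq(0.2, 1.2, by = 0.1)) {
  phi_branch <- function(K, branch) {
    s <- pair_converge(game, K, pair_seed(game, branch, eps = 0.01),
                       tol = 1e-10)
    if (pair_branch_label(s$p2, game) != branch) return(NA_real_)
    pair_phi(s$p2, game, K)
  }
  d <- function(K) {
    a <- phi_branch(K, "potts"); b <- phi_branch(K, "ising")
    if (is.na(a) || is.na(b)) NA_real_ else a - b
  }
  vals <- vapply(K_grid, d, numeric(1))
  ok <- which(!is.na(vals))
  sgn <- sign(vals[ok])
  flip <- which(sgn[-1] != sgn[-length(sgn)])
  if (!length(flip)) return(tibble::tibble(K_PI = NA_real_, found = FALSE))
  lo <- K_grid[ok[flip[1]]]; hi <- K_grid[ok[flip[1] + 1]]
  f_lo <- vals[ok[flip[1]]]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- d(mid)
    if (is.na(f_mid)) { hi <- mid; next }
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  tibble::tibble(K_PI = (lo + hi) / 2, found = TRUE)
}
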