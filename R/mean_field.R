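#' Mean-field thermodynamic potential per site
#'
#' One-site cluster-variation estimate of the thermodynamic potential
#' `Phi = U + K S` for a translation-invariant state with strategy
#' frequencies `rho` on a lattice of coordination number `z = 4`:
#' `Phi / N = 2 rho' A rho + K * (-sum rho_i log rho_i)`.
#' The state with the *largest* `Phi` is the thermodynamically selected one.
#'
#' @param rho numeric frequency vector on the n-simplex.
#' @param game a [game_spec()] with symmetric `A`.
#' @param K noise level (> 0).
#' @return `Phi` per site (payoff units).
#' @examples
#' mf_phi(rep(0.2, 5), ising_potts_game(1), K = 1)  # K * log(5)
#' @export
mf_phi <- function(rho, game, K) {
  check_K(K)
  check_simplex(rho, game$n)
  2 * drop(rho %*% game$A %*% rho) + K * entropy(rho)
}

entropy <- function(rho) {
  nz <- rho > 0
  -sum(rho[nz] * log(rho[nz]))
}

check_simplex <- function(rho, n, tol = 1e-8) {
  if (length(rho) != n || any(rho < -tol) || abs(sum(rho) - 1) > tol) {
    stop("`rho` must be a length-", n, " probability vector", call. = FALSE)
  }
  invisible(rho)
}

softmax <- function(x) {
  w <- exp(x - max(x))
  w / sum(w)
}

# Damped iteration of the stationarity (self-consistency) map
# rho_i propto exp(z (A rho)_i / K), the Lagrange-conditioned form of
# dPhi/drho_i = 0. Preserves the simplex; attracting fixed points are
# exactly the locally stable mean-field states.
mf_fixed_point <- function(game, K, start, z = 4, damping = 0.5,
                           tol = 1e-12, max_iter = 2e5) {
  rho <- start / sum(start)
  A <- game$A
  for (it in seq_len(max_iter)) {
    g <- softmax(z * drop(A %*% rho) / K)
    res <- max(abs(g - rho))
    rho <- (1 - damping) * rho + damping * g
    if (res < tol) {
      return(list(rho = rho, converged = TRUE, residual = res, iterations = it))
    }
  }
  list(rho = rho, converged = FALSE, residual = res, iterations = max_iter)
}

# label a requested branch resolves to for this game (generic games have a
# single "ordered" family)
branch_target_label <- function(game, branch) {
  if (!is.null(game$alpha) && game$n == 5) branch else "ordered"
}

mf_branch_label <- function(rho, game, tol = 1e-3) {
  n <- length(rho)
  if (!is.null(game$alpha) && n == 5) {
    # disordered = symmetric within each strategy family (the pair-level
    # disordered state has rho_1 = rho_2 != rho_3 due to correlations)
    if (abs(rho[1] - rho[2]) < tol && max(rho[3:5]) - min(rho[3:5]) < tol) {
      return("disordered")
    }
    if (abs(rho[1] - rho[2]) > tol && which.max(rho) %in% 1:2) return("ising")
    if (which.max(rho) %in% 3:5 &&
        max(rho[3:5]) - min(rho[3:5]) > tol) return("potts")
    return("other")
  }
  if (max(abs(rho - 1 / n)) < tol) return("disordered")
  "ordered"
}

#' Stability of a mean-field stationary point
#'
#' A stationary point is stable when it is a local maximizer of `Phi` on the
#' simplex, i.e., when the Hessian `z A - K diag(1/rho)` is negative definite
#' on the tangent space of the simplex. Near-zero leading eigenvalues are
#' flagged `"marginal"`.
#'
#' @inheritParams mf_phi
#' @param z lattice coordination number.
#' @param tol eigenvalue tolerance for marginality.
#' @return `"stable"`, `"unstable"` or `"marginal"`.
#' @export
mf_stability <- function(rho, game, K, z = 4, tol = 1e-8) {
  n <- length(rho)
  rho <- pmax(rho, 1e-300)
  H <- z * game$A - K * diag(1 / rho)
  B <- qr.Q(qr(cbind(rep(1, n))), complete = TRUE)[, -1, drop = FALSE]
  ev <- eigen(t(B) %*% H %*% B, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev)
  if (abs(mx) < tol) "marginal" else if (mx < 0) "stable" else "unstable"
}

mf_default_starts <- function(n, eps = 1e-3) {
  starts <- lapply(seq_len(n), function(i) {
    v <- rep(eps, n); v[i] <- 1 - (n - 1) * eps; v
  })
  starts <- c(starts, list(rep(1 / n, n)))
  if (n == 5) {
    starts <- c(starts,
                list(c(0.45, 0.45, 0.1 / 3, 0.1 / 3, 0.1 / 3)),
                list(c(0.05, 0.05, 0.3, 0.3, 0.3)))
  }
  starts
}

#' Mean-field stationary points at one noise level
#'
#' Iterates the self-consistency map from a standard start set (each
#' near-pure vertex, the barycenter, and mixed starts), deduplicates the
#' converged fixed points, classifies each branch, and evaluates `Phi` and
#' stability.
#'
#' @inheritParams mf_phi
#' @param starts optional list of start vectors; defaults to the standard set.
#' @param z lattice coordination number.
#' @param tol convergence tolerance on the stationarity residual.
#' @return A tibble with columns `branch`, `rho_1..rho_n`, `phi_per_site`,
#'   `stable`, `stability`, `residual`, `converged`, sorted by decreasing
#'   `phi_per_site`.
#' @examples
#' mf_stationary(ising_potts_game(1), K = 1)
#' @export
mf_stationary <- function(game, K, starts = NULL, z = 4, tol = 1e-12) {
  if (!game$symmetric) stop("mean-field solver requires a potential game",
                            call. = FALSE)
  starts <- starts %||% mf_default_starts(game$n)
  sols <- purrr::map(starts, function(s0) mf_fixed_point(game, K, s0, z = z, tol = tol))
  keep <- list()
  for (s in sols) {
    dup <- any(vapply(keep, function(k) max(abs(k$rho - s$rho)) < 1e-6, logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- s
  }
  rows <- purrr::map_dfr(keep, function(s) {
    stab <- mf_stability(s$rho, game, K, z = z)
    tibble::tibble(
      branch = mf_branch_label(s$rho, game),
      !!!setNames(as.list(s$rho), paste0("rho_", seq_along(s$rho))),
      phi_per_site = mf_phi(s$rho, game, K),
      stable = identical(stab, "stable"),
      stability = stab,
      residual = s$residual,
      converged = s$converged
    )
  })
  dplyr::arrange(rows, dplyr::desc(.data$phi_per_site))
}

# Continuation of one branch over an increasing K grid. Seeds each K from the
# previous solution; reports rows until the branch collapses (label changes).
mf_branch_scan <- function(game, K_values, branch = c("ising", "potts"),
                           z = 4, tol = 1e-12) {
  branch <- match.arg(branch)
  n <- game$n
  seed <- rep(1e-3, n)
  seed[if (branch == "ising") 1 else 3] <- 1 - (n - 1) * 1e-3
  rho <- seed
  out <- list()
  for (K in sort(K_values)) {
    fp <- mf_fixed_point(game, K, rho, z = z, tol = tol)
    lab <- mf_branch_label(fp$rho, game)
    if (lab != branch) break
    rho <- fp$rho
    out[[length(out) + 1L]] <- tibble::tibble(
      K = K, branch = lab,
      !!!setNames(as.list(fp$rho), paste0("rho_", seq_len(n))),
      phi_per_site = mf_phi(fp$rho, game, K),
      stable = identical(mf_stability(fp$rho, game, K, z = z), "stable")
    )
  }
  dplyr::bind_rows(out)
}

#' All mean-field branches over a noise grid
#'
#' Convenience scan producing the branch table behind the mean-field phase
#' diagram: the ordered Ising and Potts branches (tracked by continuation
#' until they vanish) and the disordered branch at every `K`.
#'
#' @inheritParams mf_stationary
#' @param K_values increasing numeric vector of noise levels.
#' @return Tibble with columns `K`, `branch`, `rho_1..rho_n`, `phi_per_site`,
#'   `stable`.
#' @export
mf_branches <- function(game, K_values, z = 4) {
  n <- game$n
  dis <- purrr::map_dfr(K_values, function(K) {
    fp <- mf_fixed_point(game, K, rep(1 / n, n), z = z)
    tibble::tibble(
      K = K, branch = "disordered",
      !!!setNames(as.list(fp$rho), paste0("rho_", seq_len(n))),
      phi_per_site = mf_phi(fp$rho, game, K),
      stable = identical(mf_stability(fp$rho, game, K, z = z), "stable")
    )
  })
  dplyr::bind_rows(
    mf_branch_scan(game, K_values, "ising", z = z),
    if (!is.null(game$alpha) && game$alpha > 0)
      mf_branch_scan(game, K_values, "potts", z = z),
    dis
  ) |> dplyr::arrange(.data$K, .data$branch)
}

# Does the ordered `branch` exist at K? Continuation-style: converge from a
# strongly ordered seed with damping; existence = the fixed point keeps the
# branch's label.
mf_branch_exists <- function(game, K, branch, z = 4) {
  n <- game$n
  seed <- rep(1e-3, n)
  seed[if (branch == "ising") 1 else 3] <- 1 - (n - 1) * 1e-3
  fp <- mf_fixed_point(game, K, seed, z = z, tol = 1e-13)
  mf_branch_label(fp$rho, game) == branch_target_label(game, branch)
}

#' Mean-field endpoint of an ordered branch
#'
#' Largest noise level at which the ordered branch still exists as a
#' stationary point, located by bisection on branch existence under the
#' self-consistency map. For the composite game the Ising branch endpoint is
#' the mean-field order-disorder critical noise.
#'
#' @param game a [game_spec()].
#' @param branch `"ising"` or `"potts"`.
#' @param K_lo,K_hi initial bracket (branch must exist at `K_lo`, not at
#'   `K_hi`).
#' @param tol bisection tolerance on `K`.
#' @param z coordination number.
#' @return The endpoint `K` (payoff units).
#' @examples
#' \donttest{
#' mf_branch_endpoint(ising_potts_game(1), "ising")  # 8/5
#' }
#' @export
mf_branch_endpoint <- function(game, branch = "ising", K_lo = 0.5, K_hi = 4,
                               tol = 1e-4, z = 4) {
  if (!mf_branch_exists(game, K_lo, branch, z)) {
    stop("branch does not exist at K_lo", call. = FALSE)
  }
  if (mf_branch_exists(game, K_hi, branch, z)) {
    stop("branch still exists at K_hi; widen the bracket", call. = FALSE)
  }
  while (K_hi - K_lo > tol) {
    K_mid <- (K_lo + K_hi) / 2
    if (mf_branch_exists(game, K_mid, branch, z)) K_lo <- K_mid else K_hi <- K_mid
  }
  (K_lo + K_hi) / 2
}

mf_branch_phi <- function(game, K, branch, z = 4) {
  n <- game$n
  seed <- rep(1e-3, n)
  seed[if (branch == "ising") 1 else 3] <- 1 - (n - 1) * 1e-3
  fp <- mf_fixed_point(game, K, seed, z = z, tol = 1e-13)
  if (mf_branch_label(fp$rho, game) != branch_target_label(game, branch)) return(NA_real_)
  mf_phi(fp$rho, game, K)
}

#' Mean-field first-order Potts-Ising transition
#'
#' Locates the noise level at which the thermodynamic potentials of the
#' tracked Potts and Ising branches cross (`Phi_Potts = Phi_Ising`), the
#' mean-field first-order transition between the two ordered phases. Both
#' branches are continued past the crossing as metastable states, which is
#' what makes the crossing observable.
#'
#' @param alpha Potts strength of the composite game (> 1 for a crossing).
#' @param tol bisection tolerance on `K`.
#' @param K_grid coarse grid scanned for a sign change before bisection.
#' @param z coordination number.
#' @return A one-row tibble `alpha`, `K_PI`, `found`; `K_PI = NA` when the
#'   branches never cross while both exist.
#' @export
mf_potts_ising_crossing <- function(alpha, tol = 1e-4,
                                    K_grid = c(seq(0.05, 1.45, by = 0.05),
                                               seq(1.455, 1.62, by = 0.005)),
                                    z = 4) {
  game <- ising_potts_game(alpha)
  d <- function(K) {
    pi_ <- mf_branch_phi(game, K, "potts", z)
    is_ <- mf_branch_phi(game, K, "ising", z)
    if (is.na(pi_) || is.na(is_)) NA_real_ else pi_ - is_
  }
  vals <- vapply(K_grid, d, numeric(1))
  # Phi differences below the solver resolution cannot carry a sign
  # (at alpha = 1 the gap decays like exp(-c/K) at low K): treat as ties.
  vals[abs(vals) < 1e-10] <- NA_real_
  ok <- which(!is.na(vals))
  if (length(ok) < 2) {
    return(tibble::tibble(alpha = alpha, K_PI = NA_real_, found = FALSE))
  }
  sgn <- sign(vals[ok])
  flip <- which(sgn[-1] != sgn[-length(sgn)])
  if (!length(flip)) {
    return(tibble::tibble(alpha = alpha, K_PI = NA_real_, found = FALSE))
  }
  lo <- K_grid[ok[flip[1]]]; hi <- K_grid[ok[flip[1] + 1]]
  f_lo <- vals[ok[flip[1]]]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- d(mid)
    if (is.na(f_mid)) { hi <- mid; next }
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  tibble::tibble(alpha = alpha, K_PI = (lo + hi) / 2, found = TRUE)
}

#' Mean-field endpoint of the Ising phase in alpha
#'
#' The critical Potts strength at which the first-order Potts-Ising noise
#' level `K_PI(alpha)` reaches the Ising branch endpoint `K_I(alpha)` and the
#' stable Ising phase disappears from the mean-field phase diagram. The
#' `Phi` gap between the Potts and Ising branches decreases monotonically in
#' `K` up to the Ising endpoint, where the Ising branch merges into the
#' disordered state; the crossing therefore reaches `K_I` exactly when
#' `Phi_Potts(K_I)` meets the disordered `Phi(K_I) = K_I log n`. Bisection on
#' the sign of that endpoint gap locates `alpha_c`.
#'
#' @param alpha_lo,alpha_hi bracket (Ising window must exist at `alpha_lo`
#'   and be gone at `alpha_hi`).
#' @param tol bisection tolerance on `alpha`.
#' @return The critical `alpha`.
#' @export
mf_alpha_c <- function(alpha_lo = 1.05, alpha_hi = 1.25, tol = 5e-4) {
  endpoint_gap <- function(alpha) {
    game <- ising_potts_game(alpha)
    K_I <- mf_branch_endpoint(game, "ising", tol = 1e-5)
    phi_p <- mf_branch_phi(game, K_I, "potts")
    # Potts branch already gone at the Ising endpoint: the Ising window
    # certainly survives there.
    if (is.na(phi_p)) return(-Inf)
    phi_p - K_I * log(game$n)
  }
  g_lo <- endpoint_gap(alpha_lo); g_hi <- endpoint_gap(alpha_hi)
  if (g_lo >= 0) stop("Ising phase already gone at alpha_lo", call. = FALSE)
  if (g_hi < 0) stop("Ising phase still present at alpha_hi", call. = FALSE)
  while (alpha_hi - alpha_lo > tol) {
    mid <- (alpha_lo + alpha_hi) / 2
    if (endpoint_gap(mid) >= 0) alpha_hi <- mid else alpha_lo <- mid
  }
  (alpha_lo + alpha_hi) / 2
}
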