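#' Define a matrix game for lattice play
#'
#' A `game_spec` bundles the strategy count `n`, the payoff matrix `A`
#' (row player's income against the column player's strategy) and, when `A`
#' is symmetric, the potential matrix `V = A`. Symmetry of `A` is exactly the
#' potential-game condition under which logit dynamics relax to the Boltzmann
#' distribution over the configuration potential; asymmetric games can still
#' be simulated, but every thermodynamic solver (mean-field, pair
#' approximation, exact enumeration) refuses them.
#'
#' @param A numeric `n x n` payoff matrix.
#' @param labels optional character vector of strategy names (length `n`).
#'
#' @return An object of class `game_spec` with fields `n`, `A`, `V`
#'   (`NULL` for asymmetric `A`), `labels` and `symmetric`.
#' @examples
#' g <- game_spec(matrix(c(1, -1, -1, 1), 2, 2))
#' g$symmetric
#' @export
game_spec <- function(A, labels = NULL) {
  A <- as.matrix(A)
  if (!is.numeric(A) || nrow(A) != ncol(A)) {
    stop("`A` must be a square numeric matrix", call. = FALSE)
  }
  n <- nrow(A)
  if (n < 2) stop("a game needs at least 2 strategies", call. = FALSE)
  if (!is.null(labels) && length(labels) != n) {
    stop("`labels` must have length n = ", n, call. = FALSE)
  }
  sym <- isTRUE(all.equal(A, t(A), tolerance = 1e-12))
  structure(
    list(
      n = n,
      A = unname(A),
      V = if (sym) unname(A) else NULL,
      labels = labels %||% as.character(seq_len(n)),
      symmetric = sym
    ),
    class = "game_spec"
  )
}

#' @export
print.game_spec <- function(x, ...) {
  cat(sprintf(
    "<game_spec> n = %d strategies, %s\n", x$n,
    if (x$symmetric) "symmetric (potential game, V = A)" else
      "asymmetric (no potential)"
  ))
  A <- x$A
  dimnames(A) <- list(x$labels, x$labels)
  print(round(A, 6))
  invisible(x)
}

#' Composite Ising + Potts coordination game
#'
#' Builds the five-strategy game whose first two strategies form an Ising
#' coordination pair of unit strength and whose last three strategies form a
#' three-state Potts triple of relative strength `alpha`: the payoff matrix is
#' block-diagonal with blocks `[[1, -1], [-1, 1]]` and
#' `alpha * [[1, -1/2, -1/2], [-1/2, 1, -1/2], [-1/2, -1/2, 1]]`,
#' and zero payoff between the two strategy families. Every row and column
#' sums to zero (pure coordination type), so the Potts block is the standard
#' diagonal Potts matrix shifted by an irrelevant constant. The matrix is
#' symmetric, hence the game is a potential game with `V = A`.
#'
#' @param alpha nonnegative relative strength of the Potts subgame
#'   (payoff units; the Ising coordination payoff is the unit of currency).
#'
#' @return A [game_spec()] with `n = 5`.
#' @examples
#' ising_potts_game(1)
#' @export
ising_potts_game <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha < 0) {
    stop("`alpha` must be a single nonnegative number", call. = FALSE)
  }
  A <- matrix(0, 5, 5)
  A[1:2, 1:2] <- matrix(c(1, -1, -1, 1), 2, 2)
  A[3:5, 3:5] <- alpha * (1.5 * diag(3) - 0.5)
  g <- game_spec(A, labels = c("I1", "I2", "P3", "P4", "P5"))
  g$alpha <- alpha
  g
}

#' Elementary n-strategy coordination game
#'
#' Two coordinated strategies (the Ising pair, payoffs `[[1, -1], [-1, 1]]`)
#' plus `n - 2` neutral strategies that provide zero payoff regardless of the
#' opponent's strategy.
#'
#' @param n total strategy count (>= 2).
#' @return A [game_spec()].
#' @examples
#' coordination_game(4)
#' @export
coordination_game <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 2) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  A <- matrix(0, n, n)
  A[1:2, 1:2] <- matrix(c(1, -1, -1, 1), 2, 2)
  game_spec(A)
}

#' q-state Potts coordination game
#'
#' The zero-row-sum Potts coordination matrix: diagonal `alpha`, off-diagonal
#' `-alpha / (q - 1)`. For `q = 3` this is the Potts block of
#' [ising_potts_game()]. Relative to the standard diagonal Potts matrix the
#' entries are shifted by a constant, which leaves logit dynamics unchanged;
#' the effective Potts coupling is `alpha * q / (q - 1)`.
#'
#' @param alpha coordination strength (> 0).
#' @param q number of Potts states (>= 2).
#' @return A [game_spec()].
#' @export
potts_game <- function(alpha = 1, q = 3) {
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  if (q < 2 || q != round(q)) stop("`q` must be an integer >= 2", call. = FALSE)
  game_spec(alpha * (q / (q - 1) * diag(q) - 1 / (q - 1)))
}

#' Income of one player from its four nearest neighbors
#'
#' The player at `site` plays the game against each of its four nearest
#' neighbors (periodic boundaries) and collects
#' `sum_delta A[s_x, s_(x+delta)]`.
#'
#' @param state a [lattice_state()] (or a plain integer matrix of strategy
#'   labels in `1..n`).
#' @param site integer vector `c(row, col)`, 1-based.
#' @param game a [game_spec()].
#' @return Scalar payoff.
#' @export
player_payoff <- function(state, site, game) {
  s <- lattice_sites(state)
  L <- nrow(s)
  r <- site[1]; c <- site[2]
  if (r < 1 || r > L || c < 1 || c > L) stop("site out of range", call. = FALSE)
  nb <- neighbor_strategies(s, r, c)
  sum(game$A[s[r, c], nb])
}

neighbor_strategies <- function(s, r, c) {
  L <- nrow(s)
  c(
    s[if (r == 1) L else r - 1, c],
    s[if (r == L) 1 else r + 1, c],
    s[r, if (c == 1) L else c - 1],
    s[r, if (c == L) 1 else c + 1]
  )
}

#' Configuration potential of a lattice state
#'
#' Sum of the pair potential `V[s_x, s_y]` over the `2 N` undirected
#' nearest-neighbor edges of the periodic `L x L` lattice (half of the
#' directed-pair double sum). Defined only for potential games
#' (symmetric payoff matrix).
#'
#' @inheritParams player_payoff
#' @return Scalar total potential (payoff units).
#' @export
total_potential <- function(state, game) {
  if (!game$symmetric) {
    stop("total_potential requires a symmetric (potential) game", call. = FALSE)
  }
  cpp_total_potential(lattice_sites(state), game$V)
}

#' Per-player average payoff and potential of a configuration
#'
#' For any configuration of a potential game (symmetric `A`) every edge
#' contributes its pair payoff to the income of both endpoints but only once
#' to the potential, so the average payoff per player is exactly twice the
#' average potential per player.
#'
#' @inheritParams player_payoff
#' @return A one-row tibble with columns `payoff_per_player` and
#'   `potential_per_player`.
#' @export
payoff_potential <- function(state, game) {
  s <- lattice_sites(state)
  N <- length(s)
  U <- total_potential(state, game)
  tibble::tibble(payoff_per_player = 2 * U / N, potential_per_player = U / N)
}

#' Serialize a game to JSON (and back)
#'
#' The JSON carries `n`, the payoff matrix row by row, the labels, and the
#' `alpha` tag for composite Ising+Potts games.
#'
#' @param game a [game_spec()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `game_to_json()`: the JSON string (invisibly, when written to
#'   `path`); `game_from_json()`: a [game_spec()].
#' @export
game_to_json <- function(game, path = NULL) {
  x <- list(n = game$n, A = game$A, labels = game$labels)
  if (!is.null(game$alpha)) x$alpha <- game$alpha
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @param x a JSON string or path to a JSON file.
#' @rdname game_to_json
#' @export
game_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  if (is.null(obj$A)) {
    if (is.null(obj$alpha)) stop("JSON must carry `A` or `alpha`", call. = FALSE)
    return(ising_potts_game(obj$alpha))
  }
  g <- game_spec(matrix(unlist(obj$A), obj$n, obj$n, byrow = FALSE),
                 labels = obj$labels)
  if (!is.null(obj$alpha)) g$alpha <- obj$alpha
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
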