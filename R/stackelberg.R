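#' Leader-follower resource-allocation game
#'
#' Defines a single-leader, N-follower Stackelberg game. The leader commits a
#' bounded scalar strategy `x` (read as a bandwidth/compute share); each
#' follower `i` best-responds with `y_i` in its own box. The default
#' parametric family is chosen so equilibria have closed forms:
#' \describe{
#'   \item{follower utility}{`U_F = p_i x y - q_i y^2 / 2 - r_i y`
#'     (strictly concave in `y` when `q_i > 0`)}
#'   \item{leader utility}{`U_L = sum_i lambda1 * A_i(y_i) - lambda2 *
#'     C_i(x, y_i)` with saturating accuracy `A_i(y) = a_i (1 - exp(-k_i y))`
#'     and linear cost `C_i(x, y) = e_i y + g_i x`}
#' }
#' Any field can be replaced by a custom callable through
#' `follower_utility_fn` / `accuracy_fn` / `cost_fn` (signatures
#' `f(x, y, pars_i)`).
#'
#' @param leader_bounds Length-2 numeric, the leader's strategy interval.
#' @param follower_bounds Either a length-2 numeric (shared by all followers)
#'   or an `N x 2` matrix of per-follower intervals.
#' @param lambda1,lambda2 Nonnegative leader weights (performance vs. cost).
#' @param p,q,r Per-follower utility parameters (recycled to length `N`);
#'   `q > 0` required.
#' @param a,k Accuracy parameters `A_i(y) = a (1 - exp(-k y))`.
#' @param e,g Cost parameters `C_i(x, y) = e y + g x`.
#' @param n_followers `N`.
#' @param follower_utility_fn,accuracy_fn,cost_fn Optional callables
#'   overriding the default family.
#' @param response_noise Half-width of an optional uniform perturbation of the
#'   follower best responses (bounded-rationality model; default 0 = exact).
#' @return A list of class `game_spec`.
#' @export
game_spec <- function(leader_bounds = c(0, 1), n_followers = 3L,
                      follower_bounds = c(0, 5),
                      lambda1 = 1, lambda2 = 0.5,
                      p = 1, q = 1, r = 0,
                      a = 1, k = 1, e = 0.1, g = 0.05,
                      follower_utility_fn = NULL, accuracy_fn = NULL,
                      cost_fn = NULL, response_noise = 0) {
  N <- as.integer(n_followers)
  stopifnot(N >= 1L, length(leader_bounds) == 2L,
            lambda1 >= 0, lambda2 >= 0, response_noise >= 0)
  if (is.null(dim(follower_bounds))) {
    follower_bounds <- matrix(rep(follower_bounds, each = N), N, 2L)
  }
  stopifnot(nrow(follower_bounds) == N, ncol(follower_bounds) == 2L)
  rec <- function(v) rep_len(v, N)
  structure(list(
    leader_bounds = as.numeric(leader_bounds), n_followers = N,
    follower_bounds = follower_bounds,
    lambda1 = lambda1, lambda2 = lambda2,
    p = rec(p), q = rec(q), r = rec(r),
    a = rec(a), k = rec(k), e = rec(e), g = rec(g),
    follower_utility_fn = follower_utility_fn,
    accuracy_fn = accuracy_fn, cost_fn = cost_fn,
    response_noise = response_noise
  ), class = "game_spec")
}

#' Follower utility
#'
#' @param game A [game_spec()].
#' @param x Leader strategy.
#' @param y_i Follower strategy.
#' @param i Follower index (1-based).
#' @return Utility value.
#' @export
follower_utility <- function(game, x, y_i, i) {
  if (i < 1L || i > game$n_followers) stop("follower index out of range")
  if (!is.null(game$follower_utility_fn)) {
    return(game$follower_utility_fn(x, y_i,
                                    list(p = game$p[i], q = game$q[i],
                                         r = game$r[i])))
  }
  game$p[i] * x * y_i - game$q[i] * y_i^2 / 2 - game$r[i] * y_i
}

accuracy_term <- function(game, y, i) {
  if (!is.null(game$accuracy_fn)) {
    return(game$accuracy_fn(NA_real_, y, list(a = game$a[i], k = game$k[i])))
  }
  game$a[i] * (1 - exp(-game$k[i] * y))
}

cost_term <- function(game, x, y, i) {
  if (!is.null(game$cost_fn)) {
    return(game$cost_fn(x, y, list(e = game$e[i], g = game$g[i])))
  }
  game$e[i] * y + game$g[i] * x
}

#' Leader utility
#'
#' `U_L(x, y) = sum_i [lambda1 A_i(y_i) - lambda2 C_i(x, y_i)]`.
#'
#' @param game A [game_spec()].
#' @param x Leader strategy.
#' @param y Numeric vector of all follower strategies (length `N`).
#' @return Utility value.
#' @export
leader_utility <- function(game, x, y) {
  if (length(y) != game$n_followers) {
    stop("y must have one entry per follower")
  }
  sum(vapply(seq_len(game$n_followers), function(i) {
    game$lambda1 * accuracy_term(game, y[i], i) -
      game$lambda2 * cost_term(game, x, y[i], i)
  }, numeric(1)))
}

#' Follower best response
#'
#' For the default family the argmax is the clipped stationary point
#' `y* = clip((p_i x - r_i) / q_i, bounds)`; a custom concave utility is
#' maximized numerically over the follower's interval.
#'
#' @inheritParams follower_utility
#' @param tol Numerical tolerance for the generic maximizer.
#' @return The maximizing `y_i`.
#' @export
follower_best_response <- function(game, x, i, tol = 1e-8) {
  lo <- game$follower_bounds[i, 1L]; hi <- game$follower_bounds[i, 2L]
  if (is.null(game$follower_utility_fn)) {
    if (game$q[i] <= 0) stop("follower utility not strictly concave (q <= 0)")
    y <- (game$p[i] * x - game$r[i]) / game$q[i]
    return(min(max(y, lo), hi))
  }
  probe_concavity(function(y) follower_utility(game, x, y, i), lo, hi)
  opt <- stats::optimize(function(y) follower_utility(game, x, y, i),
                         c(lo, hi), maximum = TRUE, tol = tol)
  cands <- c(opt$maximum, lo, hi)
  cands[which.max(vapply(cands,
                         function(y) follower_utility(game, x, y, i),
                         numeric(1)))]
}

probe_concavity <- function(f, lo, hi, n = 41L, tol = 1e-8) {
  ys <- seq(lo, hi, length.out = n)
  v <- vapply(ys, f, numeric(1))
  d2 <- diff(v, differences = 2L)
  if (any(d2 > tol * max(1, max(abs(v))))) {
    stop("follower utility failed the concavity probe")
  }
  invisible(TRUE)
}

all_best_responses <- function(game, x, tol = 1e-8) {
  vapply(seq_len(game$n_followers),
         function(i) follower_best_response(game, x, i, tol), numeric(1))
}

# reduced leader objective: followers at exact best response
reduced_objective <- function(game, x, tol = 1e-8) {
  leader_utility(game, x, all_best_responses(game, x, tol))
}

# d U_L / dx for the default family on a region of fixed clipping pattern
reduced_derivative <- function(game, x) {
  d <- -game$lambda2 * sum(game$g)
  for (i in seq_len(game$n_followers)) {
    y <- (game$p[i] * x - game$r[i]) / game$q[i]
    lo <- game$follower_bounds[i, 1L]; hi <- game$follower_bounds[i, 2L]
    if (y > lo && y < hi) {
      dy <- game$p[i] / game$q[i]
      d <- d + game$lambda1 * game$a[i] * game$k[i] * exp(-game$k[i] * y) * dy -
        game$lambda2 * game$e[i] * dy
    }
  }
  d
}

#' Solve the Stackelberg game
#'
#' Bilevel solution: for each candidate leader strategy the followers'
#' *exact* best responses are recomputed, and the leader maximizes the
#' resulting reduced objective. Three solvers are available:
#' \describe{
#'   \item{`closed_form`}{default family only; splits the leader interval at
#'     the best-response clipping breakpoints and solves the first-order
#'     condition by root bracketing on each piece (the reduced derivative is
#'     strictly decreasing there), then compares piece optima and endpoints.}
#'   \item{`grid`}{dense grid plus golden-section refinement.}
#'   \item{`npo`}{the package's nomadic swarm optimizer on the reduced
#'     objective.}
#' }
#'
#' @param game A [game_spec()].
#' @param solver `"closed_form"`, `"grid"` or `"npo"`.
#' @param tol Solver tolerance on `x*`.
#' @param swarm_cfg Optional [swarm_config()] for the `"npo"` solver.
#' @return A list of class `equilibrium`: `x_star`, `y_star`,
#'   `leader_utility`, `follower_utilities`, `solver`, `residual` (max
#'   follower best-response utility gap).
#' @export
solve_stackelberg <- function(game, solver = c("closed_form", "grid", "npo"),
                              tol = 1e-6, swarm_cfg = NULL) {
  solver <- match.arg(solver)
  v <- validate_game(game)
  if (!v$ok) stop("invalid game: ", paste(v$violations, collapse = "; "))
  lo <- game$leader_bounds[1L]; hi <- game$leader_bounds[2L]
  if (solver == "closed_form") {
    if (!is.null(game$follower_utility_fn) || !is.null(game$accuracy_fn) ||
        !is.null(game$cost_fn)) {
      stop("closed_form solver requires the default utility family")
    }
    # breakpoints where some follower's unclipped response crosses its bounds
    bps <- unlist(lapply(seq_len(game$n_followers), function(i) {
      c((game$q[i] * game$follower_bounds[i, 1L] + game$r[i]) / game$p[i],
        (game$q[i] * game$follower_bounds[i, 2L] + game$r[i]) / game$p[i])
    }))
    knots <- sort(unique(c(lo, hi, bps[is.finite(bps) & bps > lo & bps < hi])))
    cands <- knots
    for (j in seq_len(length(knots) - 1L)) {
      a <- knots[j]; b <- knots[j + 1L]
      da <- reduced_derivative(game, a + 1e-12 * (b - a))
      db <- reduced_derivative(game, b - 1e-12 * (b - a))
      if (da > 0 && db < 0) {
        root <- stats::uniroot(function(x) reduced_derivative(game, x),
                               c(a, b), tol = min(tol, 1e-10))$root
        cands <- c(cands, root)
      }
    }
    vals <- vapply(cands, function(x) reduced_objective(game, x), numeric(1))
    x_star <- cands[which.max(vals)]
  } else if (solver == "grid") {
    xs <- seq(lo, hi, length.out = 2001L)
    vals <- vapply(xs, function(x) reduced_objective(game, x), numeric(1))
    j <- which.max(vals)
    bracket <- c(xs[max(1L, j - 1L)], xs[min(length(xs), j + 1L)])
    if (bracket[1L] < bracket[2L]) {
      opt <- stats::optimize(function(x) reduced_objective(game, x),
                             bracket, maximum = TRUE, tol = tol)
      x_star <- if (opt$objective >= vals[j]) opt$maximum else xs[j]
    } else {
      x_star <- xs[j]
    }
  } else {
    cfg <- swarm_cfg
    if (is.null(cfg)) {
      cfg <- swarm_config(swarm_size = 20L, dims = 1L,
                          bounds = matrix(c(lo, hi), 1L, 2L),
                          max_iters = 120L, seed = 1L)
    }
    res <- npo_optimize(function(x) reduced_objective(game, x[1L]), cfg)
    x_star <- res$best_point[1L]
  }
  y_star <- all_best_responses(game, x_star)
  if (game$response_noise > 0) {
    y_star <- pmin(pmax(y_star + stats::runif(length(y_star),
                                              -game$response_noise,
                                              game$response_noise),
                        game$follower_bounds[, 1L]), game$follower_bounds[, 2L])
  }
  fu <- vapply(seq_len(game$n_followers),
               function(i) follower_utility(game, x_star, y_star[i], i),
               numeric(1))
  br <- all_best_responses(game, x_star)
  residual <- max(vapply(seq_len(game$n_followers), function(i) {
    follower_utility(game, x_star, br[i], i) - fu[i]
  }, numeric(1)))
  structure(list(x_star = x_star, y_star = y_star,
                 leader_utility = leader_utility(game, x_star, y_star),
                 follower_utilities = fu, solver = solver,
                 residual = residual),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium> solver=%s  x*=%.6g  U_L=%.6g  residual=%.2e\n",
              x$solver, x$x_star, x$leader_utility, x$residual))
  cat("  y* =", paste(sprintf("%.6g", x$y_star), collapse = ", "), "\n")
  invisible(x)
}

#' Validate a game specification
#'
#' Checks bound non-emptiness and finiteness, weight signs, strict concavity
#' of the follower utilities (analytic `q_i > 0` for the default family, a
#' second-difference probe for custom callables).
#'
#' @param game A [game_spec()].
#' @return A list: `ok` and `violations` (character vector).
#' @export
validate_game <- function(game) {
  v <- character(0)
  if (!all(is.finite(game$leader_bounds)) ||
      game$leader_bounds[1L] > game$leader_bounds[2L]) {
    v <- c(v, "leader strategy set empty or unbounded")
  }
  bad <- !is.finite(game$follower_bounds[, 1L]) |
    !is.finite(game$follower_bounds[, 2L]) |
    game$follower_bounds[, 1L] > game$follower_bounds[, 2L]
  if (any(bad)) {
    v <- c(v, paste0("follower strategy set empty or unbounded: ",
                     paste(which(bad), collapse = ",")))
  }
  if (game$lambda1 < 0 || game$lambda2 < 0) v <- c(v, "negative lambda weight")
  if (is.null(game$follower_utility_fn)) {
    if (any(game$q <= 0)) {
      v <- c(v, paste0("follower utility not strictly concave (q <= 0): ",
                       paste(which(game$q <= 0), collapse = ",")))
    }
  } else if (!any(bad)) {
    x_mid <- mean(game$leader_bounds)
    for (i in seq_len(game$n_followers)) {
      ok <- tryCatch({
        probe_concavity(function(y) follower_utility(game, x_mid, y, i),
                        game$follower_bounds[i, 1L],
                        game$follower_bounds[i, 2L])
        TRUE
      }, error = function(e) FALSE)
      if (!ok) v <- c(v, paste0("concavity probe failed for follower ", i))
    }
  }
  list(ok = length(v) == 0L, violations = v)
}
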