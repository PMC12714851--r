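#' Swarm optimizer configuration
#'
#' Position-velocity swarm with inertia weight `w` and acceleration
#' coefficients `c1` (personal best) and `c2` (global best); maximization
#' convention throughout. The optional nomadic extension partitions the swarm
#' into clans and periodically re-scatters the worst clan around the global
#' best (migration).
#'
#' @param swarm_size Number of particles (>= 2).
#' @param dims Problem dimensionality.
#' @param bounds `dims x 2` matrix of finite per-dimension bounds (a length-2
#'   vector is recycled).
#' @param w Inertia weight.
#' @param c1,c2 Acceleration coefficients.
#' @param max_iters Iteration budget.
#' @param seed RNG seed.
#' @param migration_every Iterations between clan migrations (0 disables the
#'   nomadic extension).
#' @param n_clans Number of clans when migration is enabled.
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(swarm_size = 30L, dims = 1L, bounds = c(-5, 5),
                         w = 0.729, c1 = 1.494, c2 = 1.494,
                         max_iters = 300L, seed = 1L,
                         migration_every = 0L, n_clans = 3L) {
  if (is.null(dim(bounds))) {
    bounds <- matrix(rep(bounds, each = dims), dims, 2L)
  }
  stopifnot(swarm_size >= 2L, nrow(bounds) == dims, ncol(bounds) == 2L,
            all(is.finite(bounds)), all(bounds[, 1L] <= bounds[, 2L]),
            w >= 0, c1 >= 0, c2 >= 0)
  structure(list(swarm_size = as.integer(swarm_size), dims = as.integer(dims),
                 bounds = bounds, w = w, c1 = c1, c2 = c2,
                 max_iters = as.integer(max_iters), seed = as.integer(seed),
                 migration_every = as.integer(migration_every),
                 n_clans = as.integer(n_clans)),
            class = "swarm_config")
}

#' Initialize a swarm
#'
#' Positions are drawn uniformly within bounds from the seeded stream,
#' velocities start at zero, and personal bests coincide with the initial
#' positions.
#'
#' @param cfg A [swarm_config()].
#' @param fitness Function mapping a `dims`-vector to a finite scalar
#'   (maximized).
#' @return A `swarm_state` list.
#' @export
init_swarm <- function(cfg, fitness) {
  set.seed(cfg$seed)
  n <- cfg$swarm_size; d <- cfg$dims
  pos <- sapply(seq_len(d), function(j) {
    stats::runif(n, cfg$bounds[j, 1L], cfg$bounds[j, 2L])
  })
  pos <- matrix(pos, n, d)
  fit <- apply(pos, 1L, fitness)
  if (any(!is.finite(fit))) {
    bad <- which(!is.finite(fit))[1L]
    stop("non-finite fitness at initial point: ",
         paste(signif(pos[bad, ], 6), collapse = ", "))
  }
  gb <- which.max(fit)
  structure(list(positions = pos, velocities = matrix(0, n, d),
                 pbest = pos, pbest_fit = fit,
                 gbest = pos[gb, ], gbest_fit = fit[gb],
                 iteration = 0L, frozen = rep(FALSE, n)),
            class = "swarm_state")
}

#' Advance the swarm one iteration
#'
#' Velocity and position updates:
#' \deqn{V_i \leftarrow w V_i + c_1 r_1 (pbest_i - x_i) + c_2 r_2 (gbest - x_i)}
#' \deqn{x_i \leftarrow x_i + V_i}
#' with fresh uniform `r1`, `r2` per particle per dimension, velocity clamped
#' to half the bound width, positions clamped to bounds, and personal/global
#' bests updated on improvement.
#'
#' @param state A `swarm_state`.
#' @param cfg A [swarm_config()].
#' @param fitness Fitness function (maximized).
#' @return The updated `swarm_state`.
#' @export
swarm_step <- function(state, cfg, fitness) {
  n <- cfg$swarm_size; d <- cfg$dims
  r1 <- matrix(stats::runif(n * d), n, d)
  r2 <- matrix(stats::runif(n * d), n, d)
  gb <- matrix(state$gbest, n, d, byrow = TRUE)
  V <- cfg$w * state$velocities +
    cfg$c1 * r1 * (state$pbest - state$positions) +
    cfg$c2 * r2 * (gb - state$positions)
  vmax <- (cfg$bounds[, 2L] - cfg$bounds[, 1L]) / 2
  V <- pmin(pmax(V, matrix(-vmax, n, d, byrow = TRUE)),
            matrix(vmax, n, d, byrow = TRUE))
  X <- state$positions + V
  X <- pmin(pmax(X, matrix(cfg$bounds[, 1L], n, d, byrow = TRUE)),
            matrix(cfg$bounds[, 2L], n, d, byrow = TRUE))
  fit <- apply(X, 1L, fitness)
  nf <- !is.finite(fit)
  if (any(nf)) {
    warning(sum(nf), " particle(s) hit non-finite fitness; frozen")
    X[nf, ] <- state$positions[nf, , drop = FALSE]
    V[nf, ] <- 0
    fit[nf] <- -Inf
    state$frozen <- state$frozen | nf
  }
  state$positions <- X
  state$velocities <- V
  imp <- fit > state$pbest_fit
  state$pbest[imp, ] <- X[imp, , drop = FALSE]
  state$pbest_fit[imp] <- fit[imp]
  b <- which.max(state$pbest_fit)
  if (state$pbest_fit[b] > state$gbest_fit) {
    state$gbest <- state$pbest[b, ]
    state$gbest_fit <- state$pbest_fit[b]
  }
  state$iteration <- state$iteration + 1L
  state
}

#' Run the optimizer
#'
#' Runs `max_iters` steps from a seeded initialization. When
#' `migration_every > 0` the swarm is split into `n_clans` contiguous clans
#' and, every `migration_every` iterations, the worst clan (by its best
#' member) is re-scattered uniformly in a box around the global best spanning
#' 10% of each bound width (the nomadic migration rule); the global best
#' itself is never discarded, so the reported trace is monotone.
#'
#' @param fitness Fitness function (maximized).
#' @param cfg A [swarm_config()].
#' @return A list: `best_point`, `best_fitness`, `trace` (gbest fitness per
#'   iteration), `state`.
#' @export
npo_optimize <- function(fitness, cfg = swarm_config()) {
  state <- init_swarm(cfg, fitness)
  trace <- numeric(cfg$max_iters)
  clans <- if (cfg$migration_every > 0L) {
    split(seq_len(cfg$swarm_size),
          cut(seq_len(cfg$swarm_size), cfg$n_clans, labels = FALSE))
  } else NULL
  for (it in seq_len(cfg$max_iters)) {
    state <- swarm_step(state, cfg, fitness)
    if (!is.null(clans) && it %% cfg$migration_every == 0L) {
      state <- migrate_worst_clan(state, cfg, fitness, clans)
    }
    trace[it] <- state$gbest_fit
  }
  list(best_point = state$gbest, best_fitness = state$gbest_fit,
       trace = trace, state = state)
}

migrate_worst_clan <- function(state, cfg, fitness, clans) {
  clan_best <- vapply(clans, function(i) max(state$pbest_fit[i]), numeric(1))
  worst <- clans[[which.min(clan_best)]]
  width <- (cfg$bounds[, 2L] - cfg$bounds[, 1L]) * 0.1
  for (i in worst) {
    newx <- state$gbest + stats::runif(cfg$dims, -width / 2, width / 2)
    newx <- pmin(pmax(newx, cfg$bounds[, 1L]), cfg$bounds[, 2L])
    f <- fitness(newx)
    if (!is.finite(f)) next
    state$positions[i, ] <- newx
    state$velocities[i, ] <- 0
    state$pbest[i, ] <- newx
    state$pbest_fit[i] <- f
    if (f > state$gbest_fit) {
      state$gbest <- newx
      state$gbest_fit <- f
    }
  }
  state
}
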