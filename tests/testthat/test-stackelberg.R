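test_that("follower_utility: direct substitution and term arithmetic", {
  g <- game_spec(n_followers = 2, p = 1, q = 1, r = 0)
  expect_equal(follower_utility(g, 1, 1, 1), 0.5)
  expect_equal(follower_utility(g, 0.7, 0, 2), 0)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(1); q <- runif(1, 0.1, 2); r <- runif(1)
    gi <- game_spec(n_followers = 1, p = p, q = q, r = r)
    x <- runif(1); y <- runif(1, 0, 5)
    expect_equal(follower_utility(gi, x, y, 1),
                 p * x * y - q * y^2 / 2 - r * y)
  }
  expect_error(follower_utility(g, 1, 1, 5), "out of range")
})

test_that("leader_utility: term isolation and summation oracle", {
  lin <- function(x, y, pars) y   # linear accuracy plug-in
  g1 <- game_spec(n_followers = 3, lambda1 = 1, lambda2 = 0,
                  accuracy_fn = lin)
  expect_equal(leader_utility(g1, 0.4, c(1, 2, 3)), 6)
  g2 <- game_spec(n_followers = 2, lambda1 = 0, lambda2 = 1,
                  e = c(0.5, 0.25), g = c(0.1, 0.2))
  x <- 0.8; y <- c(1, 2)
  expect_equal(leader_utility(g2, x, y),
               -(0.5 * 1 + 0.1 * x) - (0.25 * 2 + 0.2 * x))
  set.seed(9)
  g3 <- game_spec(n_followers = 3, lambda1 = runif(1), lambda2 = runif(1),
                  a = runif(3, 1, 2), k = runif(3, 0.5, 1.5),
                  e = runif(3, 0, .2), g = runif(3, 0, .1))
  y <- runif(3, 0, 4); x <- runif(1)
  oracle <- sum(sapply(1:3, function(i) {
    g3$lambda1 * g3$a[i] * (1 - exp(-g3$k[i] * y[i])) -
      g3$lambda2 * (g3$e[i] * y[i] + g3$g[i] * x)
  }))
  expect_equal(leader_utility(g3, x, y), oracle)
  expect_error(leader_utility(g3, x, c(1, 2)), "one entry per follower")
})

test_that("follower_best_response: analytic optimum, clipping, custom oracle", {
  g <- game_spec(n_followers = 1, p = 1, q = 1, r = 0,
                 follower_bounds = c(0, 10))
  expect_equal(follower_best_response(g, 0.5, 1), 0.5)
  expect_equal(follower_best_response(g, 20, 1), 10)

  # non-default concave utility vs dense grid search
  cu <- function(x, y, pars) -(y - 2 * x)^2 + log1p(y)
  gc <- game_spec(n_followers = 1, follower_bounds = c(0, 6),
                  follower_utility_fn = cu)
  for (x in c(0.3, 1.1, 2.4)) {
    ys <- seq(0, 6, length.out = 1e5)
    y_grid <- ys[which.max(cu(x, ys, NULL))]
    expect_lt(abs(follower_best_response(gc, x, 1) - y_grid), 1e-4)
  }
})

test_that("best responses are nondecreasing and piecewise linear in x", {
  g <- game_spec(n_followers = 1, p = 1.3, q = 0.9, r = 0.2,
                 follower_bounds = c(0, 2), leader_bounds = c(0, 3))
  xs <- seq(0, 3, length.out = 61)
  ys <- vapply(xs, function(x) follower_best_response(g, x, 1), numeric(1))
  expect_true(all(diff(ys) >= -1e-12))
  interior <- ys > 0 & ys < 2
  expect_equal(ys[interior], (1.3 * xs[interior] - 0.2) / 0.9)
})

test_that("solvers find the analytic interior equilibrium", {
  inst <- generate_game_instance(n_followers = 3, seed = 123)
  for (sv in c("closed_form", "grid")) {
    eq <- solve_stackelberg(inst$game, solver = sv, tol = 1e-8)
    expect_lt(abs(eq$x_star - inst$reference$x_star), 1e-3)
    expect_lt(abs(eq$leader_utility - inst$reference$leader_utility), 1e-3)
    expect_lte(eq$residual, 1e-8)
    expect_equal(eq$y_star,
                 vapply(1:3, function(i)
                   follower_best_response(inst$game, eq$x_star, i),
                   numeric(1)),
                 tolerance = 1e-4)
  }
  eqn <- solve_stackelberg(inst$game, solver = "npo")
  expect_lt(abs(eqn$leader_utility - inst$reference$leader_utility), 1e-3)
})

test_that("monotone case: zero cost weight pushes the leader to its bound", {
  g <- game_spec(leader_bounds = c(0.2, 1.5), n_followers = 2,
                 lambda1 = 1, lambda2 = 0, p = c(1, 1.2), q = c(1, 1),
                 r = c(0, 0), follower_bounds = c(0, 10))
  eq <- solve_stackelberg(g, solver = "closed_form")
  expect_equal(eq$x_star, 1.5)
})

test_that("equilibrium total cost never rises as lambda2 increases", {
  inst <- generate_game_instance(n_followers = 3, seed = 77)
  total_cost <- function(l2) {
    g <- inst$game
    g$lambda2 <- l2
    eq <- solve_stackelberg(g, solver = "closed_form")
    sum(g$e * eq$y_star + g$g * eq$x_star)
  }
  costs <- vapply(seq(0.1, 2, by = 0.2), total_cost, numeric(1))
  expect_true(all(diff(costs) <= 1e-9))
})

test_that("validate_game catches the stated violations", {
  expect_true(validate_game(game_spec(n_followers = 2, q = 1))$ok)
  v1 <- validate_game(game_spec(n_followers = 2, q = c(1, -1)))
  expect_false(v1$ok)
  expect_match(v1$violations, "concave", all = FALSE)
  g_bad <- game_spec(n_followers = 1)
  g_bad$follower_bounds <- matrix(c(2, 1), 1)   # lo > hi
  v2 <- validate_game(g_bad)
  expect_false(v2$ok)
  expect_match(v2$violations, "empty", all = FALSE)
  # custom convex utility flagged by the probe
  gcv <- game_spec(n_followers = 1, follower_bounds = c(0, 3),
                   follower_utility_fn = function(x, y, pars) y^2)
  expect_false(validate_game(gcv)$ok)
})

test_that("game instances are reproducible and self-consistent", {
  a <- generate_game_instance(4, seed = 5)
  b <- generate_game_instance(4, seed = 5)
  expect_identical(a, b)
  expect_lt(a$reference$foc_residual, 1e-8)
  expect_true(validate_game(a$game)$ok)
  expect_gte(a$reference$x_star, a$game$leader_bounds[1])
  expect_lte(a$reference$x_star, a$game$leader_bounds[2])
})
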