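test_that("L2 ball projection matches the radial closed form and is idempotent", {
  expect_equal(project_l2_ball(c(3, 4), c(0, 0), 1), c(0.6, 0.8),
               tolerance = 1e-15)
  y <- c(0.1, -0.2, 0.05)
  expect_identical(project_l2_ball(y, c(0, 0, 0), 1), y)  # interior point
  p1 <- project_l2_ball(c(5, 5), c(1, 1), 0.7)
  expect_identical(project_l2_ball(p1, c(1, 1), 0.7), p1)
  expect_error(project_l2_ball(c(1, 2), c(0, 0, 0), 1), "length")
  expect_error(project_l2_ball(c(1, 2), c(0, 0), -1), "nonnegative")
})

test_that("TV prox degenerate cases return the input", {
  g <- random_graph(6, seed = 3)
  set.seed(33)
  y <- rnorm(6)
  expect_identical(prox_graph_tv(y, 0, g), y)
  flat <- rep(0.4, 6)
  expect_equal(prox_graph_tv(flat, 0.3, g, inner_iter = 500,
                             inner_tol = 1e-12), flat, tolerance = 1e-10)
})

test_that("TV prox reproduces the two-node closed form", {
  g2 <- weighted_graph(1L, 2L, 1, 2)
  y <- c(0, 1)
  for (gam in c(0.05, 0.15, 0.25)) {
    u <- prox_graph_tv(y, gam, g2, inner_iter = 150000, inner_tol = 1e-14)
    expect_lt(max(abs(u - c(2 * gam, 1 - 2 * gam))), 1e-5)
  }
  for (gam in c(0.3, 1)) {
    u <- prox_graph_tv(y, gam, g2, inner_iter = 150000, inner_tol = 1e-14)
    expect_lt(max(abs(u - c(0.5, 0.5))), 1e-5)
  }
})

test_that("TV prox objectives match the certified dual reference on random graphs", {
  for (seed in 1:6) {
    g <- random_graph(7, seed = seed)
    set.seed(seed + 500)
    y <- rnorm(7)
    gam <- runif(1, 0.05, 0.6)
    u <- prox_graph_tv(y, gam, g, inner_iter = 30000, inner_tol = 1e-11)
    ref <- prox_tv_reference(y, gam, g, gap_tol = 1e-10)
    obj <- 0.5 * sum((u - y)^2) + gam * tv_bruteforce(u, g)
    expect_lt(abs(obj - ref$objective), 1e-6)
  }
})

test_that("TV prox is (approximately) firmly nonexpansive", {
  g <- random_connected_graph(6, seed = 9)
  set.seed(77)
  for (rep in 1:3) {
    a <- rnorm(6); b <- rnorm(6)
    pa <- prox_graph_tv(a, 0.3, g, inner_iter = 20000, inner_tol = 1e-12)
    pb <- prox_graph_tv(b, 0.3, g, inner_iter = 20000, inner_tol = 1e-12)
    lhs <- sum((pa - pb)^2)
    rhs <- sum((pa - pb) * (a - b))
    expect_lte(lhs, rhs + 1e-6)
  }
})

test_that("ball radius heuristic follows tau * sigma/255 * sqrt(n)", {
  expect_identical(ball_radius_heuristic(noise_model(0, seed = 1), 100), 0)
  expect_equal(ball_radius_heuristic(noise_model(25.5, seed = 1), 4096),
               6.4, tolerance = 1e-12)
  e1 <- ball_radius_heuristic(noise_model(20, seed = 1), 50, tau = 1)
  e2 <- ball_radius_heuristic(noise_model(20, seed = 1), 50, tau = 2.5)
  expect_equal(e2, 2.5 * e1, tolerance = 1e-12)
})

test_that("solver config validates its constants", {
  expect_error(solver_config(-1), "nonnegative")
  expect_error(solver_config(1, gamma = 0), "positive")
  expect_error(solver_config(1, relax = 1.995), "relax")
  expect_error(solver_config(1, tol = 0), "positive")
})

test_that("a zero-radius ball returns the observation exactly", {
  g <- random_connected_graph(8, seed = 4)
  set.seed(44)
  u0 <- rnorm(8)
  fit <- drs_solve(u0, g, solver_config(ball_radius = 0))
  expect_identical(fit$x, u0)
})

test_that("DRS output is feasible and never rougher than the observation", {
  for (seed in 1:4) {
    g <- random_connected_graph(8, seed = seed)
    set.seed(seed + 900)
    u0 <- rnorm(8)
    eps <- 0.4 * sqrt(sum((u0 - mean(u0))^2))
    fit <- drs_solve(u0, g, solver_config(ball_radius = eps, gamma = 0.5,
                                          tol = 1e-8, max_iter = 2000,
                                          inner_iter = 1000,
                                          inner_tol = 1e-10))
    expect_lte(sqrt(sum((fit$x - u0)^2)), eps * (1 + 1e-9))
    expect_lte(tv_value_pkg(fit$x, g), tv_value_pkg(u0, g))
    expect_identical(length(fit$state$tv_trace), fit$state$iterations)
  }
})

test_that("DRS reaches the same fixed point for different relaxation steps", {
  g <- random_connected_graph(7, seed = 12)
  set.seed(1212)
  u0 <- rnorm(7)
  eps <- 0.5 * sqrt(sum((u0 - mean(u0))^2))
  sols <- lapply(c(0.5, 1.0, 1.5), function(lam) {
    drs_solve(u0, g, solver_config(ball_radius = eps, gamma = 0.5,
                                   relax = lam, tol = 1e-10,
                                   max_iter = 5000, inner_iter = 2000,
                                   inner_tol = 1e-11))$x
  })
  expect_equal(sols[[1]], sols[[2]], tolerance = 1e-5)
  expect_equal(sols[[3]], sols[[2]], tolerance = 1e-5)
})
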