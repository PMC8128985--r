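test_that("Vlasov drift and diffusion match closed-form rule moments", {
  dp <- dialect_params(2, 0.1, 2)
  rule <- dialect_rule(dp)
  co <- vlasov_coefficients(rule, constant_kernel(1))
  # rescaled drift: w * (p(v_tilde) - v)
  W <- co$drift(0.3, c(0.5, 0.5), 0.7, c(0.8, 0.2))
  expect_equal(W, c(16 / 17 - 0.5, 1 / 17 - 0.5), tolerance = 1e-12)
  # kernel scales the drift
  co2 <- vlasov_coefficients(rule, constant_kernel(2))
  expect_equal(co2$drift(0, c(0.5, 0.5), 0, c(0.8, 0.2)), 2 * W)
  # unscaled diffusion at a corner partner: single-atom second moment
  co_raw <- vlasov_coefficients(rule, constant_kernel(1), rescaled = FALSE)
  A <- co_raw$diffusion(0, c(0.5, 0.5), 0, c(1, 0))
  gp <- 0.1 / 1.1
  expect_equal(A, 0.5 * gp^2 * rbind(c(0.25, -0.25), c(-0.25, 0.25)),
               tolerance = 1e-12)
})

test_that("diffusion matrix is symmetric PSD on random state pairs", {
  rule <- dialect_rule(dialect_params(3, 0.2, 2))
  co <- vlasov_coefficients(rule, triangular_kernel(1, 0.4))
  V <- random_simplex(20, 3, seed = 6)
  for (k in 1:10) {
    A <- co$diffusion(0.1, V[2 * k - 1, ], 0.3, V[2 * k, ])
    expect_equal(A, t(A))
    expect_true(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values) >= -1e-14)
  }
})

test_that("rule moment functions agree with Monte-Carlo sampling", {
  dp <- dialect_params(2, 0.15, 2)
  rule <- dialect_rule(dp)
  v_act <- c(0.7, 0.3); v_pas <- c(0.4, 0.6)
  set.seed(13)
  bs <- t(replicate(20000, {
    rule$update_pair(v_act, v_pas)$passive - v_pas
  }))
  mb <- rule$mean_b(v_act, v_pas)
  se <- apply(bs, 2, sd) / sqrt(nrow(bs))
  expect_true(all(abs(colMeans(bs) - mb) <= 4 * se))
  B_mc <- crossprod(bs) / nrow(bs)
  expect_equal(B_mc, rule$second_b(v_act, v_pas), tolerance = 0.05)
})

test_that("fixed points of the drift give constant particle trajectories", {
  rule <- dialect_rule(dialect_params(2, 0.1, 2))
  co <- vlasov_coefficients(rule, constant_kernel(1))
  corner <- matrix(rep(c(1, 0), each = 5), 5, 2)
  parts <- meanfield_particles(runif(5), corner)
  traj <- solve_vlasov_particles(parts, co, t_end = 1, dt = 0.05)
  expect_equal(trajectory_state(traj, 1), corner, tolerance = 1e-12)
})

test_that("linear toy rule reproduces its closed-form exponential decay", {
  # two particles with masses (0.3, 0.7), w = 1: each state relaxes to the
  # conserved weighted mean at unit rate.
  rule <- linear_relaxation_rule()
  co <- vlasov_coefficients(rule, constant_kernel(1))
  parts <- meanfield_particles(c(0.2, 0.8), matrix(c(1, -1), 2, 1),
                               masses = c(0.3, 0.7))
  traj <- solve_vlasov_particles(parts, co, t_end = 1.5, dt = 0.005,
                                 project = FALSE)
  vbar <- 0.3 * 1 + 0.7 * (-1)
  for (tt in c(0.5, 1.5)) {
    got <- trajectory_state(traj, tt)
    expect_equal(got[1], vbar + (1 - vbar) * exp(-tt), tolerance = 1e-6)
    expect_equal(got[2], vbar + (-1 - vbar) * exp(-tt), tolerance = 1e-6)
  }
})

test_that("monokinetic particle data reproduces the monokinetic solver", {
  n <- 16
  g <- spatial_grid(n)
  V0 <- random_simplex(n, 2, seed = 17)
  dp <- dialect_params(2, 0.1, 2)
  rule <- dialect_rule(dp)
  kern <- triangular_kernel(1, 0.3)
  km <- discretize_kernel(kern, g, density = rep(1, n))
  parts <- meanfield_particles(g$points, V0, masses = g$quad_weights)
  co <- vlasov_coefficients(rule, kern)
  tp <- solve_vlasov_particles(parts, co, t_end = 2, dt = 0.01)
  tm <- solve_monokinetic(V0, km, rule, t_end = 2, dt = 0.01)
  expect_equal(trajectory_state(tp, 2), trajectory_state(tm, 2),
               tolerance = 1e-10)
})

test_that("single-node monokinetic dynamics matches an independent ODE oracle", {
  skip_if_not_installed("deSolve")
  dp <- dialect_params(2, 0.1, 3)
  rule <- dialect_rule(dp)
  net <- node_network(matrix(2, 1, 1), rho = 1.5, include_diagonal = TRUE)
  km <- discretize_kernel(NULL, net)
  V0 <- matrix(c(0.62, 0.38), 1)
  tm <- solve_monokinetic(V0, km, rule, t_end = 3, dt = 0.002)
  oracle <- deSolve::ode(
    y = c(0.62), times = c(0, 3),
    func = function(t, y, p) {
      v <- pmin(pmax(c(y, 1 - y), 0), 1)  # guard adaptive trial steps
      list(2 * 1.5 * (choice_probabilities(v, 3) - v)[1])
    }, parms = NULL, method = "ode45")
  expect_equal(trajectory_state(tm, 3)[1], unname(oracle[2, 2]),
               tolerance = 1e-5)
})

test_that("generic monokinetic solver agrees with the dialect closure", {
  n <- 20
  g <- spatial_grid(n)
  V0 <- random_simplex(n, 3, seed = 23)
  dp <- dialect_params(3, 0.1, 2)
  rule <- dialect_rule(dp)
  km <- discretize_kernel(triangular_kernel(0.8, 0.25), g, density = rep(1, n))
  a <- solve_monokinetic(V0, km, rule, t_end = 1, dt = 0.01)
  b <- solve_dialect_monokinetic(V0, km, dp, t_end = 1, dt = 0.01,
                                 model = "network")
  expect_equal(a$states, b$states, tolerance = 1e-12)
})

test_that("particle clouds concentrate onto the monokinetic trajectory", {
  # spread initial data with small per-position dispersion stays close to
  # the concentrated solution and the distance decays in time
  n_nodes <- 10; per <- 8
  set.seed(29)
  x <- rep((0:(n_nodes - 1)) / n_nodes, each = per)
  Vc <- random_simplex(n_nodes, 2, seed = 30)
  spread <- 0.02 * (runif(length(x)) - 0.5)
  V0 <- Vc[rep(1:n_nodes, each = per), ]
  V0[, 1] <- pmin(pmax(V0[, 1] + spread, 0), 1); V0[, 2] <- 1 - V0[, 1]
  rule <- dialect_rule(dialect_params(2, 0.1, 2))
  co <- vlasov_coefficients(rule, constant_kernel(1))
  parts <- meanfield_particles(x, V0)
  traj <- solve_vlasov_particles(parts, co, t_end = 2, dt = 0.01)
  km <- discretize_kernel(constant_kernel(1),
                          node_network(matrix(1, n_nodes, n_nodes),
                                       rho = rep(1 / n_nodes, n_nodes),
                                       include_diagonal = TRUE))
  mono <- solve_monokinetic(Vc, km, rule, t_end = 2, dt = 0.01)
  d_at <- function(tt) {
    concentration_metric(x, trajectory_state(traj, tt),
                         trajectory_state(mono, tt), p = 2)
  }
  expect_lt(d_at(0), 0.03)
  expect_lt(d_at(2), d_at(0))
  expect_lt(d_at(2), 0.05)
})
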