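test_that("SIR agent rule: only I->S pairs act, removal is a pure death process", {
  rule <- sir_rule(0.5)
  # susceptible-only ensembles never fire an event
  ens_s <- agent_ensemble(runif(30), rep(sir_codes[["S"]], 30), "categorical")
  out <- simulate_boltzmann(ens_s, rule, constant_kernel(1), t_end = 5, seed = 1)
  expect_equal(out$ensemble$states, ens_s$states)
  # null pairs leave states alone
  expect_equal(rule$update_pair(sir_codes[["S"]], sir_codes[["I"]])$passive,
               sir_codes[["I"]])
  expect_equal(rule$update_pair(sir_codes[["I"]], sir_codes[["S"]])$passive,
               sir_codes[["I"]])
  # all-infected ensemble decays at rate beta (pure death, MC over seeds)
  fracI <- vapply(1:30, function(r) {
    ensI <- agent_ensemble(runif(100), rep(sir_codes[["I"]], 100), "categorical")
    s <- simulate_boltzmann(ensI, rule, constant_kernel(0), t_end = 2, seed = r)
    mean(s$ensemble$states == sir_codes[["I"]])
  }, numeric(1))
  p <- exp(-0.5 * 2)
  se <- sqrt(p * (1 - p) / 100) / sqrt(30)
  expect_lt(abs(mean(fracI) - p), 4 * se)
})

test_that("S count is nonincreasing along every trajectory", {
  set.seed(6)
  ens <- agent_ensemble(runif(100),
                        sample(c(1L, 2L), 100, TRUE, c(0.7, 0.3)), "categorical")
  s <- simulate_boltzmann(ens, sir_rule(0.2), triangular_kernel(3, 0.3),
                          t_end = 4, seed = 10,
                          snapshot_times = seq(0.5, 4, 0.5))
  nS <- apply(s$snapshots$states, 3, function(m) sum(m == 1))
  expect_true(all(diff(nS) <= 0))
})

test_that("network SIR: degenerate initial data gives closed-form solutions", {
  g <- spatial_grid(40)
  km <- discretize_kernel(triangular_kernel(0.3, 0.2), g)
  # no infected: nothing moves
  tr <- solve_sir_network(rep(0.8, 40), rep(0, 40), km, beta = 0.1, t_end = 2)
  expect_equal(trajectory_state(tr, 2)[, 1], rep(0.8, 40))
  expect_equal(trajectory_state(tr, 2)[, 3], rep(0, 40))
  # no susceptibles: v decays exponentially at rate beta
  v0 <- generate_fixture("peaked_field", n = 40, height = 0.3)
  tr2 <- solve_sir_network(rep(0, 40), v0, km, beta = 0.4, t_end = 2,
                           dt = 0.001)
  expect_equal(trajectory_state(tr2, 2)[, 2], v0 * exp(-0.4 * 2),
               tolerance = 1e-3)  # first-order Euler bias at dt = 1e-3
})

test_that("the two algebraic forms of the network model coincide", {
  scn <- fig1_scenario()
  km <- discretize_kernel(scn$kernel, scn$grid)
  a <- solve_sir_network(scn$u0, scn$v0, km, scn$beta, 1, scn$dt)
  b <- solve_sir_network(scn$u0, scn$v0, km, scn$beta, 1, scn$dt,
                         form = "reaction_diffusion")
  expect_equal(a$states, b$states, tolerance = 1e-13)
})

test_that("structural bounds hold along the reference epidemic run", {
  scn <- fig1_scenario()
  traj <- run_sir_scenario(scn, "network")
  rep <- conservation_report(traj, "sir")
  expect_true(rep$pass)
  expect_gte(rep$min_uv, 0)
  expect_lte(rep$max_uv_excess, 1e-12)      # u + v <= u0 + v0 pointwise
  expect_lte(rep$mass_residual, 1e-8)       # u + v + r conserved
  expect_equal(rep$u_monotonicity_violations, 0)
})

test_that("rd comparison model conserves mass up to removal and disperses u", {
  scn <- fig1_scenario()
  km <- discretize_kernel(scn$kernel, scn$grid)
  trd <- solve_sir_rd_comparison(scn$u0, scn$v0, km, scn$beta, D1 = 1, D2 = 1,
                                 t_end = 5, dt = 0.01)
  qw <- scn$grid$quad_weights
  # integral identity: d/dt (int u + int v) = -beta int v, so
  # int u + int v + beta * int_0^t int v ds is constant (Euler quadrature)
  U <- trd$states[, 1, ]; V <- trd$states[, 2, ]
  intu <- colSums(qw * U); intv <- colSums(qw * V)
  cum <- c(0, cumsum(0.01 * scn$beta * intv[-length(intv)]))
  lhs <- intu + intv + cum
  expect_lt(max(abs(lhs - lhs[1])), 1e-6)
  # D1 = D2 = 0 reduces to the pointwise mass-action ODEs
  t0 <- solve_sir_rd_comparison(scn$u0, scn$v0, km, scn$beta, D1 = 0, D2 = 0,
                                t_end = 1, dt = 0.01)
  alpha_x <- km$row_integral
  rhs_ode <- function(t, y, p) {
    u <- y[1:100]; v <- y[101:200]
    list(c(-alpha_x * u * v, alpha_x * u * v - scn$beta * v))
  }
  skip_if_not_installed("deSolve")
  oracle <- deSolve::ode(c(scn$u0, scn$v0), c(0, 1), rhs_ode, NULL,
                         method = "ode45")
  expect_equal(trajectory_state(t0, 1)[, 1], unname(oracle[2, 2:101]),
               tolerance = 1e-5)
  # v0 = 0: u relaxes toward uniformity, constants stay constant
  tu <- solve_sir_rd_comparison(scn$u0, rep(0, 100), km, scn$beta,
                                t_end = 2, dt = 0.01)
  expect_equal(trajectory_state(tu, 2)[, 1], scn$u0)
  bump <- scn$u0 + generate_fixture("peaked_field", n = 100, height = 0.2)
  tb <- solve_sir_rd_comparison(bump, rep(0, 100), km, scn$beta,
                                t_end = 5, dt = 0.01)
  spread0 <- diff(range(bump)); spread5 <- diff(range(trajectory_state(tb, 5)[, 1]))
  expect_lt(spread5, spread0)
})

test_that("network vs rd contrast: more infections without susceptible transport", {
  scn <- fig1_scenario()
  tn <- run_sir_scenario(scn, "network")
  trd <- run_sir_scenario(scn, "rd", D1 = 1, D2 = 1)
  qw <- scn$grid$quad_weights
  r_net <- sum(qw * trajectory_state(tn, 5)[, 3])
  r_rd <- sum(qw * trajectory_state(trd, 5)[, 3])
  expect_gt(r_net, r_rd)
  # rd transports susceptibles: a dip forms at the seed relative to far field
  u_rd <- trajectory_state(trd, 5)[, 1]
  expect_lt(u_rd[51], u_rd[1])
  # rd smoothes the infected peak more than the network model
  expect_lt(max(trajectory_state(trd, 5)[, 2]), max(trajectory_state(tn, 5)[, 2]))
})

test_that("local limits: classical SIR oracle and the sign-violation demo", {
  g <- spatial_grid(50)
  # leading order with constant data equals the classical SIR ODEs
  u0 <- rep(0.9, 50); v0 <- rep(0.1, 50)
  tl <- solve_sir_local(u0, v0, g, beta = 0.5, alpha_coef = 2, t_end = 3,
                        dt = 0.005, variant = "leading_order", scheme = "rk4")
  skip_if_not_installed("deSolve")
  oracle <- deSolve::ode(c(u = 0.9, v = 0.1), c(0, 3),
                         function(t, y, p) list(c(-2 * y[1] * y[2],
                                                  2 * y[1] * y[2] - 0.5 * y[2])),
                         NULL, method = "ode45")
  expect_equal(trajectory_state(tl, 3)[1, 1:2], unname(oracle[2, 2:3]),
               tolerance = 1e-4)
  # v = 0 keeps u constant in both variants
  for (variant in c("degenerate", "leading_order")) {
    t0 <- solve_sir_local(u0, rep(0, 50), g, 0.5, 2, 1, 0.01, variant)
    expect_equal(trajectory_state(t0, 1)[, 1], u0)
  }
  # narrow concave infected bump with Lap v < -alpha v makes du/dt > 0:
  # the degenerate system violates monotonicity of the susceptibles
  vb <- generate_fixture("peaked_field", n = 50, center = 0.5, width = 0.05,
                         height = 0.1)
  td <- solve_sir_local(rep(1, 50), vb, g, beta = 0.1, alpha_coef = 1,
                        t_end = 0.01, dt = 0.001, variant = "degenerate")
  expect_gt(length(td$du_positive), 0)
  expect_true(26 %in% td$du_positive)  # at the peak itself
})

test_that("the packaged scenario carries the reference configuration", {
  scn <- fig1_scenario()
  expect_equal(length(scn$grid$points), 100)
  expect_equal(scn$grid$h, 0.01)
  expect_equal(evaluate_kernel(scn$kernel, 0.3, 0.3), 0.06)  # 0.3 * 0.2
  km <- discretize_kernel(scn$kernel, scn$grid)
  expect_equal(km$row_integral, rep(0.012, 100), tolerance = 1e-12)
  expect_equal(scn$beta, 0.1)
  expect_equal(scn$dt, 0.01)
  expect_equal(scn$u0, rep(1, 100))
  expect_equal(which.max(scn$v0), 51)  # peak at x = 0.5
  expect_equal(max(scn$v0), 0.05)
})

test_that("binned agent fractions track the continuum fields (MC bands)", {
  set.seed(44)
  n_nodes <- 20
  nodes <- (0:(n_nodes - 1)) / n_nodes
  per <- 100; N <- n_nodes * per
  x <- rep(nodes, each = per)
  kern <- constant_kernel(1)
  beta <- 0.5
  p_inf <- 0.2
  states <- ifelse(runif(N) < p_inf, sir_codes[["I"]], sir_codes[["S"]])
  ens <- agent_ensemble(x, states, "categorical")
  # continuum initial data = exact sampled per-node fractions, density 1
  vI <- vapply(seq_len(n_nodes), function(k) mean(states[x == nodes[k]] == 2L),
               numeric(1))
  net <- node_network(matrix(1, n_nodes, n_nodes), rho = rep(1 / n_nodes, n_nodes),
                      include_diagonal = TRUE)
  km <- discretize_kernel(NULL, net)
  km$matrix <- km$matrix / n_nodes  # eta mass 1/n per node
  km$row_integral <- rowSums(km$matrix)
  tr <- solve_sir_network(1 - vI, vI, km, beta, t_end = 2, dt = 0.005,
                          record_times = c(1, 2))
  sim <- simulate_boltzmann(ens, sir_rule(beta), kern, t_end = 2, seed = 45,
                            snapshot_times = c(1, 2))
  for (k in 1:2) {
    snap <- sim$snapshots$states[, , k]
    fI <- vapply(seq_len(n_nodes), function(j) mean(snap[x == nodes[j]] == 2L),
                 numeric(1))
    vpde <- trajectory_state(tr, c(1, 2)[k])[, 2]
    # binomial band: per-node sd <= 0.5/sqrt(per), averaged over 20 nodes
    expect_lt(mean(abs(fI - vpde)), 0.08)
  }
})
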