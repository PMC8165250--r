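test_that("stage and terminal costs are the expected quadratic forms", {
  model <- models$active
  cfg <- nmpc_config(q_angle = 1e3, q_vel = 1e3, r_scale = 1,
                     qf_factor = 100)
  z6 <- numeric(6); z3 <- numeric(3)
  expect_equal(stage_cost(z6, z3, cfg, model), 0)
  expect_equal(terminal_cost(z6, cfg, model), 0)
  x <- c(0.1, -0.2, 0.3, 0.5, 0, -1)
  tau <- c(10, -20, 5)
  expect_equal(stage_cost(x, tau, cfg, model),
               0.5 * (1e3 * sum(x^2) + sum(tau^2)))
  # quadratic scaling: doubling x quadruples the state part
  expect_equal(stage_cost(2 * x, z3, cfg, model),
               4 * stage_cost(x, z3, cfg, model))
  # state-to-input weight ratio 10^3 by direct evaluation
  ones_x <- rep(1, 6); ones_u <- rep(1, 3)
  expect_equal(stage_cost(ones_x, z3, cfg, model) /
                 stage_cost(z6, ones_u, cfg, model), 1e3 * 6 / 3)
  # terminal: Qf = 1e5 I, x = e1 -> 0.5e5
  e1 <- c(1, numeric(5))
  expect_equal(terminal_cost(e1, cfg, model), 0.5e5)
  expect_equal(terminal_cost(e1, cfg, model) / stage_cost(e1, z3, cfg,
                                                          model), 1e2)
  expect_error(stage_cost(numeric(4), z3, cfg, model), "dimension")
})

test_that("per-mode default bounds carry the standard boxes", {
  ba <- default_bounds("active")
  expect_equal(ba$tau_min, c(-120, -500, -200))
  expect_equal(ba$tau_max, c(120, 500, 200))
  expect_length(ba$x_min, 6)
  expect_equal(ba$x_min[1:2], c(-0.2, -0.35))
  expect_equal(ba$x_max[1:2], c(0.4, 1.3))
  expect_equal(abs(ba$x_max[3] - ba$x_min[3]), 3)  # 3 rad arm range
  expect_true(all(is.infinite(ba$x_max[4:6])))
  bp <- default_bounds("passive")
  expect_equal(bp$tau_min, c(-120, -500))
  expect_length(bp$x_min, 6)
  bf <- default_bounds("fixed")
  expect_equal(bf$tau_max, c(120, 500))
  expect_length(bf$x_min, 4)
  expect_equal(bf$x_min[1:2], c(-0.2, -0.35))
  expect_error(nmpc_bounds(1, 0, -1, 1), "min <= max")
})

test_that("discrete map has the equilibrium fixed point and RK4 local
           order", {
  model <- models$active
  f1 <- discretize(model, 0.05)
  expect_equal(f1(numeric(6), numeric(3)), numeric(6))
  # one-step error vs a fine reference drops ~16x when dt halves
  x0 <- c(0.1, -0.05, 0.2, 0.3, 0.1, -0.4)
  tau <- c(10, 5, -2)
  ref <- x0
  fref <- discretize(model, 0.1 / 1024)
  for (i in 1:1024) ref <- fref(ref, tau)
  err <- function(dt) {
    f <- discretize(model, dt)
    x <- x0
    for (i in seq_len(round(0.1 / dt))) x <- f(x, tau)
    max(abs(x - ref))
  }
  e1 <- err(0.1)
  e2 <- err(0.05)
  expect_gt(e1 / e2, 8)
  expect_lt(e1 / e2, 40)
})

test_that("one-step map agrees with a high-accuracy ODE solution", {
  skip_if_not_installed("deSolve")
  model <- models$passive
  tau <- c(15, -30)
  x0 <- c(0.1, 0.2, -0.3, 0.1, -0.2, 0.5)
  rhs <- function(t, y, parms) {
    list(c(y[4:6], forward_dynamics(model, y[1:3], y[4:6], tau, 25)))
  }
  out <- deSolve::lsoda(x0, c(0, 0.05), rhs, NULL, rtol = 1e-11,
                        atol = 1e-11)
  ref <- unname(out[2, -1])
  # one coarse RK4 step carries its truncation error ...
  f <- discretize(model, 0.05)
  expect_lt(max(abs(f(x0, tau, 25) - ref)), 5e-4)
  # ... which refinement removes
  f10 <- discretize(model, 0.005)
  x <- x0
  for (i in 1:10) x <- f10(x, tau, 25)
  expect_lt(max(abs(x - ref)), 1e-7)
})

test_that("the optimal control problem returns zero torque at
           equilibrium", {
  for (model in models) {
    sol <- solve_ocp(model, numeric(2 * model$dof), 0, nmpc_config())
    expect_equal(sol$status, "optimal")
    expect_equal(max(abs(sol$tau_opt)), 0, tolerance = 1e-8)
    expect_equal(sol$cost, 0, tolerance = 1e-10)
  }
})

test_that("near the origin with inactive constraints the first NMPC input
           matches the finite-horizon LQR", {
  cfg <- nmpc_config()
  for (model in models) {
    n2 <- 2 * model$dof
    x0 <- 0.01 * seq(-1, 1, length.out = n2)
    sol <- solve_ocp(model, x0, 0, cfg)
    expect_equal(sol$status, "optimal")
    lqr <- finite_horizon_lqr(model, cfg)
    u_lqr <- -as.numeric(lqr$K[[1]] %*% x0)
    expect_lt(sqrt(sum((sol$tau_opt[, 1] - u_lqr)^2)) /
                sqrt(sum(u_lqr^2)), 0.01)
  }
})

test_that("warm-started resolve reproduces the cold solution", {
  model <- models$active
  cfg <- nmpc_config()
  x0 <- c(0.03, -0.02, 0.05, 0.1, 0, -0.1)
  cold <- solve_ocp(model, x0, 0, cfg)
  warm <- solve_ocp(model, x0, 0, cfg, warm_start = cold$warm)
  expect_equal(warm$tau_opt[, 1], cold$tau_opt[, 1], tolerance = 1e-4)
  expect_equal(warm$cost, cold$cost, tolerance = 1e-6)
})

test_that("solutions respect torque boxes and predicted state boxes", {
  model <- models$active
  cfg <- nmpc_config()
  bounds <- default_bounds("active")
  # a strong perturbed state forces the ankle torque onto its box
  x0 <- c(0.15, 0.3, 0.1, 0.5, 0.8, 0)
  sol <- solve_ocp(model, x0, 70, cfg, bounds)
  expect_true(all(sol$tau_opt >= bounds$tau_min - 1e-9))
  expect_true(all(sol$tau_opt <= bounds$tau_max + 1e-9))
  if (sol$status == "optimal") {
    pred <- sol$x_opt[, -1]
    expect_true(all(pred >= bounds$x_min - 1e-6))
    expect_true(all(pred <= bounds$x_max + 1e-6))
  }
})

test_that("predicted trajectory is dynamically consistent with the
           rollout map", {
  model <- models$passive
  cfg <- nmpc_config()
  x0 <- c(0.05, -0.1, 0.02, 0, 0.2, 0)
  sol <- solve_ocp(model, x0, 30, cfg)
  f <- discretize(model, cfg$dt)
  x <- x0
  for (k in seq_len(cfg$horizon)) {
    x <- f(x, sol$tau_opt[, k], 30)
    expect_lt(max(abs(x - sol$x_opt[, k + 1])), 1e-9)
  }
})

test_that("mpc_step applies the first sample and keeps torques in the
           box", {
  model <- models$fixed
  cfg <- nmpc_config()
  ctrl <- nmpc_controller(model, cfg)
  st <- mpc_step(ctrl, numeric(4))
  expect_equal(st$tau, c(0, 0), tolerance = 1e-8)
  st2 <- mpc_step(ctrl, c(0.1, -0.05, 0.2, 0))
  expect_identical(st2$tau, st2$solution$tau_opt[, 1])
  b <- default_bounds("fixed")
  expect_true(all(st2$tau >= b$tau_min & st2$tau <= b$tau_max))
  expect_error(nmpc_controller(models$active, cfg, default_bounds("fixed")),
               "dimensions")
})

test_that("closed-loop stage cost decays for an unpushed perturbation", {
  model <- models$fixed
  cfg <- nmpc_config()
  ctrl <- nmpc_controller(model, cfg)
  f <- discretize(model, cfg$dt)
  x <- c(0.05, -0.08, 0, 0)
  costs <- numeric(200)
  for (k in 1:200) {
    st <- mpc_step(ctrl, x)
    costs[k] <- stage_cost(x, st$tau, cfg, model)
    x <- f(x, st$tau)
  }
  expect_lt(costs[200], 1e-6 * costs[1])
})
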