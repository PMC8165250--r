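test_that("segment and body parameter validation rejects bad inputs", {
  expect_error(segment_params("x", mass = -1, length = 1), "mass")
  expect_error(segment_params("x", mass = 1, length = 0), "length")
  expect_error(segment_params("x", 1, 1, com_fraction = 1.2), "com_fraction")
  body <- anthropometric_model()
  expect_equal(total_mass(body), 69.3)
  expect_equal(body$foot_height + body$lower_body$length +
                 body$upper_body$length, 1.7)
})

test_that("model dof and torque dimensions follow the arm condition", {
  expect_equal(models$active$dof, 3L)
  expect_equal(models$passive$dof, 3L)
  expect_equal(models$fixed$dof, 2L)
  expect_equal(models$active$n_torque, 3L)
  expect_equal(models$passive$n_torque, 2L)
  expect_equal(models$fixed$n_torque, 2L)
  expect_error(mass_matrix(models$fixed, c(0, 0, 0)), "length")
})

test_that("mass matrix is symmetric positive definite across the
           configuration space", {
  set.seed(42)
  for (model in models) {
    for (i in 1:200) {
      q <- runif(model$dof, -pi / 2, pi / 2)
      M <- mass_matrix(model, q)
      expect_equal(M, t(M), tolerance = 1e-12)
      expect_gt(min(eigen(M, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
    }
  }
})

test_that("mass matrix at upright matches a finite-difference Hessian of
           the kinetic energy", {
  for (model in models) {
    n <- model$dof
    q0 <- numeric(n)
    h <- 1e-4
    H <- matrix(0, n, n)
    kin <- function(qd) energies(model, q0, qd)[["T"]]
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        ei <- numeric(n); ei[i] <- h
        ej <- numeric(n); ej[j] <- h
        H[i, j] <- (kin(ei + ej) - kin(ei - ej) - kin(ej - ei) +
                      kin(-ei - ej)) / (4 * h^2)
      }
    }
    expect_equal(mass_matrix(model, q0), H, tolerance = 1e-6)
  }
})

test_that("upright equilibrium has zero bias forces and zero acceleration", {
  for (model in models) {
    n <- model$dof
    z <- numeric(n)
    expect_equal(bias_forces(model, z, z), z, tolerance = 1e-10)
    tau <- numeric(model$n_torque)
    expect_equal(forward_dynamics(model, z, z, tau), z, tolerance = 1e-10)
  }
})

test_that("bias at zero velocity equals the gravity gradient of V", {
  set.seed(7)
  for (model in models) {
    n <- model$dof
    q <- runif(n, -0.8, 0.8)
    gradV <- vapply(seq_len(n), function(i) {
      e <- numeric(n); e[i] <- 1e-6
      (energies(model, q + e, numeric(n))[["V"]] -
         energies(model, q - e, numeric(n))[["V"]]) / 2e-6
    }, numeric(1))
    expect_equal(bias_forces(model, q, numeric(n)), gradV,
                 tolerance = 1e-5)
  }
})

test_that("velocity-dependent bias scales quadratically with qdot", {
  set.seed(8)
  for (model in models) {
    st <- random_state(model)
    g <- bias_forces(model, st$q, numeric(model$dof))
    c1 <- bias_forces(model, st$q, st$qdot) - g
    c2 <- bias_forces(model, st$q, 3 * st$qdot) - g
    expect_equal(c2, 9 * c1, tolerance = 1e-8)
  }
})

test_that("M qddot + C matches the finite-difference Euler-Lagrange
           oracle at random states", {
  set.seed(11)
  for (model in models) {
    for (i in 1:25) {
      st <- random_state(model)
      qddot <- runif(model$dof, -3, 3)
      lhs <- as.numeric(mass_matrix(model, st$q) %*% qddot) +
        bias_forces(model, st$q, st$qdot)
      rhs <- el_oracle(model, st$q, st$qdot, qddot)
      expect_equal(lhs, rhs, tolerance = 1e-6)
    }
  }
})

test_that("push maps through the upper-body CoM Jacobian", {
  model <- models$active
  expect_equal(generalized_push(model, c(0, 0, 0), 0), c(0, 0, 0))
  # upright lever arms: CoM height above ankle and above hip
  gp <- generalized_push(model, c(0, 0, 0), 70)
  expect_equal(gp, c(70 * 1.3, 70 * 0.3, 0))
  # the arm entry is exactly zero at every configuration
  set.seed(13)
  for (i in 1:20) {
    q <- runif(3, -1, 1)
    expect_identical(generalized_push(model, q, 55)[3], 0)
  }
  # injected power equals F * vx of the upper-body CoM segment
  q <- c(0.2, -0.1, 0.4); qd <- c(0.3, 0.5, -0.2)
  p_gen <- sum(generalized_push(model, q, 70) * qd)
  a <- model$anthropometry
  ub_x <- function(q) {
    a$lower_body$length * sin(q[1]) +
      a$upper_body$com_fraction * a$upper_body$length * sin(q[1] + q[2])
  }
  vx <- (ub_x(q + 1e-7 * qd) - ub_x(q - 1e-7 * qd)) / 2e-7
  expect_equal(p_gen, 70 * vx, tolerance = 1e-6)
})

test_that("passive mode equals active mode with zero arm torque", {
  set.seed(17)
  for (i in 1:10) {
    st <- random_state(models$active)
    tau <- runif(2, -80, 80)
    qdd_p <- forward_dynamics(models$passive, st$q, st$qdot, tau, 40)
    qdd_a <- forward_dynamics(models$active, st$q, st$qdot, c(tau, 0), 40)
    expect_equal(qdd_p, qdd_a, tolerance = 1e-12)
  }
})

test_that("fixed mode equals the active mode reduced by the constraint
           q3 = 0", {
  set.seed(19)
  for (i in 1:10) {
    q2 <- runif(2, -0.8, 0.8)
    qd2 <- runif(2, -2, 2)
    Ma <- mass_matrix(models$active, c(q2, 0))
    Mf <- mass_matrix(models$fixed, q2)
    expect_equal(Mf, Ma[1:2, 1:2], tolerance = 1e-12)
    Ca <- bias_forces(models$active, c(q2, 0), c(qd2, 0))
    Cf <- bias_forces(models$fixed, q2, qd2)
    expect_equal(Cf, Ca[1:2], tolerance = 1e-12)
  }
})

test_that("massless arms make active and fixed trunk dynamics identical", {
  body <- anthropometric_model(
    right_arm = segment_params("right_arm", 1e-9, 0.6),
    left_arm = segment_params("left_arm", 1e-9, 0.6)
  )
  m_active <- build_model(body, "active")
  m_fixed <- build_model(body, "fixed")
  q <- c(0.3, -0.2); qd <- c(0.5, 0.1)
  qdd_a <- forward_dynamics(m_active, c(q, 0), c(qd, 0), c(10, 5, 0), 20)
  qdd_f <- forward_dynamics(m_fixed, q, qd, c(10, 5), 20)
  expect_equal(qdd_a[1:2], qdd_f, tolerance = 1e-6)
})

test_that("energies: T vanishes at rest, V matches stacked CoM heights", {
  model <- models$active
  z <- c(0, 0, 0)
  e <- energies(model, z, z)
  expect_identical(e[["T"]], 0)
  # hand computation: lower 35 kg at 0.6 m, upper 25 kg at 1.4 m, arms
  # 8 kg at 1.4 m, foot 1.3 kg at 0.05 m
  expect_equal(e[["V"]], 9.81 * (35 * 0.6 + 25 * 1.4 + 8 * 1.4 +
                                   1.3 * 0.05), tolerance = 1e-10)
  st <- random_state(model)
  expect_equal(energies(model, st$q, st$qdot)[["T"]],
               0.5 * sum(st$qdot * (mass_matrix(model, st$q) %*% st$qdot)),
               tolerance = 1e-10)
})

test_that("whole-body CoM is zeroed at upright and moves with lean", {
  for (model in models) {
    n <- model$dof
    com0 <- whole_body_com(model, numeric(n))
    expect_equal(com0[["x"]], 0, tolerance = 1e-12)
    expect_equal(com0[["vx"]], 0)
    lean <- c(0.2, numeric(n - 1))
    expect_gt(whole_body_com(model, lean)[["x"]], 0)
  }
})

test_that("CoM velocity is the time derivative of CoM position along a
           trajectory", {
  model <- models$active
  f <- discretize(model, 1e-3)
  x <- c(0.05, 0.1, -0.3, 0.2, -0.1, 0.4)
  tau <- c(5, -3, 1)
  xs <- list(x)
  for (i in 1:200) xs[[i + 1]] <- f(xs[[i]], tau)
  xpos <- vapply(xs, function(s)
    whole_body_com(model, s[1:3], s[4:6])[["x"]], numeric(1))
  vx <- vapply(xs, function(s)
    whole_body_com(model, s[1:3], s[4:6])[["vx"]], numeric(1))
  mid <- 2:200
  fd <- (xpos[mid + 1] - xpos[mid - 1]) / (2e-3)
  expect_equal(vx[mid], fd, tolerance = 1e-4)
})

test_that("unforced simulation conserves total energy at RK4 order", {
  model <- models$active
  x0 <- c(0.05, 0.1, -0.2, 0, 0, 0)
  tau0 <- c(0, 0, 0)
  drift <- function(dt) {
    f <- discretize(model, dt)
    x <- x0
    for (i in seq_len(round(1 / dt))) x <- f(x, tau0)
    e0 <- sum(energies(model, x0[1:3], x0[4:6]))
    e1 <- sum(energies(model, x[1:3], x[4:6]))
    abs(e1 - e0)
  }
  d1 <- drift(0.01)
  d2 <- drift(0.005)
  # fourth-order integrator: halving dt divides the energy error by ~16
  expect_gt(d1 / d2, 8)
  expect_lt(d1 / d2, 40)
  expect_lt(d2, 1e-2)
})

test_that("upright standing is open-loop unstable", {
  for (model in models) {
    n <- model$dof
    nu <- model$n_torque
    f <- discretize(model, 0.01)
    A <- matrix(0, 2 * n, 2 * n)
    for (i in seq_len(2 * n)) {
      e <- numeric(2 * n); e[i] <- 1e-6
      A[, i] <- (f(e, numeric(nu)) - f(-e, numeric(nu))) / 2e-6
    }
    # discrete eigenvalue outside the unit circle <=> positive real part
    # of the continuous-time linearisation
    expect_gt(max(Mod(eigen(A, only.values = TRUE)$values)), 1)
  }
})
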