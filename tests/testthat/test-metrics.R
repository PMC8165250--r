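# Metrics are defined on plain trajectory data frames, so hand-built
# fixtures with known answers exercise every formula.

make_traj <- function(t, q, qdot = NULL, tau = NULL, arm_mode = "active",
                      recovery_time = NA_real_) {
  n <- ncol(q)
  if (is.null(qdot)) qdot <- matrix(0, length(t), n)
  nu <- if (arm_mode == "active") 3L else 2L
  if (is.null(tau)) tau <- matrix(0, length(t), nu)
  df <- data.frame(t = t)
  for (i in seq_len(n)) df[[paste0("q", i)]] <- q[, i]
  for (i in seq_len(n)) df[[paste0("dq", i)]] <- qdot[, i]
  for (i in seq_len(ncol(tau))) df[[paste0("tau", i)]] <- tau[, i]
  structure(df, class = c("closed_loop_trajectory", "data.frame"),
            dof = n, n_torque = ncol(tau), arm_mode = arm_mode,
            dt = if (length(t) > 1) t[2] - t[1] else 1,
            recovery_time = recovery_time, push_start = 0,
            termination = if (is.na(recovery_time)) "timeout"
                          else "recovered")
}

test_that("total RMS deviation follows the printed ankle-hip formula", {
  tr0 <- make_traj(0:3, matrix(0, 4, 3))
  expect_equal(total_rms_deviation(tr0), 0)
  # constant angles: formula collapses to sqrt(a^2 + b^2)
  trc <- make_traj(0:4, cbind(0.3, -0.4, 99))
  expect_equal(total_rms_deviation(trc), 0.5)
  # two samples, hand arithmetic: sqrt((0.3^2 + 0.4^2 + 0 + 0) / 2)
  tr2 <- make_traj(0:1, rbind(c(0.3, 0.4, 0), c(0, 0, 0)))
  expect_equal(total_rms_deviation(tr2), sqrt(0.125))
  expect_equal(total_rms_deviation(tr2), 0.35355, tolerance = 1e-4)
  # the arm angle never enters, even in active mode
  tr3 <- make_traj(0:1, rbind(c(0.3, 0.4, 5), c(0, 0, -5)))
  expect_equal(total_rms_deviation(tr3), sqrt(0.125))
})

test_that("RMS windows stop at the recovery time", {
  q <- rbind(c(0.3, 0.4, 0), c(0, 0, 0), c(9, 9, 9), c(9, 9, 9))
  tr <- make_traj(0:3, q, recovery_time = 1)
  expect_equal(total_rms_deviation(tr), sqrt(0.125))
})

test_that("arm RMS deviation is the q3 analogue and absent for fixed
           arms", {
  expect_equal(arm_rms_deviation(make_traj(0:3, matrix(0, 4, 3))), 0)
  trc <- make_traj(0:4, cbind(0, 0, -0.25))
  expect_equal(arm_rms_deviation(trc), 0.25)
  trf <- make_traj(0:4, matrix(0.3, 5, 2), arm_mode = "fixed")
  expect_true(is.na(arm_rms_deviation(trf)))
})

test_that("energy consumption integrates absolute mechanical power", {
  # constant tau = 1 N m against qdot = 1 rad/s for 2 s -> 2 J
  tr <- make_traj(seq(0, 2, 0.5), matrix(0, 5, 3),
                  qdot = matrix(rep(c(1, 0, 0), each = 5), 5, 3),
                  tau = matrix(rep(c(1, 0, 0), each = 5), 5, 3))
  en <- energy_consumption(tr)
  expect_equal(unname(en$per_joint), c(2, 0, 0))
  expect_equal(en$TEC, 2)
  expect_equal(en$AEC, 0)
  # sign convention: negative work costs the same
  tr2 <- make_traj(seq(0, 2, 0.5), matrix(0, 5, 3),
                   qdot = matrix(rep(c(-1, 0, 1), each = 5), 5, 3),
                   tau = matrix(rep(c(1, 0, 2), each = 5), 5, 3))
  en2 <- energy_consumption(tr2)
  expect_equal(unname(en2$per_joint), c(2, 0, 4))
  expect_equal(en2$AEC, 4)
  expect_equal(en2$TEC, 6)
  # positive-work-only option discards eccentric work
  en3 <- energy_consumption(tr2, positive_work_only = TRUE)
  expect_equal(unname(en3$per_joint), c(0, 0, 4))
  # zero torques cost nothing
  trz <- make_traj(0:5, matrix(0.2, 6, 3),
                   qdot = matrix(1, 6, 3))
  expect_equal(energy_consumption(trz)$TEC, 0)
})

test_that("passive arms have zero AEC; fixed arms none", {
  trp <- make_traj(0:2, matrix(0.1, 3, 3), arm_mode = "passive")
  expect_equal(energy_consumption(trp)$AEC, 0)
  trf <- make_traj(0:2, matrix(0.1, 3, 2), arm_mode = "fixed")
  expect_true(is.na(energy_consumption(trf)$AEC))
})

test_that("joint correlation is Pearson on the recovery window", {
  t <- 0:20
  s <- sin(t / 3)
  tr <- make_traj(t, cbind(s, s, -s))
  expect_equal(joint_correlation(tr, "ankle_hip"), 1)
  expect_equal(joint_correlation(tr, "hip_arm"), -1)
  # zero-variance series is undefined
  trz <- make_traj(t, cbind(s, rep(0, 21), s))
  expect_true(is.na(joint_correlation(trz, "ankle_hip")))
  # fixed arms have no hip-arm pair
  trf <- make_traj(t, cbind(s, s), arm_mode = "fixed")
  expect_true(is.na(joint_correlation(trf, "hip_arm")))
})

test_that("phase portrait extracts the angle-velocity pair", {
  t <- 0:10
  q <- cbind(sin(t), cos(t), t / 10)
  qd <- cbind(cos(t), -sin(t), rep(0.1, 11))
  tr <- make_traj(t, q, qd)
  pp <- phase_portrait(tr, "hip")
  expect_equal(pp$angle, cos(t))
  expect_equal(pp$velocity, -sin(t))
  expect_error(phase_portrait(make_traj(t, q[, 1:2],
                                        arm_mode = "fixed"), "arm"),
               "arm")
})

test_that("balance_metrics bundles all indexes consistently", {
  t <- seq(0, 2, 0.5)
  q <- cbind(c(0.2, 0.1, 0, 0, 0), c(0.1, 0.05, 0, 0, 0),
             c(-0.1, -0.05, 0, 0, 0))
  tr <- make_traj(t, q, recovery_time = 2)
  m <- balance_metrics(tr)
  expect_s3_class(m, "balance_metrics")
  expect_equal(m$total_rms, total_rms_deviation(tr))
  expect_equal(m$arm_rms, arm_rms_deviation(tr))
  expect_true(m$TEC >= m$AEC)
  expect_true(abs(m$corr_ankle_hip) <= 1)
})

test_that("detect_recovery defers past transient entries into tolerance", {
  crit <- recovery_criterion(angle_tol = 0.01, vel_tol = 0.02, dwell = 2)
  # enters at t=2, leaves at t=4, re-enters at t=6 for good
  q1 <- c(0.5, 0.5, 0, 0, 0.5, 0.5, 0, 0, 0, 0, 0)
  tr <- make_traj(0:10, cbind(q1, 0, 0))
  expect_equal(detect_recovery(tr, crit), 6)
  # identically at equilibrium -> 0
  tr0 <- make_traj(0:10, matrix(0, 11, 3))
  expect_equal(detect_recovery(tr0, crit), 0)
  # never inside -> NA
  trn <- make_traj(0:10, matrix(0.5, 11, 3))
  expect_true(is.na(detect_recovery(trn, crit)))
  # dwell window must be fully observed
  tre <- make_traj(0:1, matrix(0, 2, 3))
  expect_true(is.na(detect_recovery(tre, crit)))
})
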