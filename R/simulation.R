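#' Push protocol
#'
#' A constant horizontal force applied at the upper-body centre of mass for
#' a fixed duration: the standard perturbation is a 1 s push, with up to
#' 4 s of simulation for the recovery to complete (raise `max_sim_time` for
#' slow recoveries, e.g. under a weakened ankle).
#'
#' @param force signed push force in N (positive = forward).
#' @param push_duration push duration in s (default 1).
#' @param max_sim_time simulation cap in s (default 4).
#' @param start_time push onset in s (default 0).
#' @return an object of class `push_protocol`.
#' @export
push_protocol <- function(force, push_duration = 1, max_sim_time = 4,
                          start_time = 0) {
  stopifnot(is.finite(force), push_duration > 0,
            max_sim_time >= push_duration, start_time >= 0)
  structure(list(force = force, push_duration = push_duration,
                 max_sim_time = max_sim_time, start_time = start_time),
            class = "push_protocol")
}

push_at <- function(push, t) {
  ifelse(t >= push$start_time &
           t < push$start_time + push$push_duration, push$force, 0)
}

#' Recovery criterion
#'
#' The model counts as recovered at the earliest time from which every
#' joint angle and velocity stays inside tolerance for a full dwell
#' window.
#'
#' @param angle_tol angle tolerance in rad.
#' @param vel_tol velocity tolerance in rad/s.
#' @param dwell time the state must remain inside tolerance, s.
#' @return an object of class `recovery_criterion`.
#' @export
recovery_criterion <- function(angle_tol = 0.01, vel_tol = 0.02,
                               dwell = 0.5) {
  stopifnot(angle_tol > 0, vel_tol > 0, dwell >= 0)
  structure(list(angle_tol = angle_tol, vel_tol = vel_tol, dwell = dwell),
            class = "recovery_criterion")
}

traj_inside <- function(traj, criterion) {
  n <- attr(traj, "dof")
  q <- as.matrix(traj[paste0("q", seq_len(n))])
  qd <- as.matrix(traj[paste0("dq", seq_len(n))])
  apply(abs(q) <= criterion$angle_tol, 1L, all) &
    apply(abs(qd) <= criterion$vel_tol, 1L, all)
}

#' Closed-loop balance recovery simulation
#'
#' Runs the receding-horizon controller against the plant (the same RK4
#' discretisation as the controller's internal predictor): at every
#' sampling instant a finite-horizon problem is solved at the current
#' state, the first torque sample is applied, and the state advances one
#' step with the scheduled push.  The run terminates at recovery (see
#' [recovery_criterion()]), at the simulation cap (`timeout`), or when the
#' controller reports an infeasible problem (`no_solution`).
#'
#' @param model a [build_model()] object.
#' @param config an [nmpc_config()].
#' @param push a [push_protocol()].
#' @param criterion a [recovery_criterion()].
#' @param bounds an [nmpc_bounds()]; defaults to the arm condition's
#'   standard boxes.
#' @param x0 initial state, default upright equilibrium.
#' @return a `closed_loop_trajectory`: a data frame with one row per
#'   sample and columns `t`, `q*`, `dq*`, `tau*`, `push`, `com_x`,
#'   `com_vx`, carrying as attributes `termination` (`"recovered"`,
#'   `"timeout"` or `"no_solution"`), `recovery_time`, `dof`, `n_torque`,
#'   `arm_mode`, `dt` and the resolved configuration.  Torques are those
#'   applied over `[t, t + dt)`; the final row's torques are `NA`.
#' @export
simulate_closed_loop <- function(model, config = nmpc_config(),
                                 push = push_protocol(0),
                                 criterion = recovery_criterion(),
                                 bounds = default_bounds(model$arm_mode),
                                 x0 = NULL) {
  n <- model$dof
  nu <- model$n_torque
  n2 <- 2L * n
  dt <- config$dt
  if (is.null(x0)) x0 <- numeric(n2)
  stopifnot(length(x0) == n2)

  n_steps <- ceiling(push$max_sim_time / dt - 1e-9)
  dwell_steps <- ceiling(criterion$dwell / dt - 1e-9)
  ctrl <- nmpc_controller(model, config, bounds)

  X <- matrix(NA_real_, n2, n_steps + 1L)
  TA <- matrix(NA_real_, nu, n_steps + 1L)
  PU <- numeric(n_steps + 1L)
  X[, 1L] <- x0
  inside <- logical(n_steps + 1L)
  is_inside <- function(x) {
    all(abs(x[seq_len(n)]) <= criterion$angle_tol) &&
      all(abs(x[n + seq_len(n)]) <= criterion$vel_tol)
  }
  inside[1L] <- is_inside(x0)
  termination <- "timeout"
  run_len <- if (inside[1L]) 1L else 0L
  k_end <- n_steps

  for (k in seq_len(n_steps)) {
    t_k <- (k - 1L) * dt
    preview <- if (config$push_preview) {
      push_at(push, t_k + dt * (seq_len(config$horizon) - 1L))
    } else {
      numeric(config$horizon)  # unmodelled disturbance: reactive control
    }
    step <- mpc_step(ctrl, X[, k], preview)
    if (step$solution$status == "infeasible") {
      termination <- "no_solution"
      k_end <- k - 1L
      break
    }
    TA[, k] <- step$tau
    PU[k] <- push_at(push, t_k)
    X[, k + 1L] <- cpp_rk4_step(model$par, X[, k], step$tau, PU[k], dt)
    inside[k + 1L] <- is_inside(X[, k + 1L])
    run_len <- if (inside[k + 1L]) run_len + 1L else 0L
    if (run_len >= dwell_steps + 1L) {
      termination <- "recovered"
      k_end <- k
      break
    }
  }

  keep <- seq_len(k_end + 1L)
  tgrid <- (keep - 1L) * dt
  com <- t(vapply(keep, function(k) {
    cpp_com(model$par, X[seq_len(n), k], X[n + seq_len(n), k])
  }, numeric(3)))
  traj <- data.frame(t = tgrid)
  for (i in seq_len(n)) traj[[paste0("q", i)]] <- X[i, keep]
  for (i in seq_len(n)) traj[[paste0("dq", i)]] <- X[n + i, keep]
  for (i in seq_len(nu)) traj[[paste0("tau", i)]] <- TA[i, keep]
  traj$push <- PU[keep]
  traj$com_x <- com[, 1L]
  traj$com_vx <- com[, 3L]

  recovery_time <- NA_real_
  if (termination == "recovered") {
    recovery_time <- (k_end + 1L - (dwell_steps + 1L)) * dt
  }
  structure(traj,
            class = c("closed_loop_trajectory", "data.frame"),
            termination = termination, recovery_time = recovery_time,
            dof = n, n_torque = nu, arm_mode = model$arm_mode, dt = dt,
            force = push$force, push_start = push$start_time,
            criterion = criterion, config = config, bounds = bounds)
}

#' @export
print.closed_loop_trajectory <- function(x, ...) {
  cat(sprintf(
    "Closed-loop trajectory (%s arms, push %g N): %d samples, %s",
    attr(x, "arm_mode"), attr(x, "force"), nrow(x),
    attr(x, "termination")))
  if (!is.na(attr(x, "recovery_time")))
    cat(sprintf(", recovery at %.2f s", attr(x, "recovery_time")))
  cat("\n")
  invisible(x)
}

#' Detect the recovery time of a trajectory
#'
#' Earliest time `t` such that every sample in `[t, t + dwell]` (the
#' window fully observed) has all joint angles and velocities inside
#' tolerance; `NA` if no such time exists.  An early excursion into the
#' tolerance band that is left again before the dwell elapses defers
#' detection to the later, permanent entry.
#'
#' @param traj a `closed_loop_trajectory` (or any data frame with the same
#'   columns and `dof` attribute).
#' @param criterion a [recovery_criterion()].
#' @return recovery time in s, or `NA`.
#' @export
detect_recovery <- function(traj, criterion = recovery_criterion()) {
  inside <- traj_inside(traj, criterion)
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- stats::median(diff(traj$t))
  dwell_steps <- ceiling(criterion$dwell / dt - 1e-9)
  ns <- length(inside)
  for (k in seq_len(ns)) {
    if (k + dwell_steps > ns) return(NA_real_)
    if (all(inside[k:(k + dwell_steps)])) return(traj$t[k])
  }
  NA_real_
}
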