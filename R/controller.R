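#' Torque and state box constraints
#'
#' @param tau_min,tau_max per-joint torque bounds (N m), length equal to
#'   the number of actuated joints.
#' @param x_min,x_max per-state bounds (angles in rad, velocities in
#'   rad/s), length `2 * dof`; use `-Inf`/`Inf` for unbounded entries.
#' @return an object of class `nmpc_bounds`.
#' @seealso [default_bounds()]
#' @export
nmpc_bounds <- function(tau_min, tau_max, x_min, x_max) {
  if (any(tau_min > tau_max) || any(x_min > x_max))
    stop("bounds require min <= max elementwise", call. = FALSE)
  structure(list(tau_min = as.numeric(tau_min),
                 tau_max = as.numeric(tau_max),
                 x_min = as.numeric(x_min), x_max = as.numeric(x_max)),
            class = "nmpc_bounds")
}

#' Default joint-torque and state boxes per arm condition
#'
#' Torque limits: ankle +/-120, hip +/-500 and (active arms only) arm
#' +/-200 N m.  Angle limits: ankle \[-0.2, 0.4\], hip \[-0.35, 1.3\] and
#' (three-dof conditions) arm \[-2.5, 0.5\] rad; the arm box is asymmetric
#' because a large backward-upward arm rotation is anatomically available
#' while the forward swing is short.  Angular velocities are unbounded.
#'
#' @param arm_mode `"active"`, `"passive"` or `"fixed"`.
#' @return an [nmpc_bounds()] object: 6 state bounds for active/passive,
#'   4 for fixed arms.
#' @export
default_bounds <- function(arm_mode = c("active", "passive", "fixed")) {
  arm_mode <- match.arg(arm_mode)
  ang_lo <- c(-0.2, -0.35, -2.5)
  ang_hi <- c(0.4, 1.3, 0.5)
  switch(arm_mode,
    active = nmpc_bounds(c(-120, -500, -200), c(120, 500, 200),
                         c(ang_lo, rep(-Inf, 3)), c(ang_hi, rep(Inf, 3))),
    passive = nmpc_bounds(c(-120, -500), c(120, 500),
                          c(ang_lo, rep(-Inf, 3)), c(ang_hi, rep(Inf, 3))),
    fixed = nmpc_bounds(c(-120, -500), c(120, 500),
                        c(ang_lo[1:2], rep(-Inf, 2)),
                        c(ang_hi[1:2], rep(Inf, 2)))
  )
}

#' NMPC configuration
#'
#' The quadratic weighting follows the published structure -- `Q`, `R`,
#' `Qf` diagonal with a state-to-input ratio of `10^3` and a terminal
#' weight two orders of magnitude above the stage weight -- while the
#' absolute scales, the sampling period and the horizon are the package's
#' calibration (the published description fixes only the ratios; see the
#' methods vignette for how the defaults were chosen against the reported
#' balance studies).  Per-joint stage weights: ankle and hip angle
#' deviations carry the full scale, the arm angle 1% of it (the arm is a
#' momentum reservoir, not a posture variable), and velocities one tenth
#' of the corresponding angle weight.
#'
#' @param dt controller sampling period in s.
#' @param horizon prediction horizon `Nt` in steps (the preview covers
#'   `horizon * dt` seconds).
#' @param q_angle per-joint stage weights on angle deviations (ankle,
#'   hip, arm); a scalar is recycled.
#' @param q_vel per-joint stage weights on angular velocities; a scalar is
#'   recycled.
#' @param r_scale per-joint input weights (a scalar is recycled).
#' @param qf_factor terminal weight `Qf` as a multiple of the stage `Q`.
#' @param push_preview if `TRUE` the controller's predictor is given the
#'   true future push profile inside its horizon; if `FALSE` (default) the
#'   push is an unmodelled disturbance -- the controller reacts purely to
#'   the measured state, which is how the perturbation studies are run.
#' @param solver list of solver controls: `maxit` (iterated-LQR iteration
#'   cap per subproblem) and `tol` (relative cost-decrease stop); `mu0`,
#'   `mu_growth`, `outer_max`, `feas_tol`, `infeas_tol` for the
#'   augmented-Lagrangian treatment of the joint-angle boxes; `fd_step`
#'   for the central-difference dynamics Jacobians.
#' @return an object of class `nmpc_config`.
#' @export
nmpc_config <- function(dt = 0.035, horizon = 29L,
                        q_angle = c(7e5, 7e5, 7e3),
                        q_vel = c(7e4, 7e4, 7e2),
                        r_scale = 1, qf_factor = 100,
                        push_preview = FALSE, solver = list()) {
  stopifnot(dt > 0, horizon >= 1, all(q_angle >= 0), all(q_vel >= 0),
            all(r_scale > 0), qf_factor > 0)
  q_angle <- rep_len(as.numeric(q_angle), 3L)
  q_vel <- rep_len(as.numeric(q_vel), 3L)
  sdef <- list(maxit = 250L, tol = 1e-9, mu0 = 1e3, mu_growth = 10,
               outer_max = 15L, feas_tol = 1e-7, infeas_tol = 1e-3,
               fd_step = 1e-5)
  solver <- modifyList(sdef, solver)
  structure(list(dt = dt, horizon = as.integer(horizon),
                 q_angle = q_angle, q_vel = q_vel,
                 r_scale = as.numeric(r_scale), qf_factor = qf_factor,
                 push_preview = isTRUE(push_preview), solver = solver),
            class = "nmpc_config")
}

config_weights <- function(model, config) {
  n <- model$dof
  qw <- c(config$q_angle[seq_len(n)], config$q_vel[seq_len(n)])
  list(qw = qw,
       rw = rep_len(config$r_scale, model$n_torque),
       qfw = config$qf_factor * qw)
}

#' Stage cost of the optimal control problem
#'
#' `l(x, tau) = (x' Q x + tau' R tau) / 2` with diagonal `Q`, `R` built
#' from the configured scales.
#'
#' @param x state vector `(q, qdot)`.
#' @param tau torque vector.
#' @param config an [nmpc_config()].
#' @param model the [build_model()] the dimensions refer to.
#' @return non-negative scalar.
#' @export
stage_cost <- function(x, tau, config, model) {
  w <- config_weights(model, config)
  if (length(x) != 2L * model$dof || length(tau) != model$n_torque)
    stop("stage_cost: dimension mismatch", call. = FALSE)
  0.5 * (sum(w$qw * x^2) + sum(w$rw * tau^2))
}

#' Terminal cost of the optimal control problem
#'
#' `Vf(x) = x' Qf x / 2`.
#'
#' @inheritParams stage_cost
#' @return non-negative scalar.
#' @export
terminal_cost <- function(x, config, model) {
  w <- config_weights(model, config)
  if (length(x) != 2L * model$dof)
    stop("terminal_cost: dimension mismatch", call. = FALSE)
  0.5 * sum(w$qfw * x^2)
}

#' One-step discrete transition map
#'
#' Fixed-step fourth-order Runge-Kutta discretisation of the forward
#' dynamics.  The same map serves as the controller's internal predictor
#' and as the simulated plant, so prediction is exact up to solver
#' tolerance.
#'
#' @param model a [build_model()] object.
#' @param dt step in s.
#' @return a function `f(x, tau, push = 0)` mapping state `(q, qdot)` to
#'   the state one step later.
#' @export
discretize <- function(model, dt) {
  stopifnot(dt > 0)
  force(model)
  function(x, tau, push = 0) {
    cpp_rk4_step(model$par, as.numeric(x), as.numeric(tau), push, dt)
  }
}

#' Solve the finite-horizon constrained optimal control problem
#'
#' Minimises the quadratic stage-plus-terminal cost over the horizon
#' subject to the RK4-discretised dynamics, the torque boxes and the
#' joint-angle boxes.  The solver is an iterated LQR: each iteration
#' linearises the dynamics along the current rollout, performs a Riccati
#' backward sweep in which the feedforward torque step solves a small box
#' QP against the torque limits (projected Newton), and rolls forward
#' with backtracking line search under time-varying state feedback.
#' Joint-angle boxes on the predicted samples `k = 1..Nt` are enforced by
#' an augmented-Lagrangian outer loop (the `k = 0` sample is the
#' measurement and is exempt).  The problem is declared infeasible -- no
#' dynamically consistent trajectory can stay inside the angle boxes --
#' when, after multiplier updates and penalty growth, the worst box
#' violation still exceeds `solver$infeas_tol`.
#'
#' @param model a [build_model()] object.
#' @param x0 initial state `(q, qdot)`, length `2 * dof`.
#' @param push_preview scalar or length-`horizon` vector of previewed push
#'   forces (N) over the horizon.
#' @param config an [nmpc_config()].
#' @param bounds an [nmpc_bounds()]; defaults to [default_bounds()] for the
#'   model's arm condition.
#' @param warm_start optional warm start: the `warm` element of a previous
#'   `ocp_solution` (torque sequence, multipliers and penalty weight,
#'   already shifted by [mpc_step()]).
#' @return a list of class `ocp_solution`: `tau_opt` (`n_torque x Nt`
#'   matrix), `x_opt` (`2 dof x (Nt+1)` matrix of predicted states,
#'   measurement first), `cost` (quadratic objective value), `status`
#'   (`"optimal"`, `"max_iter"` or `"infeasible"`), `max_violation`
#'   (worst joint-angle box violation over the horizon, rad),
#'   `outer_iterations`, `ilqr_iterations`, and `warm` (state for
#'   warm-starting the next solve).
#' @export
solve_ocp <- function(model, x0, push_preview = 0,
                      config = nmpc_config(),
                      bounds = default_bounds(model$arm_mode),
                      warm_start = NULL) {
  Nt <- config$horizon
  nu <- model$n_torque
  n2 <- 2L * model$dof
  if (length(x0) != n2)
    stop("x0 must have length ", n2, call. = FALSE)
  push <- rep_len(as.numeric(push_preview), Nt)
  w <- config_weights(model, config)
  s <- config$solver

  U0 <- if (is.null(warm_start)) matrix(0, nu, Nt) else warm_start$U
  lamlo <- if (is.null(warm_start)) matrix(0, n2, Nt) else warm_start$lamlo
  lamhi <- if (is.null(warm_start)) matrix(0, n2, Nt) else warm_start$lamhi
  mu <- if (is.null(warm_start)) s$mu0 else warm_start$mu

  run <- function(U0, lamlo, lamhi, mu) {
    cpp_ocp_solve(model$par, x0, push, config$dt, w$qw, w$rw, w$qfw,
                  bounds$tau_min, bounds$tau_max, bounds$x_min,
                  bounds$x_max, U0, lamlo, lamhi, mu, s$mu_growth,
                  s$outer_max, s$feas_tol, s$infeas_tol, s$maxit, s$tol,
                  s$fd_step)
  }
  res <- run(U0, lamlo, lamhi, mu)
  restarted <- FALSE
  if (res$status != "optimal" && !is.null(warm_start)) {
    # restoration attempt from a cold start before declaring failure
    restarted <- TRUE
    res2 <- run(matrix(0, nu, Nt), matrix(0, n2, Nt), matrix(0, n2, Nt),
                s$mu0)
    if (res2$violation < res$violation) res <- res2
  }
  structure(list(tau_opt = res$tau, x_opt = res$X, cost = res$cost,
                 status = res$status, max_violation = res$violation,
                 outer_iterations = res$outer_iterations,
                 ilqr_iterations = res$ilqr_iterations,
                 restarted = restarted,
                 warm = list(U = res$tau, lamlo = res$lamlo,
                             lamhi = res$lamhi, mu = res$mu)),
            class = "ocp_solution")
}

#' Create a receding-horizon controller
#'
#' Holds the model, configuration and bounds plus the warm-start state
#' (the previous optimal torque sequence, shifted by one step between
#' calls).
#'
#' @inheritParams solve_ocp
#' @return an object of class `nmpc_controller`.
#' @export
nmpc_controller <- function(model, config = nmpc_config(),
                            bounds = default_bounds(model$arm_mode)) {
  if (length(bounds$tau_min) != model$n_torque ||
      length(bounds$x_min) != 2L * model$dof)
    stop("bounds dimensions do not match the model's arm condition",
         call. = FALSE)
  ctrl <- new.env(parent = emptyenv())
  ctrl$model <- model
  ctrl$config <- config
  ctrl$bounds <- bounds
  ctrl$prev <- NULL
  class(ctrl) <- "nmpc_controller"
  ctrl
}

#' One receding-horizon control step
#'
#' Solves a fresh finite-horizon problem at the measured state (using the
#' shifted previous solution as warm start) and returns the first torque
#' sample of the optimal sequence; the rest of the sequence is discarded,
#' and the optimisation is repeated at the next sampling instant.
#'
#' @param ctrl an [nmpc_controller()].
#' @param x_measured current state `(q, qdot)`.
#' @param push_preview scalar or length-`horizon` previewed push (N).
#' @return list with `tau` (applied torque vector) and `solution` (the full
#'   [solve_ocp()] result; its `status` propagates controller
#'   infeasibility).
#' @export
mpc_step <- function(ctrl, x_measured, push_preview = 0) {
  warm <- NULL
  if (!is.null(ctrl$prev)) {
    # shift torque samples and multipliers one step forward, duplicating
    # the last sample; keep the adapted penalty weight
    p <- ctrl$prev
    shift <- function(m) cbind(m[, -1L, drop = FALSE],
                               m[, ncol(m), drop = FALSE])
    warm <- list(U = shift(p$U), lamlo = shift(p$lamlo),
                 lamhi = shift(p$lamhi), mu = p$mu)
  }
  sol <- solve_ocp(ctrl$model, x_measured, push_preview, ctrl$config,
                   ctrl$bounds, warm_start = warm)
  ctrl$prev <- if (sol$status == "optimal") sol$warm else NULL
  list(tau = sol$tau_opt[, 1L], solution = sol)
}

#' Finite-horizon LQR on the linearised model
#'
#' Linearises the discrete one-step map about the upright equilibrium by
#' central differences and runs the discrete-time Riccati recursion over
#' the configured horizon with the configured weights.  Near the origin,
#' with no active constraints, the NMPC first input converges to
#' `-K[[1]] x0`.
#'
#' @inheritParams solve_ocp
#' @return list with `A`, `B` (linearised dynamics), `K` (list of feedback
#'   gain matrices, `K[[1]]` applying at the first step) and `P1` (the
#'   first cost-to-go matrix).
#' @export
finite_horizon_lqr <- function(model, config = nmpc_config()) {
  n2 <- 2L * model$dof
  nu <- model$n_torque
  f <- discretize(model, config$dt)
  h <- 1e-6
  A <- matrix(0, n2, n2)
  B <- matrix(0, n2, nu)
  for (i in seq_len(n2)) {
    e <- numeric(n2); e[i] <- h
    A[, i] <- (f(e, numeric(nu)) - f(-e, numeric(nu))) / (2 * h)
  }
  for (i in seq_len(nu)) {
    e <- numeric(nu); e[i] <- h
    B[, i] <- (f(numeric(n2), e) - f(numeric(n2), -e)) / (2 * h)
  }
  w <- config_weights(model, config)
  Q <- diag(w$qw, n2)
  R <- diag(w$rw, nu)
  P <- diag(w$qfw, n2)
  K <- vector("list", config$horizon)
  for (k in rev(seq_len(config$horizon))) {
    G <- R + t(B) %*% P %*% B
    Kk <- solve(G, t(B) %*% P %*% A)
    P <- Q + t(A) %*% P %*% A - t(A) %*% P %*% B %*% Kk
    K[[k]] <- Kk
  }
  list(A = A, B = B, K = K, P1 = P)
}
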