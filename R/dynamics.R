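#' Build the standing-model dynamics for one arm condition
#'
#' Assembles the equations of motion of the three-joint, five-link
#' sagittal-plane model from Lagrangian mechanics.  The foot is welded to
#' the ground; the lower body pivots about the ankle, the upper body about
#' the hip, and the two arms -- which share a single shoulder joint and a
#' common angle -- hang from the top of the upper body and are lumped into
#' one equivalent link.
#'
#' Angle conventions (used consistently throughout the package):
#' * `q1`: ankle angle of the lower body from the vertical, forward lean
#'   positive (forward = direction of a positive push, +x).
#' * `q2`: hip flexion of the upper body relative to the lower body.
#' * `q3`: arm rotation relative to the upper body; the arms hang straight
#'   down at `q3 = 0` and swing forward for `q3 > 0`.
#' `q = 0` is the upright equilibrium.
#'
#' Arm conditions:
#' * `"active"`: 3 dof, all three joints actuated.
#' * `"passive"`: 3 dof, the arm joint is unactuated (zero torque).
#' * `"fixed"`: 2 dof, the arms are rigidly locked to the upper body at
#'   `q3 = 0`.
#'
#' @param anthropometry an [anthropometric_model()].
#' @param arm_mode `"active"`, `"passive"` or `"fixed"`.
#' @return an object of class `balance_model` with elements `anthropometry`,
#'   `arm_mode`, `dof`, `n_torque` and the internal parameter pack used by
#'   the compiled evaluators.
#' @examples
#' mdl <- build_model(anthropometric_model(), "active")
#' mass_matrix(mdl, c(0, 0, 0))
#' @export
build_model <- function(anthropometry = anthropometric_model(),
                        arm_mode = c("active", "passive", "fixed")) {
  arm_mode <- match.arg(arm_mode)
  a <- anthropometry
  stopifnot(inherits(a, "anthropometric_model"))
  if (!isTRUE(all.equal(a$right_arm$com_fraction, a$left_arm$com_fraction)))
    stop("lumped arms require equal com_fraction for both arms",
         call. = FALSE)

  n <- if (arm_mode == "fixed") 2L else 3L
  nu <- if (arm_mode == "active") 3L else 2L
  mode_code <- match(arm_mode, c("active", "passive", "fixed")) - 1L

  L1 <- a$lower_body$length; c1 <- a$lower_body$com_fraction
  L2 <- a$upper_body$length; c2 <- a$upper_body$com_fraction
  La <- a$right_arm$length;  ca <- a$right_arm$com_fraction
  m_arm <- a$right_arm$mass + a$left_arm$mass
  I_arm <- segment_inertia(a$right_arm) + segment_inertia(a$left_arm)

  # CoM term lists over absolute angles phi = phi0 + A q.
  # phi1: lower body from vertical; phi2: upper body from vertical;
  # phi3 = pi - (upper-body angle + q3): the arm hangs downward, so its
  # unit vector (sin, cos) needs the reflected angle (positive q3 swings
  # the arm CoM forward, +x).
  acoef <- rbind(c(c1 * L1, 0,       0),
                 c(L1,      c2 * L2, 0),
                 c(L1,      L2,      ca * La))
  if (n == 3L) {
    Amat <- rbind(c(1, 0, 0), c(1, 1, 0), c(-1, -1, -1))
  } else {
    Amat <- rbind(c(1, 0), c(1, 1), c(-1, -1))
  }
  phi0 <- c(0, 0, pi)

  m_tot <- total_mass(a)
  foot_cx <- a$foot$length / 2            # mid-foot, ankle above the heel
  foot_cz <- a$foot_height / 2
  par <- list(
    mode = mode_code, n = n, nu = nu, g = a$gravity,
    mb = c(a$lower_body$mass, a$upper_body$mass, m_arm),
    Ib = c(segment_inertia(a$lower_body), segment_inertia(a$upper_body),
           I_arm),
    acoef = acoef, Amat = Amat, phi0 = phi0,
    m_tot = m_tot, m_foot = a$foot$mass,
    foot_cx = foot_cx, foot_cz = foot_cz,
    h0 = a$foot_height,
    com_x_off = a$foot$mass * foot_cx / m_tot
  )
  structure(
    list(anthropometry = a, arm_mode = arm_mode, dof = n, n_torque = nu,
         par = par),
    class = "balance_model"
  )
}

#' @export
print.balance_model <- function(x, ...) {
  cat("Standing balance model:", x$arm_mode, "arms,", x$dof,
      "dof,", x$n_torque, "actuated joints\n")
  invisible(x)
}

check_q <- function(model, q) {
  if (length(q) != model$dof)
    stop("q must have length ", model$dof, " for ", model$arm_mode,
         " arms", call. = FALSE)
  as.numeric(q)
}

check_qdot <- function(model, qdot) {
  if (length(qdot) != model$dof)
    stop("qdot must have length ", model$dof, call. = FALSE)
  as.numeric(qdot)
}

#' Joint-space mass matrix
#'
#' @param model a [build_model()] object.
#' @param q joint angles (rad), length `model$dof`.
#' @return the symmetric positive-definite `dof x dof` inertia matrix
#'   (kg m^2).
#' @export
mass_matrix <- function(model, q) {
  cpp_mass_matrix(model$par, check_q(model, q))
}

#' Bias forces: Coriolis, centrifugal and gravity terms
#'
#' Returns the vector `C(q, qdot)` such that the equations of motion read
#' `M(q) qddot + C(q, qdot) = tau_generalized`.  At `qdot = 0` this is the
#' gravity gradient of the potential energy.
#'
#' @inheritParams mass_matrix
#' @param qdot joint velocities (rad/s).
#' @return numeric vector of length `model$dof` (N m).
#' @export
bias_forces <- function(model, q, qdot) {
  cpp_bias(model$par, check_q(model, q), check_qdot(model, qdot))
}

#' Generalized forces of a horizontal push at the upper-body CoM
#'
#' Maps a horizontal (sagittal, anteroposterior) force applied at the
#' centre of mass of the upper-body segment to joint-space generalized
#' forces through the transpose of the point's velocity Jacobian.  The arm
#' entry is identically zero: the upper-body CoM does not move with the arm
#' angle.
#'
#' @inheritParams mass_matrix
#' @param force signed force in N; positive pushes forward (+x).
#' @return numeric vector of length `model$dof` (N m).
#' @export
generalized_push <- function(model, q, force) {
  cpp_push_vec(model$par, check_q(model, q), force)
}

#' Forward dynamics
#'
#' Solves `M(q) qddot = tau + push - C(q, qdot)` for the joint
#' accelerations.  In the passive arm condition `tau` has two entries
#' (ankle, hip) and zero torque is applied at the arm joint.
#'
#' @inheritParams bias_forces
#' @param tau applied joint torques (N m), length `model$n_torque`.
#' @param force horizontal push at the upper-body CoM (N).
#' @return joint accelerations (rad/s^2), length `model$dof`.
#' @export
forward_dynamics <- function(model, q, qdot, tau, force = 0) {
  if (length(tau) != model$n_torque)
    stop("tau must have length ", model$n_torque, " for ", model$arm_mode,
         " arms", call. = FALSE)
  cpp_qdd(model$par, check_q(model, q), check_qdot(model, qdot),
          as.numeric(tau), force)
}

#' Kinetic and potential energy
#'
#' `T = qdot' M(q) qdot / 2`; `V = sum_i m_i g h_i` with segment CoM
#' heights measured from the ground (the welded foot contributes a
#' constant).
#'
#' @inheritParams bias_forces
#' @return named numeric vector `c(T = ..., V = ...)` in J.
#' @export
energies <- function(model, q, qdot) {
  cpp_energies(model$par, check_q(model, q), check_qdot(model, qdot))
}

#' Whole-body centre of mass
#'
#' Mass-weighted mean of all five segment CoMs, foot included.  The
#' horizontal coordinate is reported relative to its upright-equilibrium
#' value (the welded foot's CoM sits mid-foot, ahead of the ankle, which
#' would otherwise shift `x` by a constant), so `x = 0` at `q = 0`.
#'
#' @inheritParams bias_forces
#' @return named numeric vector `c(x = , z = , vx = )`: horizontal position
#'   (m, equilibrium-referenced), height (m) and horizontal velocity (m/s).
#' @export
whole_body_com <- function(model, q, qdot = NULL) {
  if (is.null(qdot)) qdot <- numeric(model$dof)
  cpp_com(model$par, check_q(model, q), check_qdot(model, qdot))
}
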