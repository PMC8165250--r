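#' Read a structured run configuration
#'
#' YAML schema (all sections optional; omitted values fall back to the
#' defaults, which reproduce the standard 1.7 m / 69.3 kg model):
#'
#' ```yaml
#' anthropometry:
#'   gravity: 9.81
#'   foot_height: 0.1
#'   segments:              # per segment: mass, length, com_fraction,
#'     foot:                #   inertia_model
#'       mass: 1.3
#'       length: 0.3
#'     lower_body: {mass: 35, length: 1.0}
#'     upper_body: {mass: 25, length: 0.6}
#'     right_arm:  {mass: 4, length: 0.6}
#'     left_arm:   {mass: 4, length: 0.6}
#' arm_mode: active         # active | passive | fixed
#' controller:
#'   dt: 0.035
#'   horizon: 29
#'   q_angle: [700000, 700000, 7000]
#'   q_vel: [70000, 70000, 700]
#'   r_scale: 1
#'   qf_factor: 100
#'   push_preview: false
#' bounds:                  # optional overrides of the per-mode defaults
#'   ankle_torque: [-120, 120]
#' protocol:
#'   force: 70
#'   push_duration: 1
#'   max_sim_time: 4
#' recovery:
#'   angle_tol: 0.01
#'   vel_tol: 0.02
#'   dwell: 0.5
#' ```
#'
#' @param path path to a YAML file.
#' @return list with components `model`, `config`, `bounds`, `push`,
#'   `criterion` ready to pass to [simulate_closed_loop()], plus
#'   `resolved` (every value after defaulting, for the run record).
#' @export
read_balance_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  seg_def <- list(
    foot = list(mass = 1.3, length = 0.3),
    lower_body = list(mass = 35, length = 1.0),
    upper_body = list(mass = 25, length = 0.6),
    right_arm = list(mass = 4, length = 0.6),
    left_arm = list(mass = 4, length = 0.6)
  )
  segs <- raw$anthropometry$segments
  mk_seg <- function(nm) {
    s <- modifyList(seg_def[[nm]], if (is.null(segs[[nm]])) list()
                    else segs[[nm]])
    segment_params(nm, s$mass, s$length,
                   com_fraction = if (is.null(s$com_fraction)) 0.5
                                  else s$com_fraction,
                   inertia_model = if (is.null(s$inertia_model))
                     "uniform_rod" else s$inertia_model)
  }
  anthro <- anthropometric_model(
    foot = mk_seg("foot"), lower_body = mk_seg("lower_body"),
    upper_body = mk_seg("upper_body"), right_arm = mk_seg("right_arm"),
    left_arm = mk_seg("left_arm"),
    foot_height = if (is.null(raw$anthropometry$foot_height)) 0.1
                  else raw$anthropometry$foot_height,
    gravity = if (is.null(raw$anthropometry$gravity)) 9.81
              else raw$anthropometry$gravity)
  arm_mode <- if (is.null(raw$arm_mode)) "active" else raw$arm_mode
  model <- build_model(anthro, arm_mode)

  cc <- raw$controller
  def <- nmpc_config()
  config <- nmpc_config(
    dt = if (is.null(cc$dt)) def$dt else cc$dt,
    horizon = if (is.null(cc$horizon)) def$horizon else cc$horizon,
    q_angle = if (is.null(cc$q_angle)) def$q_angle else unlist(cc$q_angle),
    q_vel = if (is.null(cc$q_vel)) def$q_vel else unlist(cc$q_vel),
    r_scale = if (is.null(cc$r_scale)) def$r_scale else unlist(cc$r_scale),
    qf_factor = if (is.null(cc$qf_factor)) def$qf_factor else cc$qf_factor,
    push_preview = if (is.null(cc$push_preview)) def$push_preview
                   else cc$push_preview,
    solver = if (is.null(cc$solver)) list() else cc$solver)

  bounds <- default_bounds(arm_mode)
  if (!is.null(raw$bounds$ankle_torque))
    bounds <- apply_ankle_override(bounds,
                                   unlist(raw$bounds$ankle_torque))

  pp <- raw$protocol
  push <- push_protocol(
    force = if (is.null(pp$force)) 0 else pp$force,
    push_duration = if (is.null(pp$push_duration)) 1 else pp$push_duration,
    max_sim_time = if (is.null(pp$max_sim_time)) 4 else pp$max_sim_time,
    start_time = if (is.null(pp$start_time)) 0 else pp$start_time)

  rc <- raw$recovery
  criterion <- recovery_criterion(
    angle_tol = if (is.null(rc$angle_tol)) 0.01 else rc$angle_tol,
    vel_tol = if (is.null(rc$vel_tol)) 0.02 else rc$vel_tol,
    dwell = if (is.null(rc$dwell)) 0.5 else rc$dwell)

  resolved <- list(
    anthropometry = lapply(
      anthro[c("foot", "lower_body", "upper_body", "right_arm",
               "left_arm")],
      function(s) s[c("mass", "length", "com_fraction", "inertia_model")]),
    foot_height = anthro$foot_height, gravity = anthro$gravity,
    arm_mode = arm_mode,
    controller = config[c("dt", "horizon", "q_angle", "q_vel",
                          "r_scale", "qf_factor", "push_preview")],
    bounds = unclass(bounds),
    protocol = unclass(push), recovery = unclass(criterion))
  list(model = model, config = config, bounds = bounds, push = push,
       criterion = criterion, resolved = resolved)
}

#' Write a JSON run record for a closed-loop trajectory
#'
#' Stores every resolved configuration value together with the outcome
#' (termination, recovery time, metrics), so a run can be reproduced
#' exactly from its record.
#'
#' @param traj a `closed_loop_trajectory`.
#' @param path output JSON path.
#' @param resolved optional resolved-configuration list (from
#'   [read_balance_config()]); if `NULL`, the trajectory's own attributes
#'   are used.
#' @return invisibly, the record list.
#' @export
write_run_record <- function(traj, path, resolved = NULL) {
  m <- balance_metrics(traj)
  cfg <- attr(traj, "config")
  record <- list(
    arm_mode = attr(traj, "arm_mode"),
    force = attr(traj, "force"),
    dt = attr(traj, "dt"),
    controller = cfg[c("dt", "horizon", "q_angle", "q_vel", "r_scale",
                       "qf_factor", "push_preview")],
    bounds = unclass(attr(traj, "bounds")),
    recovery_criterion = unclass(attr(traj, "criterion")),
    resolved = resolved,
    termination = attr(traj, "termination"),
    recovery_time = m$recovery_time,
    metrics = list(total_rms = m$total_rms, arm_rms = m$arm_rms,
                   AEC = m$AEC, TEC = m$TEC,
                   energy_per_joint = as.list(m$energy_per_joint),
                   corr_ankle_hip = m$corr_ankle_hip,
                   corr_hip_arm = m$corr_hip_arm)
  )
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(record)
}

#' Write a trajectory to CSV
#'
#' Columns: `t`, joint angles, velocities, applied torques, push, CoM
#' position/velocity, plus a `status` column repeating the termination
#' flag.
#'
#' @param traj a `closed_loop_trajectory`.
#' @param path output CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- as.data.frame(traj)
  out$status <- attr(traj, "termination")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
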