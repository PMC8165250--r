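#' Force-sweep specification
#'
#' The default sweep reproduces the standard perturbation protocol: pushes
#' of -80 ... 80 N (1 s each) applied to all three arm conditions, with no
#' stochastic component (runs are fully deterministic).
#'
#' @param modes arm conditions to run.
#' @param forces push forces in N.
#' @param ankle_torque optional length-2 override of the ankle torque box
#'   (N m).
#' @param push_duration,max_sim_time see [push_protocol()].
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(modes = c("active", "passive", "fixed"),
                       forces = c(-80, -70, -60, -40, -20, 0,
                                  20, 40, 60, 70, 80),
                       ankle_torque = NULL, push_duration = 1,
                       max_sim_time = 4) {
  modes <- match.arg(modes, c("active", "passive", "fixed"),
                     several.ok = TRUE)
  stopifnot(all(is.finite(forces)))
  if (!is.null(ankle_torque)) {
    stopifnot(length(ankle_torque) == 2L, ankle_torque[1] <= ankle_torque[2])
  }
  structure(list(modes = modes, forces = forces,
                 ankle_torque = ankle_torque,
                 push_duration = push_duration,
                 max_sim_time = max_sim_time),
            class = "sweep_spec")
}

apply_ankle_override <- function(bounds, ankle_torque) {
  if (is.null(ankle_torque)) return(bounds)
  bounds$tau_min[1L] <- ankle_torque[1L]
  bounds$tau_max[1L] <- ankle_torque[2L]
  bounds
}

run_one <- function(mode, force, config, criterion, anthropometry,
                    ankle_torque = NULL, push_duration = 1,
                    max_sim_time = 4) {
  model <- build_model(anthropometry, mode)
  bounds <- apply_ankle_override(default_bounds(mode), ankle_torque)
  push <- push_protocol(force, push_duration = push_duration,
                        max_sim_time = max_sim_time)
  simulate_closed_loop(model, config, push, criterion, bounds)
}

metrics_row <- function(mode, force, traj) {
  m <- balance_metrics(traj)
  data.frame(mode = mode, force = force,
             status = m$termination,
             recovery_time = m$recovery_time,
             total_rms = m$total_rms, arm_rms = m$arm_rms,
             AEC = m$AEC, TEC = m$TEC,
             corr_ankle_hip = m$corr_ankle_hip,
             corr_hip_arm = m$corr_hip_arm,
             stringsAsFactors = FALSE)
}

#' Run the force sweep over arm conditions
#'
#' One closed-loop run per (arm condition, force) pair; failed runs
#' (controller infeasibility) are recorded with `status = "no_solution"`
#' and `NA` metrics, not raised as errors.
#'
#' @param spec a [sweep_spec()].
#' @param config an [nmpc_config()].
#' @param criterion a [recovery_criterion()].
#' @param anthropometry an [anthropometric_model()].
#' @param keep_trajectories if `TRUE`, attach the list of trajectories as
#'   attribute `trajectories` (named `mode_force`).
#' @return data frame with one row per run and columns `mode`, `force`,
#'   `status`, `recovery_time`, `total_rms`, `arm_rms`, `AEC`, `TEC`,
#'   `corr_ankle_hip`, `corr_hip_arm`.
#' @export
run_force_sweep <- function(spec = sweep_spec(), config = nmpc_config(),
                            criterion = recovery_criterion(),
                            anthropometry = anthropometric_model(),
                            keep_trajectories = FALSE) {
  rows <- list()
  trajs <- list()
  for (mode in spec$modes) {
    for (force in spec$forces) {
      traj <- run_one(mode, force, config, criterion, anthropometry,
                      spec$ankle_torque, spec$push_duration,
                      spec$max_sim_time)
      row <- metrics_row(mode, force, traj)
      if (row$status != "recovered") {
        row[c("recovery_time", "total_rms", "arm_rms", "AEC", "TEC",
              "corr_ankle_hip", "corr_hip_arm")] <- NA_real_
      }
      rows[[length(rows) + 1L]] <- row
      if (keep_trajectories)
        trajs[[paste(mode, force, sep = "_")]] <- traj
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_trajectories) attr(out, "trajectories") <- trajs
  out
}

#' Ankle-capacity study (active arms)
#'
#' Five active-arm runs probing how a weakened ankle recruits the arms:
#' ankle torque boxes of +/-80, +/-100, +/-120 N m under a 56 N push, and
#' +/-100, +/-120 N m under a 70 N push.  The simulation cap is raised
#' (default 8 s) so that the slow recovery under the tightest ankle box
#' completes.
#'
#' @inheritParams run_force_sweep
#' @param max_sim_time simulation cap in s.
#' @return data frame with one row per case and columns `case`,
#'   `ankle_tc_min`, `ankle_tc_max`, `force`, `recovery_time`, `arm_rms`,
#'   `AEC`, `TEC`, `status`.
#' @export
run_ankle_capacity_cases <- function(config = nmpc_config(),
                                     criterion = recovery_criterion(),
                                     anthropometry = anthropometric_model(),
                                     max_sim_time = 8,
                                     keep_trajectories = FALSE) {
  cases <- list(list(tc = c(-80, 80), df = 56),
                list(tc = c(-100, 100), df = 56),
                list(tc = c(-120, 120), df = 56),
                list(tc = c(-100, 100), df = 70),
                list(tc = c(-120, 120), df = 70))
  rows <- list()
  trajs <- list()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    traj <- run_one("active", cs$df, config, criterion, anthropometry,
                    ankle_torque = cs$tc, max_sim_time = max_sim_time)
    m <- balance_metrics(traj)
    rows[[i]] <- data.frame(case = i, ankle_tc_min = cs$tc[1],
                            ankle_tc_max = cs$tc[2], force = cs$df,
                            recovery_time = m$recovery_time,
                            arm_rms = m$arm_rms, AEC = m$AEC, TEC = m$TEC,
                            status = m$termination,
                            stringsAsFactors = FALSE)
    if (keep_trajectories) trajs[[i]] <- traj
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_trajectories) attr(out, "trajectories") <- trajs
  out
}

#' Export per-figure CSV bundles from a sweep
#'
#' Writes the data behind the standard plots to `dir`: whole-body CoM time
#' series and CoM phase portraits (per run), RMS-deviation and
#' total-energy tables (across the sweep), joint phase portraits (per run
#' and joint) and -- for active arms only -- joint-angle triplets.  Failed
#' runs contribute a failure record instead of trajectory files.
#'
#' @param sweep result of [run_force_sweep()] with
#'   `keep_trajectories = TRUE`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame of written files.
#' @export
export_figures_data <- function(sweep, dir) {
  trajs <- attr(sweep, "trajectories")
  if (is.null(trajs))
    stop("run the sweep with keep_trajectories = TRUE", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(file, what) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, what = what, stringsAsFactors = FALSE)
  }
  write.csv(sweep, file.path(dir, "rms_energy_bars.csv"),
            row.names = FALSE)
  add("rms_energy_bars.csv", "RMS deviation and energy per (mode, force)")
  fails <- sweep[sweep$status != "recovered", c("mode", "force", "status")]
  if (nrow(fails) > 0L) {
    write.csv(fails, file.path(dir, "failures.csv"), row.names = FALSE)
    add("failures.csv", "runs without a solution")
  }
  for (nm in names(trajs)) {
    traj <- trajs[[nm]]
    if (attr(traj, "termination") == "no_solution") next
    f <- paste0("com_", nm, ".csv")
    write.csv(traj[c("t", "com_x", "com_vx")], file.path(dir, f),
              row.names = FALSE)
    add(f, "whole-body CoM series")
    joints <- c("ankle", "hip", "arm")[seq_len(attr(traj, "dof"))]
    for (j in joints) {
      f <- paste0("phase_", j, "_", nm, ".csv")
      write.csv(phase_portrait(traj, j), file.path(dir, f),
                row.names = FALSE)
      add(f, paste(j, "phase portrait"))
    }
    if (attr(traj, "arm_mode") == "active") {
      f <- paste0("joint_angles_", nm, ".csv")
      write.csv(traj[c("t", "q1", "q2", "q3")], file.path(dir, f),
                row.names = FALSE)
      add(f, "ankle-hip-arm angle triplet")
    }
  }
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
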