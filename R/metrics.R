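#' Recovery-window sample indices of a trajectory
#'
#' Metrics are evaluated on the samples from the start of the run up to
#' the detected recovery time; if the run never recovered the whole
#' trajectory is used.
#' @keywords internal
recovery_window <- function(traj) {
  rt <- attr(traj, "recovery_time")
  if (is.null(rt) || is.na(rt)) return(seq_len(nrow(traj)))
  which(traj$t <= rt + 1e-9)
}

#' Total RMS deviation of ankle and hip angles
#'
#' `sqrt(mean(q1^2 + q2^2))` over the recovery window -- the motion
#' intensity index.  Only ankle and hip enter, in every arm condition.
#'
#' @param traj a `closed_loop_trajectory`.
#' @return RMS deviation in rad.
#' @export
total_rms_deviation <- function(traj) {
  if (nrow(traj) < 1L) stop("empty trajectory", call. = FALSE)
  i <- recovery_window(traj)
  sqrt(mean(traj$q1[i]^2 + traj$q2[i]^2))
}

#' Arm RMS deviation
#'
#' `sqrt(mean(q3^2))` over the recovery window, the arm-only analogue of
#' [total_rms_deviation()].  Undefined (`NA`) for fixed arms, which have no
#' arm coordinate.
#'
#' @inheritParams total_rms_deviation
#' @return RMS deviation in rad, or `NA` for fixed arms.
#' @export
arm_rms_deviation <- function(traj) {
  if (attr(traj, "dof") < 3L) return(NA_real_)
  i <- recovery_window(traj)
  sqrt(mean(traj$q3[i]^2))
}

#' Joint actuator mechanical energy consumption
#'
#' Per actuated joint, the absolute mechanical work
#' `integral |tau_i(t) qdot_i(t)| dt` over the recovery window, by the
#' trapezoidal rule on the sample grid (no regeneration credit: negative
#' work costs as much as positive work).  `TEC` sums over all actuated
#' joints; `AEC` is the arm term (0 for passive arms, `NA` for fixed
#' arms, which have no arm joint).
#'
#' @inheritParams total_rms_deviation
#' @param positive_work_only if `TRUE`, integrate `max(tau qdot, 0)`
#'   instead of `|tau qdot|` (sensitivity option).
#' @return list with `per_joint` (named J), `AEC` (J) and `TEC` (J).
#' @export
energy_consumption <- function(traj, positive_work_only = FALSE) {
  i <- recovery_window(traj)
  nu <- attr(traj, "n_torque")
  arm_mode <- attr(traj, "arm_mode")
  joints <- c("ankle", "hip", "arm")[seq_len(nu)]
  tt <- traj$t[i]
  per <- numeric(nu)
  for (j in seq_len(nu)) {
    p <- traj[[paste0("tau", j)]][i] * traj[[paste0("dq", j)]][i]
    p[is.na(p)] <- 0        # final sample has no applied torque
    p <- if (positive_work_only) pmax(p, 0) else abs(p)
    if (length(tt) > 1L)
      per[j] <- sum(diff(tt) * (p[-1L] + p[-length(p)]) / 2)
  }
  names(per) <- joints
  aec <- if (arm_mode == "active") per[["arm"]]
         else if (arm_mode == "passive") 0
         else NA_real_
  list(per_joint = per, AEC = aec, TEC = sum(per))
}

#' Correlation between neighbouring joint angle series
#'
#' Pearson correlation of two joint-angle time series over the window from
#' push onset to recovery -- the synergy index for neighbouring joints.
#'
#' @inheritParams total_rms_deviation
#' @param pair `"ankle_hip"` or `"hip_arm"`.
#' @return correlation in \[-1, 1\], or `NA` when either series is
#'   constant (zero variance) or the arm coordinate is absent.
#' @export
joint_correlation <- function(traj, pair = c("ankle_hip", "hip_arm")) {
  pair <- match.arg(pair)
  cols <- switch(pair, ankle_hip = c("q1", "q2"), hip_arm = c("q2", "q3"))
  if (pair == "hip_arm" && attr(traj, "dof") < 3L) return(NA_real_)
  i <- recovery_window(traj)
  onset <- attr(traj, "push_start")
  if (!is.null(onset)) i <- i[traj$t[i] >= onset - 1e-9]
  x <- traj[[cols[1L]]][i]
  y <- traj[[cols[2L]]][i]
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  cor(x, y)
}

#' Phase portrait of one joint
#'
#' Extracts the (angle, angular velocity) curve of a joint.  For recovered
#' runs the curve is closed: it starts and ends near the origin.
#'
#' @inheritParams total_rms_deviation
#' @param joint `"ankle"`, `"hip"` or `"arm"`.
#' @return data frame with columns `t`, `angle`, `velocity`.
#' @export
phase_portrait <- function(traj, joint = c("ankle", "hip", "arm")) {
  joint <- match.arg(joint)
  idx <- match(joint, c("ankle", "hip", "arm"))
  if (idx > attr(traj, "dof"))
    stop("fixed-arm trajectories have no arm coordinate", call. = FALSE)
  data.frame(t = traj$t,
             angle = traj[[paste0("q", idx)]],
             velocity = traj[[paste0("dq", idx)]])
}

#' All balance metrics of one run
#'
#' @inheritParams total_rms_deviation
#' @return list of class `balance_metrics`: `recovery_time`, `total_rms`,
#'   `arm_rms`, `energy_per_joint`, `AEC`, `TEC`, `corr_ankle_hip`,
#'   `corr_hip_arm`, `termination`.
#' @export
balance_metrics <- function(traj) {
  en <- energy_consumption(traj)
  structure(list(
    recovery_time = attr(traj, "recovery_time"),
    total_rms = total_rms_deviation(traj),
    arm_rms = arm_rms_deviation(traj),
    energy_per_joint = en$per_joint,
    AEC = en$AEC,
    TEC = en$TEC,
    corr_ankle_hip = joint_correlation(traj, "ankle_hip"),
    corr_hip_arm = if (attr(traj, "dof") == 3L)
      joint_correlation(traj, "hip_arm") else NA_real_,
    termination = attr(traj, "termination")
  ), class = "balance_metrics")
}

#' @export
print.balance_metrics <- function(x, ...) {
  cat(sprintf(
    "Balance metrics: %s, recovery %.2f s, total RMS %.4f rad, TEC %.2f J\n",
    x$termination, x$recovery_time, x$total_rms, x$TEC))
  invisible(x)
}
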