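#' Segment parameters
#'
#' Describes one rigid segment of the standing model: its mass, length, the
#' location of its centre of mass along the segment, and the inertia model
#' used to derive its rotational inertia about that centre of mass.
#'
#' @param name segment label.
#' @param mass segment mass in kg (> 0).
#' @param length segment length in m (> 0).
#' @param com_fraction distance of the segment CoM from the proximal joint,
#'   as a fraction of `length` (in \[0, 1\]).  Default 0.5 (mid-segment).
#' @param inertia_model `"uniform_rod"` (rotational inertia `m L^2 / 12`
#'   about the CoM, the default) or `"point_mass_at_com"` (zero rotational
#'   inertia).
#' @return an object of class `segment_params`.
#' @export
segment_params <- function(name, mass, length,
                           com_fraction = 0.5,
                           inertia_model = c("uniform_rod",
                                             "point_mass_at_com")) {
  inertia_model <- match.arg(inertia_model)
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) ||
      mass <= 0) {
    stop("segment '", name, "': mass must be a positive number", call. = FALSE)
  }
  if (!is.numeric(length) || base::length(length) != 1L ||
      !is.finite(length) || length <= 0) {
    stop("segment '", name, "': length must be a positive number",
         call. = FALSE)
  }
  if (com_fraction < 0 || com_fraction > 1) {
    stop("segment '", name, "': com_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(name = as.character(name), mass = mass, length = length,
         com_fraction = com_fraction, inertia_model = inertia_model),
    class = "segment_params"
  )
}

#' Rotational inertia of a segment about its own centre of mass
#' @param seg a [segment_params()] object.
#' @return inertia in kg m^2.
#' @keywords internal
segment_inertia <- function(seg) {
  switch(seg$inertia_model,
         uniform_rod = seg$mass * seg$length^2 / 12,
         point_mass_at_com = 0)
}

#' Whole-body anthropometric model
#'
#' Collects the five segments of the standing model (foot, lower body,
#' upper body and the two arms) together with the ankle height above the
#' ground and gravity.  The defaults describe a 1.7 m, 69.3 kg adult:
#' foot 1.3 kg / 0.3 m (ankle 0.1 m above ground), lower body 35 kg / 1.0 m,
#' upper body 25 kg / 0.6 m, and two 4 kg / 0.6 m arms.
#'
#' @param foot,lower_body,upper_body,right_arm,left_arm segment
#'   descriptions, see [segment_params()].
#' @param foot_height height of the ankle joint above the ground in m.
#' @param gravity gravitational acceleration in m/s^2.
#' @param inertia_model default inertia model applied to the default
#'   segments (ignored for segments passed in explicitly).
#' @return an object of class `anthropometric_model`.
#' @examples
#' body <- anthropometric_model()
#' total_mass(body)  # 69.3 kg
#' @export
anthropometric_model <- function(foot = NULL, lower_body = NULL,
                                 upper_body = NULL, right_arm = NULL,
                                 left_arm = NULL, foot_height = 0.1,
                                 gravity = 9.81,
                                 inertia_model = "uniform_rod") {
  if (is.null(foot))
    foot <- segment_params("foot", 1.3, 0.3, inertia_model = inertia_model)
  if (is.null(lower_body))
    lower_body <- segment_params("lower_body", 35, 1.0,
                                 inertia_model = inertia_model)
  if (is.null(upper_body))
    upper_body <- segment_params("upper_body", 25, 0.6,
                                 inertia_model = inertia_model)
  if (is.null(right_arm))
    right_arm <- segment_params("right_arm", 4, 0.6,
                                inertia_model = inertia_model)
  if (is.null(left_arm))
    left_arm <- segment_params("left_arm", 4, 0.6,
                               inertia_model = inertia_model)
  segs <- list(foot = foot, lower_body = lower_body,
               upper_body = upper_body, right_arm = right_arm,
               left_arm = left_arm)
  for (s in segs) {
    if (!inherits(s, "segment_params"))
      stop("all segments must be segment_params objects", call. = FALSE)
  }
  if (!isTRUE(right_arm$length == left_arm$length))
    stop("the two arms are lumped into one link and must share a length",
         call. = FALSE)
  if (foot_height <= 0 || gravity <= 0)
    stop("foot_height and gravity must be positive", call. = FALSE)
  structure(
    c(segs, list(foot_height = foot_height, gravity = gravity)),
    class = "anthropometric_model"
  )
}

#' Total body mass of an anthropometric model
#' @param anthro an [anthropometric_model()].
#' @return mass in kg.
#' @export
total_mass <- function(anthro) {
  stopifnot(inherits(anthro, "anthropometric_model"))
  anthro$foot$mass + anthro$lower_body$mass + anthro$upper_body$mass +
    anthro$right_arm$mass + anthro$left_arm$mass
}

#' @export
print.anthropometric_model <- function(x, ...) {
  cat("Anthropometric model: total mass", format(total_mass(x)), "kg,",
      "standing height",
      format(x$foot_height + x$lower_body$length + x$upper_body$length),
      "m\n")
  for (nm in c("foot", "lower_body", "upper_body", "right_arm",
               "left_arm")) {
    s <- x[[nm]]
    cat(sprintf("  %-10s m = %5.1f kg, L = %4.2f m, c = %.2f (%s)\n",
                s$name, s$mass, s$length, s$com_fraction, s$inertia_model))
  }
  invisible(x)
}
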