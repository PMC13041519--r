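#' Animal escape-response parameters
#'
#' Bundles the behavioral and kinematic state of the animal at the moment it
#' initiates escape from an approaching vehicle.
#'
#' @param l body length (m), tip to tail; positive.
#' @param Sa escape speed (m/s); non-negative. `Sa = 0` denotes an animal
#'   that does not move, for which the time needed to escape is infinite.
#' @param delta sensory-motor delay (s): time spent reorienting and
#'   accelerating before effective escape motion; non-negative.
#' @param d_fid flight-initiation distance (m): distance to the vehicle when
#'   escape begins; non-negative.
#' @param theta escape angle in degrees, strictly between 0 and 180;
#'   0 points directly at the approaching vehicle, 180 directly away, 90 is
#'   perpendicular to the approach axis. The sampled behavioral range is
#'   0.01-179.99, so the exact endpoints are excluded.
#' @param d_min minimum distance to safety (m): lateral distance from the
#'   animal to the nearest edge of the vehicle's swept trajectory; positive.
#'   Its largest meaningful value is the full trajectory width, which is
#'   enforced where the animal is paired with a vehicle.
#' @return An object of class `animal_params`.
#' @export
animal_params <- function(l, Sa, delta, d_fid, theta, d_min) {
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    x
  }
  l <- chk(l, "l"); Sa <- chk(Sa, "Sa"); delta <- chk(delta, "delta")
  d_fid <- chk(d_fid, "d_fid"); theta <- chk(theta, "theta")
  d_min <- chk(d_min, "d_min")
  if (l <= 0) stop("`l` must be > 0", call. = FALSE)
  if (Sa < 0) stop("`Sa` must be >= 0", call. = FALSE)
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (d_fid < 0) stop("`d_fid` must be >= 0", call. = FALSE)
  if (theta <= 0 || theta >= 180) {
    stop("`theta` must lie strictly between 0 and 180 degrees", call. = FALSE)
  }
  if (d_min <= 0) stop("`d_min` must be > 0", call. = FALSE)
  structure(list(l = l, Sa = Sa, delta = delta, d_fid = d_fid,
                 theta = theta, d_min = d_min),
            class = "animal_params")
}

#' Vehicle approach parameters
#'
#' @param Sv constant approach speed (m/s); positive.
#' @param silhouette a [frontal_silhouette()] describing the vehicle's
#'   frontal projection; its physical extents define the swept trajectory.
#' @param d_width,d_height trajectory width and height (m); default to the
#'   silhouette's extents and must match them within floating tolerance.
#' @return An object of class `vehicle_params`.
#' @export
vehicle_params <- function(Sv, silhouette, d_width = silhouette$width_m,
                           d_height = silhouette$height_m) {
  stopifnot(inherits(silhouette, "frontal_silhouette"))
  if (!is.numeric(Sv) || length(Sv) != 1L || !is.finite(Sv) || Sv <= 0) {
    stop("`Sv` must be a single positive speed", call. = FALSE)
  }
  if (abs(d_width - silhouette$width_m) > 1e-8 * silhouette$width_m ||
      abs(d_height - silhouette$height_m) > 1e-8 * silhouette$height_m) {
    stop("`d_width`/`d_height` must match the silhouette's physical extents",
         call. = FALSE)
  }
  structure(list(Sv = Sv, d_width = d_width, d_height = d_height,
                 silhouette = silhouette),
            class = "vehicle_params")
}

#' Total distance the animal must travel to reach safety
#'
#' The lateral distance to the nearest trajectory edge plus the animal's own
#' body length, which it must clear entirely to avoid contact:
#' `d_safe = d_min + l`.
#'
#' @param a an [animal_params()].
#' @return Distance to safety (m).
#' @export
distance_to_safety <- function(a) {
  stopifnot(inherits(a, "animal_params"))
  a$d_min + a$l
}

#' Time the animal needs to clear the trajectory
#'
#' `Ta = d_safe / (sin(theta) * Sa) + delta`. Only the escape-velocity
#' component perpendicular to the approach axis moves the animal toward the
#' trajectory edge, so `Ta` is minimized at a 90-degree escape angle and
#' grows as the angle tilts toward either 0 or 180. A non-escaping animal
#' (`Sa = 0`) yields `Inf`, which compares greater than any finite time
#' available, keeping the phase-one predicate total.
#'
#' @param a an [animal_params()].
#' @return Time needed to escape (s); `Inf` when `Sa = 0`.
#' @export
time_needed <- function(a) {
  stopifnot(inherits(a, "animal_params"))
  lateral_speed <- sin(a$theta * pi / 180) * a$Sa
  if (lateral_speed <= 0) return(Inf)
  distance_to_safety(a) / lateral_speed + a$delta
}

#' Time until the vehicle reaches the animal's position
#'
#' `Tv = d_fid / (Sv + cos(theta) * Sa)`: the flight-initiation distance
#' divided by the closing speed along the approach axis. Escaping toward the
#' vehicle (`theta < 90`) increases the closing speed and shortens the time
#' available; escaping away (`theta > 90`) buys time.
#'
#' @param a an [animal_params()].
#' @param v a [vehicle_params()].
#' @return Time available before the vehicle arrives (s).
#' @export
time_available <- function(a, v) {
  stopifnot(inherits(a, "animal_params"), inherits(v, "vehicle_params"))
  closing <- v$Sv + cos(a$theta * pi / 180) * a$Sa
  if (closing <= 0) {
    stop("ill-posed closing speed: Sv + cos(theta) * Sa must be > 0",
         call. = FALSE)
  }
  a$d_fid / closing
}

#' Phase one: can the animal clear the trajectory in time?
#'
#' Compares the time the animal needs to escape ([time_needed()]) with the
#' time available before the vehicle arrives ([time_available()]). A
#' collision is possible when `Ta >= Tv` (the boundary case counts as
#' collision-possible); when `Ta < Tv` the animal clears the trajectory and
#' the interaction ends with collision probability exactly zero.
#'
#' @param a an [animal_params()].
#' @param v a [vehicle_params()].
#' @return An object of class `phase_one_result`: list with `d_safe`, `t_a`,
#'   `t_v` and logical `collision_possible`.
#' @export
phase_one <- function(a, v) {
  stopifnot(inherits(a, "animal_params"), inherits(v, "vehicle_params"))
  if (a$d_min > v$d_width) {
    stop("`d_min` cannot exceed the trajectory width", call. = FALSE)
  }
  t_a <- time_needed(a)
  t_v <- time_available(a, v)
  structure(list(d_safe = distance_to_safety(a), t_a = t_a, t_v = t_v,
                 collision_possible = t_a >= t_v),
            class = "phase_one_result")
}

#' @export
print.phase_one_result <- function(x, ...) {
  cat(sprintf("Phase one: Ta = %.4g s, Tv = %.4g s -> %s\n",
              x$t_a, x$t_v,
              if (x$collision_possible) "collision possible"
              else "escape (p = 0)"))
  invisible(x)
}

#' Threshold approach angle separating direct from indirect approaches
#'
#' For a vehicle at distance `d_mid` from the animal (measured to the center
#' of the vehicle), approach angles less than or equal to
#' `asin((d_half + l) / d_mid)` sweep over the animal's position (a direct
#' approach, collision possible without an escape response), while larger
#' angles bypass it.
#'
#' @param d_mid distance between the vehicle's center and the animal (m);
#'   positive.
#' @param d_half half the maximum width of the vehicle (m); non-negative.
#' @param l animal body length (m); positive.
#' @return Threshold angle in degrees.
#' @export
threshold_angle <- function(d_mid, d_half, l) {
  stopifnot(is.numeric(d_mid), d_mid > 0, is.numeric(d_half), d_half >= 0,
            is.numeric(l), l > 0)
  ratio <- (d_half + l) / d_mid
  if (ratio > 1) {
    stop("(d_half + l) / d_mid > 1: the animal is inside the swept width ",
         "at any approach angle", call. = FALSE)
  }
  asin(ratio) * 180 / pi
}
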