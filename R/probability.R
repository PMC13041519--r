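#' Initial position of the animal within the trajectory
#'
#' `d_initial = d_width - d_min`: the animal's x-coordinate on the trajectory
#' plane at escape initiation, anchored so that an animal at the far edge of
#' the swept width (`d_min = d_width`) starts at x = 0.
#'
#' @param a an [animal_params()].
#' @param v a [vehicle_params()].
#' @return Initial x-position (m) in `[0, d_width)`.
#' @export
initial_position <- function(a, v) {
  stopifnot(inherits(a, "animal_params"), inherits(v, "vehicle_params"))
  if (a$d_min > v$d_width) {
    stop("`d_min` cannot exceed the trajectory width", call. = FALSE)
  }
  v$d_width - a$d_min
}

#' Position of the animal when the vehicle arrives
#'
#' Advances the animal from its initial position for the time available
#' before the vehicle arrives: `d_collision = d_initial + cos(theta) * Sa *
#' t_v`. The result is the midpoint of the animal's body on the x-axis and
#' may lie beyond either edge of the trajectory, in which case the window
#' integral credits the out-of-bounds part with zero occupancy.
#'
#' The lateral-progress term uses `cos(theta)` by default, matching the
#' model as published; `eq5_term = "sin"` switches to the `sin(theta)`
#' variant (the perpendicular velocity component, consistent with the
#' clearance term in [time_needed()]) for sensitivity analysis.
#'
#' @param a an [animal_params()].
#' @param v a [vehicle_params()].
#' @param t_v time available (s), from [time_available()]; non-negative.
#' @param eq5_term `"cos"` (default) or `"sin"`.
#' @return x-position of the animal's midpoint at vehicle arrival (m).
#' @export
position_at_arrival <- function(a, v, t_v, eq5_term = c("cos", "sin")) {
  stopifnot(inherits(a, "animal_params"), inherits(v, "vehicle_params"),
            is.numeric(t_v), t_v >= 0)
  eq5_term <- match.arg(eq5_term)
  trig <- if (eq5_term == "cos") cos(a$theta * pi / 180)
          else sin(a$theta * pi / 180)
  initial_position(a, v) + trig * a$Sa * t_v
}

#' Phase two: collision probability from the animal's position
#'
#' If phase one reported an escape, the probability is exactly zero.
#' Otherwise the animal's position at vehicle arrival is computed with
#' [position_at_arrival()] and converted to a probability with the
#' silhouette window integral [window_probability()].
#'
#' @param a an [animal_params()].
#' @param v a [vehicle_params()].
#' @param p1 a `phase_one_result` from [phase_one()].
#' @param eq5_term passed to [position_at_arrival()].
#' @return An object of class `phase_two_result`: list with `d_initial`,
#'   `d_collision` and `p_collision` in `[0, 1]`.
#' @examples
#' sil <- generate_silhouette(silhouette_spec_737(), resolution = 400)
#' a <- animal_params(l = 1.15, Sa = 5, delta = 0.2, d_fid = 56.2,
#'                    theta = 45, d_min = 7)
#' v <- vehicle_params(Sv = 70.47, silhouette = sil)
#' collision_probability(a, v, phase_one(a, v))
#' @export
collision_probability <- function(a, v, p1, eq5_term = c("cos", "sin")) {
  stopifnot(inherits(a, "animal_params"), inherits(v, "vehicle_params"),
            inherits(p1, "phase_one_result"))
  eq5_term <- match.arg(eq5_term)
  d_initial <- initial_position(a, v)
  if (!p1$collision_possible) {
    res <- list(d_initial = d_initial, d_collision = NA_real_,
                p_collision = 0)
  } else {
    d_collision <- position_at_arrival(a, v, p1$t_v, eq5_term)
    res <- list(d_initial = d_initial, d_collision = d_collision,
                p_collision = window_probability(v$silhouette, d_collision,
                                                 a$l))
  }
  structure(res, class = "phase_two_result")
}

#' @export
print.phase_two_result <- function(x, ...) {
  if (is.na(x$d_collision)) {
    cat("Phase two: escape in phase one, p_collision = 0\n")
  } else {
    cat(sprintf("Phase two: d_collision = %.3f m, p_collision = %.4f\n",
                x$d_collision, x$p_collision))
  }
  invisible(x)
}
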