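# Dynamic delivery time: gantry rotation under kinematic limits coupled to
# per-control-point irradiation floors (SPArc), or step-and-shoot rotation
# between static fields (IMPT).

# time-optimal traversal of one segment of width w (deg) entering at v_in
# and leaving at v_out (deg/s), cruise capped at v_max. Requires the entry/
# exit pair to be reachable (guaranteed by the forward/backward passes).
segment_time <- function(w, v_in, v_out, gantry) {
  if (w <= 0) return(0)
  a <- gantry$a_max; d <- gantry$d_max
  v_peak <- min(gantry$v_max,
                sqrt((2 * a * d * w + d * v_in^2 + a * v_out^2) / (a + d)))
  v_peak <- max(v_peak, v_in, v_out)  # guard fp noise at the envelope
  d_acc <- (v_peak^2 - v_in^2) / (2 * a)
  d_dec <- (v_peak^2 - v_out^2) / (2 * d)
  cruise <- max(0, w - d_acc - d_dec)
  t <- (v_peak - v_in) / a + (v_peak - v_out) / d
  if (cruise > 0) t <- t + cruise / v_peak
  t
}

#' Time-optimal rest-to-rest gantry rotation
#'
#' Closed-form trapezoidal (or triangular, below the distance at which top
#' speed is reached) move time over `delta` degrees starting and ending at
#' rest. At the default limits (6 deg/s, 0.6 / 0.5 deg/s^2) the trapezoid
#' threshold is 66 degrees.
#'
#' @param delta Non-negative rotation angle, degrees. Vectorized.
#' @param gantry A `gantry_model`.
#' @return Rotation time in seconds.
#' @export
rest_to_rest_time <- function(delta, gantry = gantry_model()) {
  if (any(delta < 0)) stop_sparc("rotation angle must be non-negative")
  vapply(delta, segment_time, numeric(1), v_in = 0, v_out = 0, gantry = gantry)
}

#' Plan a gantry velocity profile over arc segments with irradiation floors
#'
#' Boundary speeds start from the per-segment nominal speed
#' `min(v_max, width / min_time)` and are limited by a forward pass under
#' the acceleration limit and a backward pass under the deceleration limit,
#' with rest at both ends. Each segment then takes the larger of its
#' irradiation floor and its time-optimal traversal time given the entry
#' and exit speeds (dwelling to stretch a segment is always feasible).
#'
#' @param widths Segment angular widths, degrees (> 0).
#' @param min_times Per-segment irradiation floors, seconds (>= 0).
#' @param gantry A `gantry_model`.
#' @return An object of class `velocity_profile`: a data.frame with columns
#'   `width_deg`, `v_in`, `v_out`, `t_segment`, `limited_by`
#'   (`"irradiation"` or `"kinematics"`), with the total duration in
#'   attribute `"total"`.
#' @export
plan_velocity_profile <- function(widths, min_times, gantry = gantry_model()) {
  n <- length(widths)
  stopifnot(n >= 1L, length(min_times) == n)
  if (any(widths <= 0)) stop_sparc("segment widths must be positive")
  if (any(min_times < 0)) stop_sparc("irradiation floors must be non-negative")

  caps <- ifelse(min_times > 0, pmin(gantry$v_max, widths / min_times),
                 gantry$v_max)
  b <- c(0, pmin(caps[-n], caps[-1]), 0)  # boundary speeds, n + 1 of them
  if (n == 1L) b <- c(0, 0)
  for (i in seq_len(n))            # forward: acceleration limit
    b[i + 1] <- min(b[i + 1], sqrt(b[i]^2 + 2 * gantry$a_max * widths[i]))
  for (i in rev(seq_len(n)))       # backward: deceleration limit
    b[i] <- min(b[i], sqrt(b[i + 1]^2 + 2 * gantry$d_max * widths[i]))

  t_opt <- vapply(seq_len(n), function(i)
    segment_time(widths[i], b[i], b[i + 1], gantry), numeric(1))
  t_seg <- pmax(min_times, t_opt)
  prof <- data.frame(width_deg = widths, v_in = b[-(n + 1)], v_out = b[-1],
                     t_segment = t_seg,
                     limited_by = ifelse(min_times >= t_opt,
                                         "irradiation", "kinematics"))
  structure(prof, total = sum(t_seg), class = c("velocity_profile", "data.frame"))
}

# exhaustive kinematic invariant check used by tests and simulators
check_velocity_profile <- function(profile, gantry, tol = 1e-9) {
  v_in <- profile$v_in; v_out <- profile$v_out; w <- profile$width_deg
  ok <- v_in >= -tol & v_out >= -tol &
    v_in <= gantry$v_max + tol & v_out <= gantry$v_max + tol &
    (v_out^2 - v_in^2) <= 2 * gantry$a_max * w + tol &
    (v_in^2 - v_out^2) <= 2 * gantry$d_max * w + tol
  all(ok) && abs(v_in[1]) <= tol && abs(v_out[length(v_out)]) <= tol
}

#' Dynamic delivery time of a SPArc plan
#'
#' Computes the static irradiation time of every control point, then plans
#' the gantry rotation connecting adjacent control points without violating
#' the kinematic limits: the layer of control point i is delivered during
#' segment i (the rotation towards control point i+1), whose duration is
#' floored by that irradiation time. The final control point is delivered
#' at rest after arrival.
#'
#' @param plan A valid SPArc `proton_plan` with at least two control points.
#' @param machine A `machine_model`.
#' @param gantry A `gantry_model`.
#' @param check Validate the plan first (default `TRUE`).
#' @return A `delivery_report` with per-unit timing plus segment columns,
#'   `bdt_s`, and `bdt_d >= bdt_s`.
#' @export
sparc_bdt_dynamic <- function(plan, machine, gantry = gantry_model(),
                              check = TRUE) {
  if (plan$modality != "sparc") stop_sparc("plan is not a sparc plan")
  if (check) {
    viol <- validate_plan(plan, machine)
    if (length(viol))
      stop_sparc("invalid plan: %s", paste(viol, collapse = "; "))
  }
  cps <- plan$arc$control_points
  n <- length(cps)
  if (n < 2L) stop_sparc("sparc dynamic simulation needs >= 2 control points")
  timing <- timing_frame(plan, machine)   # one row per control point
  widths <- abs(diff(vapply(cps, function(cp) cp$angle_deg, numeric(1))))
  prof <- plan_velocity_profile(widths, timing$total[-n], gantry)
  timing$segment_width_deg <- c(widths, 0)
  timing$v_in <- c(prof$v_in, 0)
  timing$v_out <- c(prof$v_out, 0)
  timing$t_segment <- c(prof$t_segment, timing$total[n])
  timing$limited_by <- c(prof$limited_by, "irradiation")
  new_delivery_report(timing, bdt_s = sum(timing$total),
                      bdt_d = sum(timing$t_segment))
}

#' Dynamic delivery time of an IMPT plan (step and shoot)
#'
#' The gantry stops while irradiating each field; between consecutive
#' fields it performs a rest-to-rest rotation along the shortest angular
#' path. Couch changes contribute a configurable constant (default 0 s);
#' data-transfer and beam-request overheads are not modelled.
#'
#' @param plan A valid IMPT `proton_plan`.
#' @param machine A `machine_model`.
#' @param gantry A `gantry_model`.
#' @param couch_time Seconds added per couch-angle change between fields.
#' @param check Validate the plan first (default `TRUE`).
#' @return A `delivery_report` with `bdt_s` and `bdt_d`.
#' @export
impt_bdt_dynamic <- function(plan, machine, gantry = gantry_model(),
                             couch_time = 0, check = TRUE) {
  if (plan$modality != "impt") stop_sparc("plan is not an impt plan")
  static <- plan_bdt_static(plan, machine, check = check)
  g <- vapply(plan$fields, function(f) f$gantry_deg, numeric(1))
  cc <- vapply(plan$fields, function(f) f$couch_deg, numeric(1))
  rot <- 0
  if (length(g) > 1L) {
    rot <- sum(rest_to_rest_time(angular_distance(g[-length(g)], g[-1]), gantry)) +
      couch_time * sum(cc[-length(cc)] != cc[-1])
  }
  new_delivery_report(static$timing, bdt_s = static$bdt_s,
                      bdt_d = static$bdt_s + rot)
}

#' Dynamic delivery time of any plan
#'
#' Dispatches to [sparc_bdt_dynamic()] or [impt_bdt_dynamic()] by modality.
#'
#' @inheritParams impt_bdt_dynamic
#' @param ... Passed through to the modality-specific simulator.
#' @return A `delivery_report`.
#' @export
plan_bdt_dynamic <- function(plan, machine, gantry = gantry_model(), ...) {
  if (plan$modality == "sparc") sparc_bdt_dynamic(plan, machine, gantry, ...)
  else impt_bdt_dynamic(plan, machine, gantry, ...)
}
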