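#' Build an energy layer
#'
#' An energy layer is the set of pencil-beam spots sharing one beam energy.
#' Spot delivery order is the stored row order and is never re-sorted:
#' delivery timing is order-sensitive.
#'
#' @param energy_mev Beam energy in MeV.
#' @param spots Numeric matrix with columns `x`, `y` (mm at the isocenter
#'   plane) and `mu` (monitor units), one row per spot, or a vector of
#'   length 3 for a single spot.
#' @return An object of class `energy_layer`.
#' @export
energy_layer <- function(energy_mev, spots) {
  if (is.null(dim(spots))) spots <- matrix(spots, ncol = 3, byrow = TRUE)
  spots <- as.matrix(spots)
  if (ncol(spots) != 3L) stop_sparc("spots must have columns x, y, mu")
  colnames(spots) <- c("x", "y", "mu")
  structure(list(energy_mev = as.numeric(energy_mev), spots = spots),
            class = "energy_layer")
}

#' Total monitor units in a layer
#' @param layer An `energy_layer`.
#' @return Sum of spot MU.
#' @export
layer_mu <- function(layer) sum(layer$spots[, "mu"])

#' Build a static treatment field
#'
#' @param gantry_deg Gantry angle in degrees, `[0, 360)`.
#' @param couch_deg Couch (table) angle in degrees.
#' @param layers List of [energy_layer()] objects in delivery order.
#' @return An object of class `field`.
#' @export
beam_field <- function(gantry_deg, couch_deg = 0, layers) {
  structure(list(gantry_deg = as.numeric(gantry_deg) %% 360,
                 couch_deg = as.numeric(couch_deg),
                 layers = layers), class = "field")
}

#' Build an arc control point
#'
#' A control point is one discrete gantry angle along the arc trajectory at
#' which (for a deliverable arc plan) exactly one energy layer is irradiated.
#' Intermediate plans produced during restructuring may temporarily hold
#' several layers; [validate_plan()] flags those.
#'
#' @param angle_deg Gantry angle along the (unwrapped, monotone) trajectory.
#' @param layers A single [energy_layer()] or a list of them.
#' @return An object of class `control_point`.
#' @export
control_point <- function(angle_deg, layers = list()) {
  if (inherits(layers, "energy_layer")) layers <- list(layers)
  structure(list(angle_deg = as.numeric(angle_deg), layers = layers),
            class = "control_point")
}

#' Build a treatment plan
#'
#' Plans are either multi-field IMPT (`modality = "impt"`, ordered `fields`)
#' or single-arc SPArc (`modality = "sparc"`, an `arc` trajectory of ordered
#' control points). Arc angles are stored unwrapped and strictly monotone
#' along the rotation direction, so a full rotation is 0 to 360 with no
#' modular ambiguity.
#'
#' @param modality `"impt"` or `"sparc"`.
#' @param prescription_gy Prescription dose, Gy.
#' @param fractions Number of fractions.
#' @param fields List of [beam_field()] objects (IMPT).
#' @param arc List with `direction` (+1 or -1), `start_deg`, `stop_deg`,
#'   `control_points` (list of [control_point()]) and optional
#'   `excluded_sectors` (list of `c(from, to)` IEC sectors) (SPArc).
#' @return An object of class `proton_plan`.
#' @export
proton_plan <- function(modality, prescription_gy, fractions,
                        fields = NULL, arc = NULL) {
  modality <- match.arg(modality, c("impt", "sparc"))
  if (modality == "impt" && is.null(fields))
    stop_sparc("impt plan requires fields")
  if (modality == "sparc") {
    if (is.null(arc)) stop_sparc("sparc plan requires an arc trajectory")
    arc$direction <- as.integer(sign(arc$direction %||% 1))
    if (arc$direction == 0L) arc$direction <- 1L
    arc$excluded_sectors <- arc$excluded_sectors %||% list()
  }
  structure(list(modality = modality,
                 prescription_gy = as.numeric(prescription_gy),
                 fractions = as.integer(fractions),
                 fields = fields, arc = arc),
            class = "proton_plan")
}

#' Enumerate the layers of a plan in delivery order
#'
#' @param plan A `proton_plan`.
#' @return A list with one element per layer, each
#'   `list(layer, angle_deg, unit, sub)` where `unit` indexes the field or
#'   control point and `sub` the layer within it.
#' @export
plan_layers <- function(plan) {
  out <- list()
  if (plan$modality == "impt") {
    for (i in seq_along(plan$fields)) {
      fl <- plan$fields[[i]]
      for (j in seq_along(fl$layers))
        out[[length(out) + 1L]] <- list(layer = fl$layers[[j]],
                                        angle_deg = fl$gantry_deg,
                                        unit = i, sub = j)
    }
  } else {
    cps <- plan$arc$control_points
    for (i in seq_along(cps))
      for (j in seq_along(cps[[i]]$layers))
        out[[length(out) + 1L]] <- list(layer = cps[[i]]$layers[[j]],
                                        angle_deg = cps[[i]]$angle_deg,
                                        unit = i, sub = j)
  }
  out
}

#' Total monitor units in a plan
#' @param plan A `proton_plan`.
#' @return Sum of MU over all spots of all layers.
#' @export
plan_total_mu <- function(plan) {
  sum(vapply(plan_layers(plan), function(e) layer_mu(e$layer), numeric(1)))
}

#' Validate a plan against the type invariants and a machine energy list
#'
#' Pure check: the plan is never modified. Each violation is a string of the
#' form `"<location>: <reason>"`.
#'
#' @param plan A `proton_plan`.
#' @param machine Optional `machine_model`; when given, every layer energy
#'   must match a machine energy within `tol` MeV.
#' @param tol Energy matching tolerance in MeV.
#' @return Character vector of violations; `character(0)` if the plan is valid.
#' @export
validate_plan <- function(plan, machine = NULL, tol = 0.05) {
  v <- character(0)
  add <- function(loc, why) v[[length(v) + 1L]] <<- paste0(loc, ": ", why)

  check_layer <- function(layer, loc) {
    if (!inherits(layer, "energy_layer")) { add(loc, "not an energy layer"); return() }
    sp <- layer$spots
    if (nrow(sp) < 1L) add(loc, "layer has no spots")
    if (any(!is.finite(sp[, c("x", "y")]))) add(loc, "non-finite spot position")
    if (any(sp[, "mu"] < 0)) add(loc, "negative spot MU")
    if (!is.null(machine) && is.na(machine_energy_index(machine, layer$energy_mev, tol)))
      add(loc, sprintf("energy %.3f MeV not in machine list", layer$energy_mev))
  }

  if (!inherits(plan, "proton_plan")) return("plan: not a proton_plan")
  if (!is_number(plan$prescription_gy) || plan$prescription_gy <= 0)
    add("plan", "prescription must be a positive number")

  if (plan$modality == "impt") {
    if (length(plan$fields) < 1L) add("plan", "impt plan has no fields")
    for (i in seq_along(plan$fields)) {
      fl <- plan$fields[[i]]
      loc <- sprintf("field[%d]", i)
      if (length(fl$layers) < 1L) add(loc, "field has no layers")
      en <- vapply(fl$layers, function(l) l$energy_mev, numeric(1))
      if (anyDuplicated(en)) add(loc, "duplicate layer energies within field")
      if (fl$gantry_deg < 0 || fl$gantry_deg >= 360)
        add(loc, "gantry angle outside [0, 360)")
      for (j in seq_along(fl$layers))
        check_layer(fl$layers[[j]], sprintf("%s.layer[%d]", loc, j))
    }
  } else {
    cps <- plan$arc$control_points
    if (length(cps) < 1L) add("plan", "arc has no control points")
    ang <- vapply(cps, function(cp) cp$angle_deg, numeric(1))
    if (length(ang) > 1L && any(diff(ang) * plan$arc$direction <= 0))
      add("arc", "control-point angles not strictly monotone along direction")
    for (i in seq_along(cps)) {
      loc <- sprintf("control_point[%d]", i)
      nl <- length(cps[[i]]$layers)
      if (nl != 1L)
        add(loc, sprintf("must hold exactly one energy layer (has %d)", nl))
      for (j in seq_along(cps[[i]]$layers))
        check_layer(cps[[i]]$layers[[j]], sprintf("%s.layer[%d]", loc, j))
      for (sec in plan$arc$excluded_sectors)
        if (angle_in_sector(cps[[i]]$angle_deg, sec[1], sec[2]))
          add(loc, sprintf("inside excluded sector [%g, %g]", sec[1], sec[2]))
    }
  }
  v
}

#' @export
print.proton_plan <- function(x, ...) {
  ls <- plan_layers(x)
  nsp <- sum(vapply(ls, function(e) nrow(e$layer$spots), numeric(1)))
  units <- if (x$modality == "impt") sprintf("%d fields", length(x$fields))
           else sprintf("%d control points", length(x$arc$control_points))
  cat(sprintf("<proton_plan> %s, %s, %d layers, %d spots, %.1f MU, %.4g Gy / %d fx\n",
              x$modality, units, length(ls), nsp, plan_total_mu(x),
              x$prescription_gy, x$fractions))
  invisible(x)
}
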