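# Synthetic study cases: phantoms, structures and machine-consistent plans
# emulating the scale and geometry of five representative disease sites,
# so the whole pipeline runs end to end without external data.

#' Disease-site presets
#'
#' Beam/arc geometry, prescriptions, fractionation and CTV volumes for the
#' five representative cases (head and neck, lung, liver, skull-base
#' chordoma, prostate). CTV radii derive from the case volumes; CTV depths
#' and per-site setup uncertainties are fixed clinically plausible choices.
#'
#' @param name Optional preset name; omit to get the full named list.
#' @return A preset list (`name`, `ctv_cc`, `rx_cgy`, `fractions`,
#'   `fields` as a gantry/couch matrix, `arc_start`, `arc_stop`,
#'   `arc_direction`, `setup_mm`, `range_frac`, `depth_cm`) or the list of
#'   all five presets.
#' @export
case_presets <- function(name = NULL) {
  p <- list(
    hn = list(name = "hn", ctv_cc = 129.07, rx_cgy = 7000, fractions = 35,
              fields = rbind(c(70, 0), c(75, 340), c(180, 0)),
              arc_start = 0, arc_stop = 180, arc_direction = 1,
              setup_mm = 3, range_frac = 0.035, depth_cm = 8),
    lung = list(name = "lung", ctv_cc = 93.88, rx_cgy = 6000, fractions = 30,
                fields = rbind(c(0, 180), c(160, 180), c(186, 180)),
                arc_start = 180, arc_stop = 360, arc_direction = 1,
                setup_mm = 5, range_frac = 0.035, depth_cm = 8),
    liver = list(name = "liver", ctv_cc = 175.93, rx_cgy = 6750, fractions = 15,
                 fields = rbind(c(130, 180), c(186, 180)),
                 arc_start = 180, arc_stop = 360, arc_direction = 1,
                 setup_mm = 5, range_frac = 0.035, depth_cm = 10),
    chordoma = list(name = "chordoma", ctv_cc = 34.15, rx_cgy = 5040,
                    fractions = 28,
                    fields = rbind(c(0, 0), c(130, 180), c(230, 180)),
                    arc_start = 0, arc_stop = 360, arc_direction = 1,
                    setup_mm = 2, range_frac = 0.035, depth_cm = 8),
    prostate = list(name = "prostate", ctv_cc = 41.42, rx_cgy = 3800,
                    fractions = 5,
                    fields = rbind(c(90, 0), c(270, 0)),
                    arc_start = 0, arc_stop = 360, arc_direction = 1,
                    setup_mm = 3, range_frac = 0.035, depth_cm = 12))
  if (is.null(name)) return(p)
  if (!name %in% names(p)) stop_sparc("unknown preset \"%s\"", name)
  p[[name]]
}

ctv_radius_cm <- function(ctv_cc) (3 * ctv_cc / (4 * pi))^(1 / 3)

#' Proton range in water from beam energy (Bragg-Kleeman power law)
#'
#' `R = 0.0022 * E^1.77` cm, the standard water parameterization; valid
#' across the machine energy span.
#'
#' @param energy_mev Beam energy, MeV.
#' @param span Allowed energy span, MeV.
#' @return Range in water, cm.
#' @export
proton_range_cm <- function(energy_mev, span = c(71.3, 228.8)) {
  if (any(energy_mev < span[1] - 1e-9 | energy_mev > span[2] + 1e-9))
    stop_sparc("energy outside machine span [%g, %g] MeV", span[1], span[2])
  0.0022 * energy_mev^1.77
}

#' Beam energy from proton range in water (inverse power law)
#'
#' @param range_cm Range in water, cm.
#' @param span Allowed energy span, MeV.
#' @return Beam energy, MeV.
#' @export
proton_energy_mev <- function(range_cm, span = c(71.3, 228.8)) {
  e <- (range_cm / 0.0022)^(1 / 1.77)
  if (any(e < span[1] - 1e-6 | e > span[2] + 1e-6))
    stop_sparc("range maps outside machine span [%g, %g] MeV", span[1], span[2])
  e
}

#' Build a water phantom with body, CTV and OAR structures
#'
#' A water-density spherical body (radius = CTV depth, so the
#' water-equivalent depth to the CTV center is gantry-angle independent)
#' with a spherical CTV at its center and one box OAR placed distal to the
#' CTV along each field's beam axis. Deterministic given the preset and
#' grid spec.
#'
#' @param preset A preset from [case_presets()].
#' @param spacing_mm Isotropic voxel spacing, mm.
#' @param margin_mm Air margin around the body, mm.
#' @return A phantom list: `density` (`dose_grid` of relative densities),
#'   `body`, `ctv`, `oar` (`structure_mask`s), grid geometry, and cached
#'   body-voxel coordinates used by the toy dose engine.
#' @export
make_phantom_and_structures <- function(preset, spacing_mm = 4, margin_mm = 8) {
  rb <- preset$depth_cm * 10           # body radius, mm
  r_ctv <- ctv_radius_cm(preset$ctv_cc) * 10
  if (r_ctv + spacing_mm > rb)
    stop_sparc("CTV (r = %.1f mm) does not fit inside body (r = %.1f mm)",
               r_ctv, rb)
  half <- rb + margin_mm
  n <- 2L * ceiling(half / spacing_mm) + 1L
  coords <- (seq_len(n) - (n + 1) / 2) * spacing_mm
  origin <- rep(coords[1], 3)

  cx <- array(coords, c(n, n, n))
  cy <- aperm(cx, c(2, 1, 3))
  cz <- aperm(cx, c(3, 2, 1))
  r2 <- cx^2 + cy^2 + cz^2
  body <- r2 <= rb^2
  ctv <- r2 <= r_ctv^2

  oar <- array(FALSE, dim(body))
  for (i in seq_len(nrow(preset$fields))) {
    th <- preset$fields[i, 1] * pi / 180
    ctr <- -c(sin(th), cos(th), 0) * (r_ctv + 30)  # 30 mm beyond CTV center
    oar <- oar | (abs(cx - ctr[1]) <= 10 & abs(cy - ctr[2]) <= 10 &
                    abs(cz - ctr[3]) <= 10)
  }
  oar <- oar & body & !ctv

  body_idx <- which(body)
  list(preset = preset,
       density = dose_grid(array(as.numeric(body), dim(body)), origin, spacing_mm),
       body = structure_mask("body", body, origin, spacing_mm),
       ctv = structure_mask("ctv", ctv, origin, spacing_mm),
       oar = structure_mask("oar", oar, origin, spacing_mm),
       spacing = spacing_mm, origin = origin, dims = dim(body),
       body_radius_mm = rb, ctv_radius_mm = r_ctv, depth_mm = rb,
       body_idx = body_idx,
       body_coords = cbind(x = cx[body_idx], y = cy[body_idx], z = cz[body_idx]),
       ctv_in_body = ctv[body_idx])
}

# machine energies whose water range falls inside the CTV depth band
ctv_energy_band <- function(phantom, machine) {
  span <- range(machine$energies)
  rng <- proton_range_cm(machine$energies, span) * 10
  lo <- phantom$depth_mm - phantom$ctv_radius_mm
  hi <- phantom$depth_mm + phantom$ctv_radius_mm
  idx <- which(rng >= lo & rng <= hi)
  if (!length(idx))
    stop_sparc("no machine energy reaches the CTV depth band [%.1f, %.1f] mm",
               lo, hi)
  idx
}

# spot lattice covering the CTV cross-section at depth offset dz (mm)
layer_spot_grid <- function(r_ctv, dz, spot_spacing, margin = 5) {
  rho <- sqrt(max(0, r_ctv^2 - dz^2)) + margin
  ax <- seq(-floor(rho / spot_spacing), floor(rho / spot_spacing)) * spot_spacing
  g <- expand.grid(x = ax, y = ax)
  g <- g[g$x^2 + g$y^2 <= rho^2, , drop = FALSE]
  if (!nrow(g)) g <- data.frame(x = 0, y = 0)
  # serpentine delivery order: snake along y within x columns
  g <- g[order(g$x, g$y), , drop = FALSE]
  flip <- as.integer(factor(g$x)) %% 2L == 0L
  g$y[flip] <- -g$y[flip]
  g[order(g$x), , drop = FALSE]
}

build_layers <- function(phantom, machine, band_idx, spot_spacing) {
  span <- range(machine$energies)
  lapply(rev(band_idx), function(i) {        # descending energy
    e <- machine$energies[i]
    dz <- proton_range_cm(e, span) * 10 - phantom$depth_mm
    g <- layer_spot_grid(phantom$ctv_radius_mm, dz, spot_spacing)
    energy_layer(e, cbind(g$x, g$y, mu = rep(1, nrow(g))))
  })
}

# draw uniform spot weights and normalize the plan total MU to
# mu_per_gy * fraction dose (delivery, and hence timing, is per fraction)
seed_and_scale <- function(plan, seed, mu_per_gy) {
  plan <- withr::with_seed(seed, {
    if (plan$modality == "impt") {
      for (i in seq_along(plan$fields))
        for (j in seq_along(plan$fields[[i]]$layers)) {
          sp <- plan$fields[[i]]$layers[[j]]$spots
          plan$fields[[i]]$layers[[j]]$spots[, "mu"] <-
            stats::runif(nrow(sp), 0.5, 1.5)
        }
    } else {
      cps <- plan$arc$control_points
      for (i in seq_along(cps))
        for (j in seq_along(cps[[i]]$layers)) {
          sp <- cps[[i]]$layers[[j]]$spots
          plan$arc$control_points[[i]]$layers[[j]]$spots[, "mu"] <-
            stats::runif(nrow(sp), 0.5, 1.5)
        }
    }
    plan
  })
  target <- mu_per_gy * plan$prescription_gy / plan$fractions
  factor <- target / plan_total_mu(plan)
  rescale <- function(l) { l$spots[, "mu"] <- l$spots[, "mu"] * factor; l }
  if (plan$modality == "impt") {
    for (i in seq_along(plan$fields))
      plan$fields[[i]]$layers <- lapply(plan$fields[[i]]$layers, rescale)
  } else {
    for (i in seq_along(plan$arc$control_points))
      plan$arc$control_points[[i]]$layers <-
        lapply(plan$arc$control_points[[i]]$layers, rescale)
  }
  plan
}

#' Generate a synthetic IMPT plan for a preset case
#'
#' Per field, one energy layer per `layer_stride`-th machine energy whose
#' water range lies within the CTV depth band (the stride emulates a
#' treatment planning system's energy-layer spacing choice, which keeps
#' static field layer counts below the arc's control-point count as in
#' clinical plan inventories), spots on a square lateral lattice covering
#' the CTV cross-section at each layer's depth plus a 5 mm margin, spot
#' weights drawn uniformly from [0.5, 1.5] (seeded) and then globally
#' scaled so the plan total MU equals `mu_per_gy` times the per-fraction
#' prescription in Gy. A deliberately simple stand-in for optimized spot
#' weights.
#'
#' @param preset A preset from [case_presets()].
#' @param phantom Phantom from [make_phantom_and_structures()].
#' @param machine A `machine_model`.
#' @param seed Integer seed; the plan is deterministic given it.
#' @param spot_spacing_mm Lateral spot lattice spacing, mm.
#' @param mu_per_gy MU normalization, MU per fraction-dose Gy.
#' @param layer_stride Take every k-th in-band machine energy (default 2).
#' @return A valid IMPT `proton_plan`.
#' @export
generate_impt_plan <- function(preset, phantom, machine, seed,
                               spot_spacing_mm = 5, mu_per_gy = 100,
                               layer_stride = 2) {
  band <- ctv_energy_band(phantom, machine)
  band <- band[seq(1, length(band), by = max(1L, layer_stride))]
  fields <- lapply(seq_len(nrow(preset$fields)), function(i)
    beam_field(preset$fields[i, 1], preset$fields[i, 2],
               build_layers(phantom, machine, band, spot_spacing_mm)))
  plan <- proton_plan("impt", preset$rx_cgy / 100, preset$fractions,
                      fields = fields)
  seed_and_scale(plan, seed, mu_per_gy)
}

#' Generate the coarse arc plan that seeds SPArc restructuring
#'
#' Control points equally spaced at `start_spacing` over the preset's arc
#' range (full arcs exclude the duplicate end angle), each carrying an
#' energy subset of the CTV depth band sized to its descendant-slot
#' capacity in the halving cascade down to `target_spacing`: every parent
#' owns `(start/target)` slots of the final grid, except the terminal
#' endpoint of a partial arc, which owns one. Filling each parent to
#' capacity lets the cascade reach exactly one energy per control point.
#' Spot lattices and MU normalization as in [generate_impt_plan()].
#'
#' @inheritParams generate_impt_plan
#' @param start_spacing Coarse sampling, degrees (default 20).
#' @param target_spacing Final sampling the plan is destined for (default
#'   2.5); only used to size the per-point energy cap.
#' @param excluded_sectors Optional list of `c(from, to)` IEC sectors.
#' @return A coarse SPArc `proton_plan` (multiple layers per control point;
#'   deliverable only after [sparc_restructure()]).
#' @export
generate_coarse_arc_plan <- function(preset, phantom, machine, seed,
                                     start_spacing = 20, target_spacing = 2.5,
                                     spot_spacing_mm = 5, mu_per_gy = 100,
                                     excluded_sectors = list()) {
  span <- abs(preset$arc_stop - preset$arc_start)
  full <- abs(span - 360) < 1e-6
  n_cp <- if (full) span / start_spacing else span / start_spacing + 1
  if (abs(n_cp - round(n_cp)) > 1e-9)
    stop_sparc("arc span %g not divisible by spacing %g", span, start_spacing)
  n_cp <- as.integer(round(n_cp))
  cap <- max(1L, as.integer(round(start_spacing / target_spacing)))

  band <- ctv_energy_band(phantom, machine)
  pick <- function(k) {
    take <- min(k, length(band))
    band[round(seq(1, length(band), length.out = take))]
  }
  caps <- rep(cap, n_cp)
  if (!full) caps[n_cp] <- 1L            # terminal endpoint owns one slot

  dirn <- preset$arc_direction
  angles <- preset$arc_start + (seq_len(n_cp) - 1L) * start_spacing * dirn
  cps <- lapply(seq_len(n_cp), function(i)
    control_point(angles[i],
                  build_layers(phantom, machine, pick(caps[i]),
                               spot_spacing_mm)))
  plan <- proton_plan("sparc", preset$rx_cgy / 100, preset$fractions,
                      arc = list(direction = dirn,
                                 start_deg = preset$arc_start,
                                 stop_deg = preset$arc_stop,
                                 control_points = cps,
                                 excluded_sectors = excluded_sectors))
  seed_and_scale(plan, seed, mu_per_gy)
}
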