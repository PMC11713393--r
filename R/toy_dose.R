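# Toy analytic dose engine: per spot, a Bragg-peak-like depth profile
# (entrance plateau + Gaussian peak at the layer range) times a lateral
# Gaussian that broadens with depth, summed over all spots and finally
# normalized so the CTV mean dose equals the prescription. Deliberately
# simple: homogeneous water, parallel (non-divergent) pencil beams,
# coplanar geometry (couch angles ignored).

#' Compute the toy dose of a plan on a phantom
#'
#' Per spot the deposited dose is
#' `mu * B(z; R) * exp(-r^2 / (2 * sigma(z)^2))` with depth profile
#' `B(z; R) = 0.3 + 0.7 * exp(-(z - R)^2 / (2 * sigma_z^2))` for
#' `z <= R + 2 * sigma_z` (zero beyond), `sigma_z = 0.02 * R`, and lateral
#' spread `sigma(z) = 3 mm + 0.02 * z`. Depth `z` is the water-equivalent
#' path from the body surface along the beam; `R` is the layer's
#' Bragg-Kleeman range, optionally scaled by `1 + range_scale`.
#'
#' @param plan A valid `proton_plan`.
#' @param phantom Phantom from [make_phantom_and_structures()].
#' @param rx_gy Prescription used for the final CTV-mean normalization.
#' @param range_scale Fractional range perturbation (default 0, nominal).
#' @param scale_factor Reuse a previously computed normalization factor
#'   (as robustness scenarios must); `NULL` normalizes CTV mean to `rx_gy`.
#' @return A `dose_grid` with the normalization factor in attribute
#'   `"scale_factor"`.
#' @export
toy_dose <- function(plan, phantom, rx_gy = plan$prescription_gy,
                     range_scale = 0, scale_factor = NULL) {
  entries <- plan_layers(plan)
  if (!length(entries)) stop_sparc("plan has no layers")
  px <- phantom$body_coords[, "x"]
  py <- phantom$body_coords[, "y"]
  pz <- phantom$body_coords[, "z"]
  rb <- phantom$body_radius_mm
  dose <- numeric(length(px))

  angles <- vapply(entries, `[[`, numeric(1), "angle_deg")
  for (th in unique(angles)) {
    a <- th * pi / 180
    w <- -(px * sin(a) + py * cos(a))          # along beam propagation
    l <- px * cos(a) - py * sin(a)             # in-plane lateral
    depth <- w + sqrt(pmax(0, rb^2 - l^2 - pz^2))
    sig <- 3 + 0.02 * depth
    cut <- 3.5 * max(sig)
    for (e in entries[angles == th]) {
      r_mm <- 10 * proton_range_cm(e$layer$energy_mev) * (1 + range_scale)
      sig_z <- 0.02 * r_mm
      bragg <- 0.3 + 0.7 * exp(-(depth - r_mm)^2 / (2 * sig_z^2))
      bragg[depth > r_mm + 2 * sig_z] <- 0
      sp <- e$layer$spots
      for (k in seq_len(nrow(sp))) {
        if (sp[k, "mu"] <= 0) next
        sel <- which(abs(l - sp[k, "x"]) <= cut & abs(pz - sp[k, "y"]) <= cut)
        if (!length(sel)) next
        r2 <- (l[sel] - sp[k, "x"])^2 + (pz[sel] - sp[k, "y"])^2
        dose[sel] <- dose[sel] +
          sp[k, "mu"] * bragg[sel] * exp(-r2 / (2 * sig[sel]^2))
      }
    }
  }

  if (is.null(scale_factor)) {
    ctv_mean <- mean(dose[phantom$ctv_in_body])
    if (ctv_mean <= 0) stop_sparc("plan deposits no dose in the CTV")
    scale_factor <- rx_gy / ctv_mean
  }
  arr <- array(0, phantom$dims)
  arr[phantom$body_idx] <- dose * scale_factor
  out <- dose_grid(arr, phantom$origin, phantom$spacing)
  attr(out, "scale_factor") <- scale_factor
  out
}
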