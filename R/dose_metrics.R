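# DVH engine and plan-quality metrics: cumulative dose-volume histograms,
# conformity index (body volume at 95% of prescription over CTV volume),
# and integral dose (mean body dose times body volume, Gy*L).

#' Cumulative dose-volume histogram of a structure
#'
#' V(d) is the fraction of masked voxels with dose >= d, evaluated at the
#' sorted unique voxel doses plus zero.
#'
#' @param dose A `dose_grid`.
#' @param mask A `structure_mask` on the same geometry.
#' @return An object of class `dvh`: `list(dose, volume, voxel_doses)` with
#'   `volume[dose == 0] == 1` and `volume` nonincreasing.
#' @export
compute_dvh <- function(dose, mask) {
  if (!same_geometry(dose, mask)) stop_sparc("dose and mask geometries differ")
  dv <- dose$values[mask$mask]
  if (!length(dv)) stop_sparc("empty structure: %s", mask$name)
  pts <- sort(unique(c(0, dv)))
  vol <- vapply(pts, function(d) mean(dv >= d), numeric(1))
  structure(list(dose = pts, volume = vol, voxel_doses = dv), class = "dvh")
}

#' Query a DVH
#'
#' `kind = "D"`: dose covering at least fraction `arg` of the volume,
#' `max(d : V(d) >= arg)` on the discrete curve (no interpolation unless
#' `interpolate = TRUE`). `kind = "V"`: volume fraction at dose >= `arg`
#' Gy. `"mean"` and `"max"` use the underlying voxel doses.
#'
#' @param dvh A `dvh` from [compute_dvh()].
#' @param kind One of `"D"`, `"V"`, `"mean"`, `"max"`.
#' @param arg Volume fraction in `(0, 1]` for `"D"`, dose in Gy for `"V"`.
#' @param interpolate Linearly interpolate `"D"` queries on the curve.
#' @return Dose in Gy (`"D"`, `"mean"`, `"max"`) or a volume fraction (`"V"`).
#' @export
dvh_query <- function(dvh, kind = c("D", "V", "mean", "max"), arg = NULL,
                      interpolate = FALSE) {
  kind <- match.arg(kind)
  dv <- dvh$voxel_doses
  switch(kind,
    D = {
      if (!is_number(arg) || arg <= 0 || arg > 1)
        stop_sparc("volume fraction for D must be in (0, 1]")
      if (interpolate)
        as.numeric(stats::quantile(dv, probs = 1 - arg, type = 7, names = FALSE))
      else
        max(dvh$dose[dvh$volume >= arg])
    },
    V = mean(dv >= arg),
    mean = mean(dv),
    max = max(dv))
}

#' Conformity index
#'
#' Body volume receiving at least 95% of the prescription dose divided by
#' the CTV volume (volumes from voxel counts times voxel volume).
#'
#' @param dose A `dose_grid`.
#' @param body,ctv `structure_mask`s on the same geometry.
#' @param rx Prescription dose, Gy (> 0).
#' @param level Isodose level as a fraction of `rx` (default 0.95).
#' @return The (dimensionless) conformity index.
#' @export
conformity_index <- function(dose, body, ctv, rx, level = 0.95) {
  if (!sum(ctv$mask)) stop_sparc("empty structure: %s", ctv$name)
  if (!is_number(rx) || rx <= 0) stop_sparc("prescription must be positive")
  sum(body$mask & dose$values >= level * rx) / sum(ctv$mask)
}

#' Integral dose
#'
#' Mean dose over the body (Gy) times body volume (liters), a whole-body
#' dose-bath measure in Gy*L.
#'
#' @param dose A `dose_grid`.
#' @param body A `structure_mask` on the same geometry.
#' @return Integral dose, Gy*L.
#' @export
integral_dose <- function(dose, body) {
  n <- sum(body$mask)
  if (!n) stop_sparc("empty structure: %s", body$name)
  mean(dose$values[body$mask]) * n * voxel_volume_cc(body) / 1000
}
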