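# Worst-case robustness evaluation: setup-shift and range-scale
# perturbation scenarios, and the nominal (min~max) metric summaries.

#' Generate the worst-case perturbation scenarios
#'
#' Cartesian product of the 7 setup shifts (plus/minus the setup
#' uncertainty along each axis, and zero) with the 3 range scalings
#' (minus, zero, plus the range uncertainty), minus the nominal
#' zero-shift/zero-scale combination: exactly 20 scenarios, in a
#' deterministic order (shift axis, then sign, then scaling).
#'
#' @param setup_mm Setup uncertainty, mm.
#' @param range_frac Range uncertainty as a fraction (e.g. 0.035).
#' @return A data.frame with columns `shift_x_mm`, `shift_y_mm`,
#'   `shift_z_mm`, `range_scale` (20 rows).
#' @export
make_scenarios <- function(setup_mm, range_frac) {
  if (setup_mm <= 0 && range_frac <= 0)
    stop_sparc("degenerate scenario set: both uncertainties are zero")
  shifts <- rbind(c(setup_mm, 0, 0), c(-setup_mm, 0, 0),
                  c(0, setup_mm, 0), c(0, -setup_mm, 0),
                  c(0, 0, setup_mm), c(0, 0, -setup_mm),
                  c(0, 0, 0))
  scales <- c(-range_frac, 0, range_frac)
  grid <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(i)
    data.frame(shift_x_mm = shifts[i, 1], shift_y_mm = shifts[i, 2],
               shift_z_mm = shifts[i, 3], range_scale = scales)))
  nominal <- rowSums(abs(grid)) == 0
  grid <- grid[!nominal, , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Bundle a plan, phantom and dose engine for robustness evaluation
#'
#' When `plan` is given, perturbed doses are recomputed with the toy dose
#' engine (range scalings change every layer's range, and the nominal
#' global scale factor is reused so perturbations actually move the CTV
#' metrics). When only `dose` is given, the dose is treated as fixed under
#' range scaling (setup shifts still translate it).
#'
#' @param phantom A phantom list from [make_phantom_and_structures()], or
#'   any list with `body` and `ctv` `structure_mask`s.
#' @param rx Prescription dose, Gy.
#' @param plan Optional `proton_plan` driving the toy dose engine.
#' @param dose Optional precomputed nominal `dose_grid`.
#' @return An object of class `robustness_case`.
#' @export
robustness_case <- function(phantom, rx, plan = NULL, dose = NULL) {
  if (is.null(plan) && is.null(dose))
    stop_sparc("robustness case needs a plan or a dose")
  if (is.null(dose)) dose <- toy_dose(plan, phantom, rx)
  structure(list(plan = plan, phantom = phantom, rx = rx, dose = dose,
                 scale_factor = attr(dose, "scale_factor")),
            class = "robustness_case")
}

#' Perturbed dose for one scenario
#'
#' Range scaling recomputes the toy dose with every layer's range replaced
#' by `R * (1 + scale)` under the nominal normalization factor; the setup
#' shift then translates the grid by the shift vector (nearest voxel). The
#' zero scenario returns the nominal dose unchanged.
#'
#' @param case A `robustness_case`.
#' @param scenario One row of [make_scenarios()] output (or a list with
#'   `shift_x_mm`, `shift_y_mm`, `shift_z_mm`, `range_scale`).
#' @return A `dose_grid`.
#' @export
apply_scenario <- function(case, scenario) {
  d <- if (scenario$range_scale != 0 && !is.null(case$plan))
    toy_dose(case$plan, case$phantom, case$rx,
             range_scale = scenario$range_scale,
             scale_factor = case$scale_factor)
  else case$dose
  translate_dose(d, c(scenario$shift_x_mm, scenario$shift_y_mm,
                      scenario$shift_z_mm))
}

ctv_metrics <- function(dose, ctv, rx) {
  dv <- dose$values[ctv$mask]
  sorted <- sort(dv, decreasing = TRUE)
  d95 <- sorted[ceiling(0.95 * length(sorted))]
  c(mean = mean(dv) / rx * 100,
    D95 = d95 / rx * 100,
    V95 = mean(dv >= 0.95 * rx) * 100)
}

#' Worst-case robustness table for one plan
#'
#' Recomputes the dose for the nominal case and every scenario and reports
#' the CTV mean dose, D95 and V95 as percentages of the prescription,
#' summarized as the nominal value with the (min ~ max) envelope over the
#' evaluation set (nominal included).
#'
#' @param case A `robustness_case`.
#' @param scenarios Scenario data.frame from [make_scenarios()].
#' @return An object of class `robustness_table`: a data.frame with columns
#'   `metric`, `nominal`, `min`, `max`, `formatted`.
#' @export
evaluate_robustness <- function(case, scenarios) {
  rx <- case$rx
  ctv <- case$phantom$ctv
  nominal <- ctv_metrics(case$dose, ctv, rx)

  # cache the range-scaled dose computations (shifts are translations)
  scale_cache <- list("0" = case$dose)
  per <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    key <- format(sc$range_scale, digits = 10)
    if (is.null(scale_cache[[key]])) {
      d <- if (!is.null(case$plan))
        toy_dose(case$plan, case$phantom, rx, range_scale = sc$range_scale,
                 scale_factor = case$scale_factor)
      else case$dose
      scale_cache[[key]] <<- d
    }
    shifted <- translate_dose(scale_cache[[key]],
                              c(sc$shift_x_mm, sc$shift_y_mm, sc$shift_z_mm))
    tryCatch(ctv_metrics(shifted, ctv, rx),
             error = function(e) stop_sparc(
               "scenario %d (shift [%g,%g,%g] mm, scale %g): %s", i,
               sc$shift_x_mm, sc$shift_y_mm, sc$shift_z_mm, sc$range_scale,
               conditionMessage(e)))
  })
  mat <- rbind(nominal, do.call(rbind, per))
  out <- data.frame(metric = colnames(mat),
                    nominal = nominal,
                    min = apply(mat, 2, min),
                    max = apply(mat, 2, max))
  out$formatted <- sprintf("%.2f (%.2f∼%.2f)", out$nominal, out$min, out$max)
  rownames(out) <- NULL
  structure(out, class = c("robustness_table", "data.frame"))
}
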