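# End-to-end orchestration: synthesize a case, build IMPT and SPArc plans,
# compute toy doses, plan-quality and robustness metrics, and both delivery
# times, and emit comparison tables.

default_run_config <- function() {
  list(grid_spacing_mm = 4, margin_mm = 8, spot_spacing_mm = 5,
       mu_per_gy = 100, layer_stride = 2,
       start_spacing = 20, target_spacing = 2.5,
       filter_theta = 0.1, couch_time = 0, excluded_sectors = list(),
       verbose = TRUE)
}

#' Run the full analysis for one disease-site preset
#'
#' Generates the phantom and an IMPT plan, builds the SPArc plan by
#' restructuring a coarse 20-degree arc, computes toy doses for both,
#' and derives the plan-quality table (CTV D99, OAR max/mean, conformity
#' index, integral dose), the worst-case robustness table, and the
#' static/dynamic delivery-time comparison with percentage increments
#' `(SPArc - IMPT) / IMPT * 100`. Deterministic given `seed`.
#'
#' @param preset_name One of `"hn"`, `"lung"`, `"liver"`, `"chordoma"`,
#'   `"prostate"`.
#' @param seed Integer seed.
#' @param config Named list overriding any of: `grid_spacing_mm`,
#'   `margin_mm`, `spot_spacing_mm`, `mu_per_gy`, `layer_stride`,
#'   `start_spacing`,
#'   `target_spacing`, `filter_theta`, `couch_time`, `excluded_sectors`,
#'   `verbose`.
#' @param machine A `machine_model` (default [default_machine_model()]).
#' @param gantry A `gantry_model`.
#' @return A `sparc_run` list: plans, doses, `metrics`, `robustness`,
#'   `timing` (one-row data.frame), delivery `reports`, and a `manifest`
#'   of every configuration value.
#' @export
run_case <- function(preset_name, seed, config = list(),
                     machine = default_machine_model(),
                     gantry = gantry_model()) {
  cfg <- utils::modifyList(default_run_config(), config)
  log_msg <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop_sparc("stage \"%s\" (preset %s, seed %d) failed: %s",
                 name, preset_name, seed, conditionMessage(e)))
    log_msg("[%s] %-22s %6.1f s", preset_name, name,
            proc.time()[["elapsed"]] - t0)
    out
  }

  preset <- case_presets(preset_name)
  rx <- preset$rx_cgy / 100
  phantom <- stage("phantom", make_phantom_and_structures(
    preset, cfg$grid_spacing_mm, cfg$margin_mm))
  impt <- stage("impt plan", generate_impt_plan(
    preset, phantom, machine, seed, cfg$spot_spacing_mm, cfg$mu_per_gy,
    cfg$layer_stride))
  coarse <- stage("coarse arc", generate_coarse_arc_plan(
    preset, phantom, machine, seed + 1L, cfg$start_spacing,
    cfg$target_spacing, cfg$spot_spacing_mm, cfg$mu_per_gy,
    cfg$excluded_sectors))
  sparc <- stage("restructure", sparc_restructure(
    coarse, cfg$target_spacing, cfg$filter_theta))

  dose_impt <- stage("impt dose", toy_dose(impt, phantom, rx))
  dose_sparc <- stage("sparc dose", toy_dose(sparc, phantom, rx))

  metrics <- stage("metrics", {
    row <- function(structure, value, f) {
      vi <- f(dose_impt); vs <- f(dose_sparc)
      data.frame(structure = structure, value = value,
                 impt = vi, sparc = vs, difference = vi - vs)
    }
    rbind(
      row("CTV", "D99 (Gy)", function(d)
        dvh_query(compute_dvh(d, phantom$ctv), "D", 0.99)),
      row("OAR", "Max (Gy)", function(d)
        dvh_query(compute_dvh(d, phantom$oar), "max")),
      row("OAR", "Mean (Gy)", function(d)
        dvh_query(compute_dvh(d, phantom$oar), "mean")),
      row("Body", "CI", function(d)
        conformity_index(d, phantom$body, phantom$ctv, rx)),
      row("Body", "ID (Gy*L)", function(d) integral_dose(d, phantom$body)))
  })

  robustness <- stage("robustness", {
    sc <- make_scenarios(preset$setup_mm, preset$range_frac)
    tab <- lapply(list(impt = list(impt, dose_impt),
                       sparc = list(sparc, dose_sparc)), function(pd) {
      evaluate_robustness(robustness_case(phantom, rx, plan = pd[[1]],
                                          dose = pd[[2]]), sc)
    })
    out <- rbind(cbind(modality = "impt", as.data.frame(tab$impt)),
                 cbind(modality = "sparc", as.data.frame(tab$sparc)))
    rownames(out) <- NULL
    out
  })

  reports <- stage("delivery time", list(
    impt_static = plan_bdt_static(impt, machine),
    impt_dynamic = impt_bdt_dynamic(impt, machine, gantry,
                                    couch_time = cfg$couch_time),
    sparc_static = plan_bdt_static(sparc, machine),
    sparc_dynamic = sparc_bdt_dynamic(sparc, machine, gantry)))

  timing <- data.frame(
    site = preset_name,
    impt_bdt_s = reports$impt_static$bdt_s,
    impt_bdt_d = reports$impt_dynamic$bdt_d,
    sparc_bdt_s = reports$sparc_static$bdt_s,
    sparc_bdt_d = reports$sparc_dynamic$bdt_d)
  timing$bdt_s_increment_pct <-
    (timing$sparc_bdt_s - timing$impt_bdt_s) / timing$impt_bdt_s * 100
  timing$bdt_d_increment_pct <-
    (timing$sparc_bdt_d - timing$impt_bdt_d) / timing$impt_bdt_d * 100

  manifest <- list(preset = preset_name, seed = seed,
                   config = cfg[setdiff(names(cfg), "verbose")],
                   prescription_gy = rx, fractions = preset$fractions,
                   n_impt_layers = length(plan_layers(impt)),
                   n_sparc_control_points = length(sparc$arc$control_points),
                   total_mu = plan_total_mu(impt))
  structure(list(preset = preset, phantom = phantom,
                 plans = list(impt = impt, coarse = coarse, sparc = sparc),
                 doses = list(impt = dose_impt, sparc = dose_sparc),
                 metrics = metrics, robustness = robustness,
                 timing = timing, reports = reports, manifest = manifest),
            class = "sparc_run")
}

#' Multi-case delivery-time comparison table
#'
#' Stacks the per-case timing rows and appends the unweighted `Average`
#' row; increment columns are recomputed from the absolute columns.
#'
#' @param runs A list of `sparc_run` objects (or their `timing` rows).
#' @return A data.frame in the delivery-time comparison layout.
#' @export
timing_table <- function(runs) {
  rows <- do.call(rbind, lapply(runs, function(r)
    if (inherits(r, "sparc_run")) r$timing else r))
  avg <- data.frame(site = "Average",
                    impt_bdt_s = mean(rows$impt_bdt_s),
                    impt_bdt_d = mean(rows$impt_bdt_d),
                    sparc_bdt_s = mean(rows$sparc_bdt_s),
                    sparc_bdt_d = mean(rows$sparc_bdt_d),
                    bdt_s_increment_pct = mean(rows$bdt_s_increment_pct),
                    bdt_d_increment_pct = mean(rows$bdt_d_increment_pct))
  rbind(rows, avg)
}

#' Write a run's report bundle to a directory
#'
#' Emits the canonical plan files, the metric, robustness and timing CSVs,
#' per-unit delivery reports, and a JSON manifest carrying every
#' configuration value and the MD5 hash of each written file. With
#' `write_doses = TRUE` the dose grids are also written as ascii NRRD.
#'
#' @param run A `sparc_run` from [run_case()].
#' @param dir Output directory (created if needed).
#' @param write_doses Also write dose grids (large text files).
#' @return The manifest path, invisibly.
#' @export
write_report_bundle <- function(run, dir, write_doses = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_plan(run$plans$impt, p("impt_plan.json"))
  write_plan(run$plans$sparc, p("sparc_plan.json"))
  utils::write.csv(run$metrics, p("metrics.csv"), row.names = FALSE)
  utils::write.csv(run$robustness, p("robustness.csv"), row.names = FALSE)
  utils::write.csv(run$timing, p("timing.csv"), row.names = FALSE)
  for (nm in names(run$reports))
    write_delivery_report(run$reports[[nm]], p(paste0(nm, ".csv")))
  if (write_doses) {
    write_nrrd(run$doses$impt, p("impt_dose.nrrd"))
    write_nrrd(run$doses$sparc, p("sparc_dose.nrrd"))
  }
  files <- setdiff(list.files(dir, full.names = TRUE),
                   p("manifest.json"))
  manifest <- run$manifest
  manifest$files <- lapply(files, function(f)
    list(name = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(p("manifest.json"))
}

#' @export
print.sparc_run <- function(x, ...) {
  cat(sprintf("<sparc_run> %s: IMPT %d layers, SPArc %d control points\n",
              x$preset$name, x$manifest$n_impt_layers,
              x$manifest$n_sparc_control_points))
  print(x$timing, row.names = FALSE)
  invisible(x)
}
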