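test_that("the range-energy power law is monotone and self-inverse", {
  expect_equal(proton_range_cm(71.3), 0.0022 * 71.3^1.77, tolerance = 1e-12)
  expect_equal(proton_range_cm(71.3), 4.19, tolerance = 0.01)
  expect_equal(proton_range_cm(228.8), 33.0, tolerance = 0.15)
  en <- default_machine_model()$energies
  expect_equal(proton_energy_mev(proton_range_cm(en)), en, tolerance = 1e-9)
  expect_true(all(diff(proton_range_cm(en)) > 0))
  expect_error(proton_range_cm(50), "outside machine span")
  expect_error(proton_energy_mev(40), "outside machine span")
})

test_that("phantoms are deterministic with nested structures", {
  p <- toy_preset()
  ph1 <- make_phantom_and_structures(p, spacing_mm = 3)
  ph2 <- make_phantom_and_structures(p, spacing_mm = 3)
  expect_identical(ph1$density$values, ph2$density$values)
  expect_identical(ph1$ctv$mask, ph2$ctv$mask)
  expect_true(all(ph1$body$mask[ph1$ctv$mask]))
  expect_true(all(ph1$body$mask[ph1$oar$mask]))
  expect_false(any(ph1$ctv$mask & ph1$oar$mask))
})

test_that("voxelized CTV volume approaches the analytic sphere volume", {
  p <- case_presets("prostate")
  ph <- make_phantom_and_structures(p, spacing_mm = 2)
  vol_cc <- sum(ph$ctv$mask) * voxel_volume_cc(ph$ctv)
  expect_lt(abs(vol_cc - p$ctv_cc) / p$ctv_cc, 0.05)
})

test_that("a too-large CTV is rejected", {
  p <- toy_preset()
  p$ctv_cc <- 4 / 3 * pi * 5^3   # radius 5 cm > 4 cm body
  expect_error(make_phantom_and_structures(p, 3), "does not fit")
})

test_that("generated IMPT plans select only in-band energies and normalize MU", {
  m <- default_machine_model()
  for (nm in names(case_presets())) {
    p <- case_presets(nm)
    ph <- make_phantom_and_structures(p, spacing_mm = 8)
    plan <- generate_impt_plan(p, ph, m, seed = 4)
    expect_identical(validate_plan(plan, m), character(0))
    expect_length(plan$fields, nrow(p$fields))
    expect_equal(vapply(plan$fields, `[[`, numeric(1), "gantry_deg"),
                 p$fields[, 1] %% 360)
    lo <- ph$depth_mm - ph$ctv_radius_mm
    hi <- ph$depth_mm + ph$ctv_radius_mm
    rng <- vapply(plan_layers(plan),
                  function(e) proton_range_cm(e$layer$energy_mev) * 10,
                  numeric(1))
    expect_true(all(rng >= lo & rng <= hi))
    expect_equal(plan_total_mu(plan), 100 * p$rx_cgy / 100 / p$fractions,
                 tolerance = 1e-6)
  }
})

test_that("the energy-layer stride thins fields without leaving the band", {
  m <- default_machine_model()
  p <- case_presets("liver")
  ph <- make_phantom_and_structures(p, spacing_mm = 8)
  dense <- generate_impt_plan(p, ph, m, seed = 4, layer_stride = 1)
  thin <- generate_impt_plan(p, ph, m, seed = 4, layer_stride = 2)
  n_dense <- length(dense$fields[[1]]$layers)
  n_thin <- length(thin$fields[[1]]$layers)
  expect_equal(n_thin, ceiling(n_dense / 2))
  expect_true(all(vapply(thin$fields[[1]]$layers, `[[`, numeric(1),
                         "energy_mev") %in%
                  vapply(dense$fields[[1]]$layers, `[[`, numeric(1),
                         "energy_mev")))
})

test_that("the energy band excludes adjacent out-of-band machine energies", {
  m <- default_machine_model()
  ph <- make_phantom_and_structures(toy_preset(), spacing_mm = 4)
  plan <- generate_impt_plan(toy_preset(), ph, m, seed = 1)
  used <- sort(unique(vapply(plan_layers(plan), function(e)
    e$layer$energy_mev, numeric(1))))
  idx <- match(used, m$energies)
  below <- idx[1] - 1L
  above <- idx[length(idx)] + 1L
  lo <- ph$depth_mm - ph$ctv_radius_mm
  hi <- ph$depth_mm + ph$ctv_radius_mm
  if (below >= 1)
    expect_false(proton_range_cm(m$energies[below]) * 10 >= lo)
  if (above <= 97)
    expect_false(proton_range_cm(m$energies[above]) * 10 <= hi)
})

test_that("plan generation is bitwise deterministic under a fixed seed", {
  m <- default_machine_model()
  p <- toy_preset()
  ph <- make_phantom_and_structures(p, spacing_mm = 4)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_plan(generate_impt_plan(p, ph, m, seed = 99), f1)
  write_plan(generate_impt_plan(p, ph, m, seed = 99), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile()
  write_plan(generate_impt_plan(p, ph, m, seed = 100), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("a single central spot peaks at its Bragg range", {
  m <- default_machine_model()
  p <- toy_preset()
  ph <- make_phantom_and_structures(p, spacing_mm = 2)
  e <- m$energies[4]                       # range ~4.6 cm, inside the body
  plan <- proton_plan("impt", 20, 10, fields = list(
    beam_field(0, 0, list(energy_layer(e, c(0, 0, 10))))))
  d <- toy_dose(plan, ph, rx_gy = 20, scale_factor = 1)
  # beam from gantry 0 travels along -y; profile on the central axis
  mid <- (ph$dims[1] + 1) / 2
  axis <- d$values[mid, , mid]
  ys <- (seq_len(ph$dims[2]) - mid) * ph$spacing
  depth <- -ys + ph$body_radius_mm         # water-equivalent depth at theta = 0
  r_mm <- proton_range_cm(e) * 10
  expect_lte(abs(depth[which.max(axis)] - r_mm), ph$spacing + 1e-9)
})

test_that("toy dose is additive and linear in spot weight", {
  m <- default_machine_model()
  p <- toy_preset()
  ph <- make_phantom_and_structures(p, spacing_mm = 4)
  la <- energy_layer(m$energies[2], c(0, 0, 5))
  lb <- energy_layer(m$energies[8], c(4, -4, 3))
  mk <- function(layers) proton_plan("impt", 20, 10, fields = list(
    beam_field(90, 0, layers)))
  da <- toy_dose(mk(list(la)), ph, scale_factor = 1)
  db <- toy_dose(mk(list(lb)), ph, scale_factor = 1)
  dab <- toy_dose(mk(list(la, lb)), ph, scale_factor = 1)
  expect_equal(dab$values, da$values + db$values, tolerance = 1e-12)

  la2 <- energy_layer(m$energies[2], c(0, 0, 10))
  da2 <- toy_dose(mk(list(la2)), ph, scale_factor = 1)
  expect_equal(da2$values, 2 * da$values, tolerance = 1e-12)
})

test_that("a range scale pushes the Bragg peak distally by about 3.5%", {
  m <- default_machine_model()
  p <- toy_preset()
  ph <- make_phantom_and_structures(p, spacing_mm = 1)
  e <- m$energies[3]                       # range ~4.5 cm
  plan <- proton_plan("impt", 20, 10, fields = list(
    beam_field(0, 0, list(energy_layer(e, c(0, 0, 10))))))
  d0 <- toy_dose(plan, ph, scale_factor = 1)
  d1 <- toy_dose(plan, ph, scale_factor = 1, range_scale = 0.035)
  mid <- (ph$dims[1] + 1) / 2
  depth <- -((seq_len(ph$dims[2])) - mid) * ph$spacing + ph$body_radius_mm
  r_mm <- proton_range_cm(e) * 10
  shift <- depth[which.max(d1$values[mid, , mid])] -
    depth[which.max(d0$values[mid, , mid])]
  expect_equal(shift, 0.035 * r_mm, tolerance = ph$spacing * 1.5)
})
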