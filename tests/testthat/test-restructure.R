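test_that("layers interleave between children by descending energy", {
  mk <- function(e) energy_layer(e, c(0, 0, 1))
  kids <- redistribute_layers(list(mk(100), mk(160), mk(120), mk(140)))
  expect_equal(vapply(kids[[1]], `[[`, numeric(1), "energy_mev"), c(160, 120))
  expect_equal(vapply(kids[[2]], `[[`, numeric(1), "energy_mev"), c(140, 100))

  kids <- redistribute_layers(list(mk(100)))
  expect_length(kids[[1]], 1)
  expect_length(kids[[2]], 0)
})

test_that("three halvings spread 8 layers to 8 single-layer control points", {
  m <- default_machine_model()
  es <- m$energies[c(8, 7, 6, 5, 4, 3, 2, 1)]   # ranks 1..8 by energy
  plan <- coarse_arc(m, seq(0, 340, by = 20), list(es), stop_deg = 360)
  out <- split_control_points(plan, 2.5)
  cps <- out$arc$control_points
  expect_length(cps, 144)
  expect_true(all(vapply(cps, function(cp) length(cp$layers), numeric(1)) == 1))
  # the first parent's sector: bit-reversed rank order derived by hand
  sector <- cps[1:8]
  expect_equal(vapply(sector, `[[`, numeric(1), "angle_deg"),
               seq(0, 17.5, by = 2.5))
  got <- vapply(sector, function(cp) cp$layers[[1]]$energy_mev, numeric(1))
  expect_equal(match(got, sort(es, decreasing = TRUE)),
               c(1, 5, 3, 7, 2, 6, 4, 8))
})

test_that("splitting hits the published control-point counts", {
  m <- default_machine_model()
  es8 <- m$energies[seq(1, 29, by = 4)]
  full <- coarse_arc(m, seq(0, 340, by = 20), list(es8), stop_deg = 360)
  out <- split_control_points(full, 2.5)
  expect_length(out$arc$control_points, 144)
  expect_equal(diff(vapply(out$arc$control_points, `[[`, numeric(1),
                           "angle_deg")), rep(2.5, 143))

  # partial 180-degree arc: 73 grid slots; load 9 x 8 + 1 layers to fill all
  partial <- coarse_arc(m, seq(0, 180, by = 20),
                        c(rep(list(es8), 9), list(es8[1])), stop_deg = 180)
  out <- split_control_points(partial, 2.5)
  expect_length(out$arc$control_points, 73)
  expect_identical(validate_plan(out, m), character(0))

  unchanged <- split_control_points(full, 20)
  expect_equal(unchanged, full)
  expect_error(split_control_points(full, 3), "power of two")
})

test_that("a loaded partial-arc endpoint sheds surplus layers to empty slots", {
  m <- default_machine_model()
  es7 <- m$energies[seq(1, 25, by = 4)]
  plan <- coarse_arc(m, seq(0, 180, by = 20), list(es7), stop_deg = 180)
  out <- split_control_points(plan, 2.5)
  nl <- vapply(out$arc$control_points, function(cp) length(cp$layers), numeric(1))
  expect_true(all(nl == 1))
  expect_equal(plan_total_mu(out), plan_total_mu(plan))
  expect_length(out$arc$control_points, 70)      # 10 parents x 7 layers
})

test_that("low-weight filtration removes light layers and conserves MU", {
  m <- flat_machine(energies = c(90, 100, 110))
  mk_cp <- function(a, e, mu) control_point(a, energy_layer(e, c(0, 0, mu)))
  plan <- proton_plan("sparc", 60, 30, arc = list(
    direction = 1, start_deg = 0, stop_deg = 5,
    control_points = list(mk_cp(0, 90, 10), mk_cp(2.5, 100, 10),
                          mk_cp(5, 110, 0.1))))
  out <- filter_low_weight(plan, 0.1)
  mus <- vapply(plan_layers(out), function(e) layer_mu(e$layer), numeric(1))
  expect_equal(mus, c(10.05, 10.05))
  expect_equal(plan_total_mu(out), 20.1)
  expect_length(out$arc$control_points, 2)

  expect_equal(filter_low_weight(plan, 0), plan)

  equal_plan <- proton_plan("sparc", 60, 30, arc = list(
    direction = 1, start_deg = 0, stop_deg = 5,
    control_points = list(mk_cp(0, 90, 5), mk_cp(2.5, 100, 5),
                          mk_cp(5, 110, 5))))
  expect_length(plan_layers(filter_low_weight(equal_plan, 1)), 3)
})

test_that("the heaviest layer always survives filtration", {
  m <- flat_machine(energies = c(90, 100))
  plan <- proton_plan("sparc", 60, 30, arc = list(
    direction = 1, start_deg = 0, stop_deg = 2.5,
    control_points = list(
      control_point(0, energy_layer(90, c(0, 0, 1))),
      control_point(2.5, energy_layer(100, c(0, 0, 0.1))))))
  out <- filter_low_weight(plan, 10)   # absurd threshold removes all but max
  expect_length(plan_layers(out), 1)
  expect_equal(plan_total_mu(out), 1.1)
})

test_that("full restructure conserves MU and yields a deliverable arc", {
  m <- default_machine_model()
  withr::with_seed(23, {
    for (rep in 1:4) {
      n_layers <- sample(3:8, 1)
      es <- sample(m$energies, n_layers)
      parents <- seq(0, 340, by = 20)
      plan <- coarse_arc(m, parents, list(es), stop_deg = 360,
                         mu = runif(1, 0.5, 20))
      out <- sparc_restructure(plan, 2.5, filter_theta = 0.1)
      expect_equal(plan_total_mu(out), plan_total_mu(plan),
                   tolerance = 1e-9)
      expect_identical(validate_plan(out, m), character(0))
      ang <- vapply(out$arc$control_points, `[[`, numeric(1), "angle_deg")
      expect_true(all(diff(ang) > 0))
      expect_lte(length(plan_layers(out)), length(plan_layers(plan)))
    }
  })
})

test_that("excluded sectors end up with no control points", {
  m <- default_machine_model()
  es4 <- m$energies[c(1, 5, 9, 13)]
  plan <- coarse_arc(m, seq(0, 340, by = 20), list(es4), stop_deg = 360)
  plan$arc$excluded_sectors <- list(c(85, 115))
  out <- sparc_restructure(plan, 2.5)
  ang <- vapply(out$arc$control_points, `[[`, numeric(1), "angle_deg") %% 360
  expect_false(any(ang >= 85 & ang <= 115))
  expect_equal(plan_total_mu(out), plan_total_mu(plan), tolerance = 1e-9)
  expect_identical(validate_plan(out, m), character(0))
})
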