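# Shared fixtures: small machines, random layers/plans, and a toy preset
# whose phantom is small enough for fast dose computations.

flat_machine <- function(energies = 100, t_lsw = 2, spill_rate = 8,
                         t_smag = 0.002, q_max = 2, charge_per_mu = 0.01,
                         t_hold = 8, v_x = 5000, v_y = 17000) {
  machine_model(energies = energies, t_lsw = t_lsw, spill_rate = spill_rate,
                t_smag = t_smag, q_max = q_max, charge_per_mu = charge_per_mu,
                t_hold = t_hold, v_x = v_x, v_y = v_y)
}

rand_layer <- function(energy, n_spots, mu_max = 50) {
  n <- max(1L, n_spots)
  energy_layer(energy, cbind(stats::runif(n, -50, 50),
                             stats::runif(n, -50, 50),
                             stats::runif(n, 0, mu_max / n)))
}

rand_impt_plan <- function(machine, n_fields = 2, n_layers = 3, n_spots = 5) {
  g <- sort(stats::runif(n_fields, 0, 359))
  fields <- lapply(g, function(a) {
    idx <- sample(seq_along(machine$energies), n_layers)
    beam_field(a, 0, lapply(machine$energies[idx], rand_layer,
                            n_spots = n_spots))
  })
  proton_plan("impt", 60, 30, fields = fields)
}

rand_sparc_plan <- function(machine, n_cp = 8, n_spots = 5, span = 180) {
  ang <- seq(0, span, length.out = n_cp)
  idx <- sample(seq_along(machine$energies), n_cp, replace = TRUE)
  cps <- lapply(seq_len(n_cp), function(i)
    control_point(ang[i], rand_layer(machine$energies[idx[i]], n_spots)))
  proton_plan("sparc", 60, 30,
              arc = list(direction = 1, start_deg = 0, stop_deg = span,
                         control_points = cps))
}

# compact test case: 4 cm deep 1 cm CTV, so the phantom is ~27^3 voxels
toy_preset <- function() {
  list(name = "toy", ctv_cc = 4 / 3 * pi, rx_cgy = 2000, fractions = 10,
       fields = rbind(c(0, 0), c(180, 0)),
       arc_start = 0, arc_stop = 360, arc_direction = 1,
       setup_mm = 3, range_frac = 0.035, depth_cm = 4)
}

# multi-layer coarse arc for restructuring tests: n_parents control points
# carrying the given energies each (descending applied internally)
coarse_arc <- function(machine, parent_angles, energies_per_parent,
                       stop_deg, mu = 1) {
  cps <- lapply(seq_along(parent_angles), function(k) {
    es <- energies_per_parent[[min(k, length(energies_per_parent))]]
    control_point(parent_angles[k],
                  lapply(es, function(e) energy_layer(e, c(0, 0, mu))))
  })
  proton_plan("sparc", 60, 30,
              arc = list(direction = 1, start_deg = parent_angles[1],
                         stop_deg = stop_deg, control_points = cps))
}
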