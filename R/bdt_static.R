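# Static beam delivery time for a single-energy-extraction synchrotron.
#
# Per layer i the time decomposes into three components:
#   switch: t_lsw(E_i) * (1 + mEX_i + mMU_i)   -- acceleration cycles
#   spill:  MU_i / spill_rate(E_i)             -- slow extraction
#   spot:   sum over the Nspot-1 inter-spot moves of
#           |dx|/Vx(E_i) + |dy|/Vy(E_i) + t_smag
# Extra cycles arise when one acceleration's charge cannot cover the layer
# MU (mEX) or when the spill would outlast the stable hold time (mMU).

#' Extra acceleration cycles needed by an energy layer
#'
#' `m_ex` counts the additional cycles required when the layer charge
#' (MU times charge-per-MU) exceeds what one acceleration holds (`q_max`);
#' `m_mu` counts the additional cycles required when the spill time
#' (MU over spill rate) exceeds the maximum stable hold time. A layer with
#' zero MU needs neither.
#'
#' @param layer An `energy_layer`.
#' @param machine A `machine_model`.
#' @return `list(m_ex =, m_mu =)`, both non-negative integer counts.
#' @export
extra_cycles <- function(layer, machine) {
  mu <- layer_mu(layer)
  if (mu <= 0) return(list(m_ex = 0L, m_mu = 0L))
  i <- machine_energy_index(machine, layer$energy_mev)
  if (is.na(i)) stop_sparc("layer energy %.3f MeV not in machine list",
                           layer$energy_mev)
  m_ex <- max(0L, as.integer(ceiling(mu * machine$charge_per_mu[i] /
                                       machine$q_max)) - 1L)
  m_mu <- max(0L, as.integer(ceiling(mu / machine$spill_rate[i] /
                                       machine$t_hold)) - 1L)
  list(m_ex = m_ex, m_mu = m_mu)
}

#' Static delivery time of one energy layer
#'
#' @param layer An `energy_layer`.
#' @param machine A `machine_model`.
#' @return An object of class `layer_timing`:
#'   `list(n_cycles, t_switch, t_spill, t_spot, total)`, seconds.
#' @export
layer_delivery_time <- function(layer, machine) {
  i <- machine_energy_index(machine, layer$energy_mev)
  if (is.na(i)) stop_sparc("layer energy %.3f MeV not in machine list",
                           layer$energy_mev)
  if (machine$spill_rate[i] <= 0) stop_sparc("spill rate must be positive")
  m <- extra_cycles(layer, machine)
  n_cycles <- 1L + m$m_ex + m$m_mu
  t_switch <- machine$t_lsw[i] * n_cycles
  t_spill <- layer_mu(layer) / machine$spill_rate[i]
  sp <- layer$spots
  n <- nrow(sp)
  t_spot <- if (n < 2L) 0 else {
    dx <- abs(diff(sp[, "x"]))
    dy <- abs(diff(sp[, "y"]))
    sum(dx / machine$v_x[i] + dy / machine$v_y[i] + machine$t_smag)
  }
  structure(list(n_cycles = n_cycles, t_switch = t_switch,
                 t_spill = t_spill, t_spot = t_spot,
                 total = t_switch + t_spill + t_spot),
            class = "layer_timing")
}

# per-unit timing breakdown shared by the static and dynamic simulators
timing_frame <- function(plan, machine) {
  entries <- plan_layers(plan)
  rows <- lapply(seq_along(entries), function(k) {
    e <- entries[[k]]
    lt <- layer_delivery_time(e$layer, machine)
    data.frame(unit = e$unit, angle_deg = e$angle_deg,
               energy_mev = e$layer$energy_mev,
               n_spots = nrow(e$layer$spots), mu = layer_mu(e$layer),
               n_cycles = lt$n_cycles, t_switch = lt$t_switch,
               t_spill = lt$t_spill, t_spot = lt$t_spot, total = lt$total)
  })
  if (!length(rows))
    return(data.frame(unit = integer(0), angle_deg = numeric(0),
                      energy_mev = numeric(0), n_spots = integer(0),
                      mu = numeric(0), n_cycles = integer(0),
                      t_switch = numeric(0), t_spill = numeric(0),
                      t_spot = numeric(0), total = numeric(0)))
  do.call(rbind, rows)
}

new_delivery_report <- function(timing, bdt_s, bdt_d = NA_real_) {
  structure(list(timing = timing, bdt_s = bdt_s, bdt_d = bdt_d),
            class = "delivery_report")
}

#' Static beam delivery time of a plan
#'
#' Sums [layer_delivery_time()] over every layer of every field (IMPT) or
#' every control point (SPArc), in delivery order. Gantry rotation is not
#' included: this is irradiation time only.
#'
#' @param plan A valid `proton_plan`.
#' @param machine A `machine_model`.
#' @param check Validate the plan first (default `TRUE`).
#' @return A `delivery_report` with the per-unit breakdown and `bdt_s` (s);
#'   `bdt_d` is `NA` until a dynamic simulation fills it.
#' @export
plan_bdt_static <- function(plan, machine, check = TRUE) {
  if (check) {
    viol <- validate_plan(plan, machine)
    if (length(viol))
      stop_sparc("invalid plan: %s", paste(viol, collapse = "; "))
  }
  timing <- timing_frame(plan, machine)
  new_delivery_report(timing, bdt_s = sum(timing$total))
}

#' @export
print.delivery_report <- function(x, ...) {
  cat(sprintf("<delivery_report> %d units, BDT_s %.2f s", nrow(x$timing), x$bdt_s))
  if (!is.na(x$bdt_d)) cat(sprintf(", BDT_d %.2f s", x$bdt_d))
  cat("\n")
  invisible(x)
}

#' Write a delivery report as CSV
#'
#' One row per layer/control point with the timing decomposition; dynamic
#' reports additionally carry the rotation segment columns.
#'
#' @param report A `delivery_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_delivery_report <- function(report, path) {
  utils::write.csv(report$timing, path, row.names = FALSE)
  invisible(path)
}
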