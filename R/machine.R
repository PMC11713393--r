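#' Synchrotron machine model
#'
#' Container for the accelerator timing and charge parameters that drive the
#' static delivery-time model: per-energy layer-switch time, proton spill
#' rate, scanning-magnet verification time and effective scanning speeds,
#' plus the charge budget of one acceleration cycle (`q_max`, nC), the
#' MU-to-charge conversion and the maximum stable hold time of the ring.
#'
#' Per-energy parameters (`t_lsw`, `spill_rate`, `v_x`, `v_y`,
#' `charge_per_mu`) may be given as a single value (recycled), as a length-2
#' range linearly interpolated across the energy list (low value at the
#' lowest energy), or as a full vector with one entry per energy.
#'
#' @param energies Strictly increasing beam energies (MeV).
#' @param t_lsw Energy-layer switch time(s), seconds.
#' @param spill_rate Proton spill rate(s), MU/s.
#' @param t_smag Scanning-magnet verification time, seconds.
#' @param q_max Protons extracted per acceleration cycle, nC.
#' @param charge_per_mu Charge needed per MU, nC/MU.
#' @param t_hold Maximum stable charge hold time, seconds.
#' @param v_x,v_y Effective scanning-magnet speeds, mm/s.
#' @return An object of class `machine_model`.
#' @seealso [default_machine_model()] for the packaged synchrotron defaults.
#' @export
machine_model <- function(energies,
                          t_lsw = 2.0,
                          spill_rate = c(8, 10),
                          t_smag = 0.002,
                          q_max = 2.0,
                          charge_per_mu = 0.01,
                          t_hold = 8.0,
                          v_x = c(5000, 7000),
                          v_y = c(17000, 22000)) {
  energies <- as.numeric(energies)
  n <- length(energies)
  if (n < 1L) stop_sparc("machine model needs at least one energy")
  if (any(!is.finite(energies)) || any(diff(energies) <= 0))
    stop_sparc("energies must be finite and strictly increasing")

  expand <- function(x, name) {
    x <- as.numeric(x)
    if (length(x) == 1L) x <- rep(x, n)
    else if (length(x) == 2L && n != 2L) x <- seq(x[1], x[2], length.out = n)
    else if (length(x) != n)
      stop_sparc("%s must have length 1, 2 or %d", name, n)
    if (any(!is.finite(x)) || any(x <= 0))
      stop_sparc("%s must be strictly positive and finite", name)
    x
  }

  m <- structure(list(
    energies      = energies,
    t_lsw         = expand(t_lsw, "t_lsw"),
    spill_rate    = expand(spill_rate, "spill_rate"),
    t_smag        = as.numeric(t_smag),
    q_max         = as.numeric(q_max),
    charge_per_mu = expand(charge_per_mu, "charge_per_mu"),
    t_hold        = as.numeric(t_hold),
    v_x           = expand(v_x, "v_x"),
    v_y           = expand(v_y, "v_y")
  ), class = "machine_model")
  for (f in c("t_smag", "q_max", "t_hold"))
    if (!is_number(m[[f]]) || m[[f]] <= 0)
      stop_sparc("%s must be a single positive number", f)
  m
}

#' Default synchrotron machine model
#'
#' 97 discrete energies evenly spanning 71.3 to 228.8 MeV with layer-switch
#' time 2 s, magnet verification 2 ms, spill rate 8 to 10 MU/s, 2 nC per
#' acceleration cycle, 8 s maximum hold time, and scanning speeds 5 to 7 m/s
#' (x) and 17 to 22 m/s (y), each energy-dependent parameter interpolated
#' linearly over the energy list.
#'
#' @return A `machine_model`.
#' @export
default_machine_model <- function() {
  machine_model(energies = seq(71.3, 228.8, length.out = 97))
}

#' Gantry kinematic model
#'
#' @param v_max Maximum rotation speed, deg/s.
#' @param a_max Maximum acceleration, deg/s^2.
#' @param d_max Maximum deceleration, deg/s^2.
#' @return An object of class `gantry_model`.
#' @export
gantry_model <- function(v_max = 6, a_max = 0.6, d_max = 0.5) {
  for (v in list(v_max, a_max, d_max))
    if (!is_number(v) || v <= 0) stop_sparc("gantry limits must be positive numbers")
  structure(list(v_max = v_max, a_max = a_max, d_max = d_max),
            class = "gantry_model")
}

# index of `energy` in the machine list within tolerance, or NA
machine_energy_index <- function(machine, energy, tol = 0.05) {
  i <- which.min(abs(machine$energies - energy))
  if (abs(machine$energies[i] - energy) <= tol) i else NA_integer_
}

#' Read a machine/gantry configuration file
#'
#' Accepts YAML or JSON with any of the `machine_model` fields
#' (`energies` may be a vector or a `{min, max, count}` spec) and an optional
#' `gantry` block with `v_max`, `a_max`, `d_max`. Missing fields fall back
#' to the packaged defaults.
#'
#' @param path Configuration file path.
#' @return `list(machine = machine_model, gantry = gantry_model)`.
#' @export
read_machine_config <- function(path) {
  if (!file.exists(path)) stop_sparc("machine config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  en <- cfg$energies
  if (is.list(en) && !is.null(en$count))
    en <- seq(en$min, en$max, length.out = en$count)
  en <- en %||% seq(71.3, 228.8, length.out = 97)
  args <- list(energies = as.numeric(unlist(en)))
  for (f in c("t_lsw", "spill_rate", "t_smag", "q_max", "charge_per_mu",
              "t_hold", "v_x", "v_y"))
    if (!is.null(cfg[[f]])) args[[f]] <- as.numeric(unlist(cfg[[f]]))
  g <- cfg$gantry %||% list()
  list(machine = do.call(machine_model, args),
       gantry = gantry_model(v_max = g$v_max %||% 6,
                             a_max = g$a_max %||% 0.6,
                             d_max = g$d_max %||% 0.5))
}

#' @export
print.machine_model <- function(x, ...) {
  cat(sprintf("<machine_model> %d energies, %.1f-%.1f MeV\n",
              length(x$energies), min(x$energies), max(x$energies)))
  cat(sprintf("  t_lsw %.3g s | spill %.3g-%.3g MU/s | t_smag %.3g s\n",
              x$t_lsw[1], min(x$spill_rate), max(x$spill_rate), x$t_smag))
  cat(sprintf("  q_max %.3g nC | charge/MU %.3g nC | t_hold %.3g s\n",
              x$q_max, x$charge_per_mu[1], x$t_hold))
  invisible(x)
}

#' @export
print.gantry_model <- function(x, ...) {
  cat(sprintf("<gantry_model> v_max %.3g deg/s, a_max %.3g, d_max %.3g deg/s^2\n",
              x$v_max, x$a_max, x$d_max))
  invisible(x)
}
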