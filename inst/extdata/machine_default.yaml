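# Default synchrotron + gantry configuration.
# Per-energy parameters given as [low, high] are interpolated linearly over
# the energy list (low value at the lowest energy).
energies:
  min: 71.3
  max: 228.8
  count: 97
t_lsw: 2.0            # energy-layer switch time, s (one acceleration cycle)
spill_rate: [8, 10]   # proton spill rate, MU/s
t_smag: 0.002         # scanning-magnet verification time, s
q_max: 2.0            # protons per acceleration cycle, nC
charge_per_mu: 0.01   # charge needed per MU, nC/MU
t_hold: 8.0           # maximum stable hold time, s
v_x: [5000, 7000]     # effective scanning speed x, mm/s
v_y: [17000, 22000]   # effective scanning speed y, mm/s
gantry:
  v_max: 6.0          # deg/s
  a_max: 0.6          # deg/s^2
  d_max: 0.5          # deg/s^2
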