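# Reference anchor values for the studied DMPC/DMPG-vesicle + PEG system,
# used across tests: hydrodynamic diameters, transition enthalpies, diffusion
# constants, mean Oil-Red-O lifetimes and bilayer microviscosities for the
# neat vesicles and the four polymer molar masses.

ref <- list(
  molar_mass = c(1.5e3, 2e4, 1e5, 4e5),
  diameter_neat_nm = 119.9,
  diameter_mix_nm = c(121.4, 129.6, 135.7, 157.7),
  enthalpy_neat = 0.335,
  enthalpy_mix = c(0.242, 0.241, 0.234, 0.256),
  D35 = 5.21e-12, D15 = 3.73e-12,
  T_c_neat = 22.84,
  # (tau_ns, eta_cP) per condition, neat first
  tau35 = c(24.01, 20.61, 21.43, 22.72, 23.91),
  eta35 = c(28.75, 1.02, 2.39, 8.59, 26.24),
  tau15 = c(28.91, 27.38, 27.59, 28.42, 28.74),
  eta15 = c(142.82, 3.36, 5.69, 43.93, 95.09)
)

ref$delta_nm <- (ref$diameter_mix_nm - ref$diameter_neat_nm) / 2
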