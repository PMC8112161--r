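# Independent oracles used across tests.

# Bethe-Bloch evaluated from first-principles constants (0.307 MeV cm^2/g
# coefficient, Z/A of water), structurally independent of the package's
# K-based form. Returns MeV/mm for the whole ion.
oracle_bethe <- function(E_u, Z = 1, m_u = 938.272, I_eV = 78, rho = 1) {
  ZA_water <- 0.5551
  gamma <- 1 + E_u / m_u
  b2 <- 1 - 1 / gamma^2
  coef <- 0.307075 * ZA_water * rho / 10 # MeV/mm
  coef * Z^2 / b2 * (log(2 * 0.511e6 / I_eV * b2 / (1 - b2)) - b2)
}

# Bohr straggling power per mm for water (unit charge, non-relativistic):
# 4 pi N_e r_e^2 (m_e c^2)^2 = 0.1569 * (Z/A) MeV^2/cm.
oracle_bohr_per_mm <- function(Z = 1) 0.1569 * 0.5551 / 10 * Z^2

registry_ions <- c("proton", "helium", "lithium", "boron", "carbon")

# Table of fixed-range beam energies used throughout (26 cm range in water)
fixed_range_energies <- c(proton = 200.0, helium = 200.0, lithium = 253.9,
                          boron = 345.7, carbon = 386.9)
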