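# Physical constants (CODATA), in the package's working units.

# Coulomb prefactor e^2/(4 pi eps0), kJ Angstrom / (mol e^2)
.ke_coulomb <- 1389.354

# Gas constant, kJ/(mol K)
.r_gas <- 8.31446e-3

# Avogadro constant, 1/mol
.n_avogadro <- 6.02214076e23

# 1 molecule/Angstrom^3 in mol/L (1 A^3 = 1e-27 L)
.ang3_to_molL <- 1e27 / .n_avogadro  # = 1660.54...

# Standard atomic masses (amu) for common elements; used when a topology
# omits masses.  Unknown elements fall back to unit mass with a warning.
.element_masses <- c(
  H = 1.008, D = 2.014, He = 4.0026, Li = 6.94, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Na = 22.99, Mg = 24.305, Al = 26.982,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ar = 39.948,
  Ca = 40.078, Fe = 55.845, Zn = 65.38, Br = 79.904, I = 126.904
)

.element_mass <- function(element) {
  m <- .element_masses[element]
  if (anyNA(m)) {
    warning("no standard mass for element(s) ",
            paste(unique(element[is.na(m)]), collapse = ", "),
            "; using unit mass")
    m[is.na(m)] <- 1
  }
  unname(m)
}
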