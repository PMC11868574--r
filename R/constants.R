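# Physical constants and element data used throughout the package.
# All energies are kcal/mol, distances Angstrom, time fs, masses amu.

#' Unit conversion and physical constants
#'
#' Canonical internal energy unit is kcal/mol. `hartree_to_kcal` converts
#' Hartree-labeled inputs; `kB` is Boltzmann's constant in kcal/(mol K);
#' `mvv_to_kcal` converts amu (Angstrom/fs)^2 to kcal/mol, so kinetic
#' energy is `0.5 * mvv_to_kcal * sum(m * v^2)`.
#'
#' @format Named list of scalars.
#' @export
cf_constants <- list(
  hartree_to_kcal = 627.509,
  kB              = 0.0019872041,   # kcal/(mol K)
  mvv_to_kcal     = 2390.05736      # 1 amu A^2/fs^2 in kcal/mol
)

# Element table: atomic number, mass (amu), covalent radius, van der Waals
# radius (A). Covers the synthetic library's vocabulary plus common extras.
.cf_elements <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  number = c(1L, 5L, 6L, 7L, 8L, 9L, 15L, 16L, 17L, 35L, 53L),
  mass   = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998,
             30.974, 32.06, 35.45, 79.904, 126.904),
  r_cov  = c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02, 1.20, 1.39),
  r_vdw  = c(1.10, 1.92, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98),
  # Lennard-Jones well depths (kcal/mol), OPLS-flavoured; pair depths come
  # from the Lorentz-Berthelot geometric mean.
  lj_eps = c(0.030, 0.05, 0.066, 0.17, 0.21, 0.061,
             0.20, 0.25, 0.30, 0.30, 0.30),
  # relative bond stiffness (bonds to O/N/F stiffer, to heavy atoms
  # softer); combined per bond as the geometric mean
  k_rel  = c(1.00, 0.90, 1.00, 1.25, 1.50, 1.80,
             1.20, 0.70, 0.60, 0.55, 0.50),
  stringsAsFactors = FALSE
)

.element_row <- function(symbol) {
  i <- match(symbol, .cf_elements$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  .cf_elements[i, , drop = FALSE]
}
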