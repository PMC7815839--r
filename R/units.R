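#' @title Internal unit system and physical constants
#' @description
#' All interfaces use angstrom (length), kcal/mol (energy), femtosecond
#' (time), amu (mass) and kelvin (temperature). Dynamics is propagated in a
#' consistent internal system (amu, angstrom, fs) in which energies carry the
#' unit amu*A^2/fs^2; `.kcalmol_to_internal` converts between the two.
#' Constants are CODATA 2018.
#' @name units
NULL

# Boltzmann constant, kcal/mol/K
.kB <- 0.001987204259

# 1 kcal/mol expressed in amu*A^2/fs^2 (== 4184 J/mol / (N_A * 1 amu) scaled)
.kcalmol_to_internal <- 4.184e-4

# reduced Planck constant, kcal/mol * fs
# hbar = 1.054571817e-34 J*s * N_A / 4184 J/kcal * 1e15 fs/s
.hbar_kcalmol_fs <- 1.054571817e-34 * 6.02214076e23 / 4184 * 1e15

# hbar in internal units, amu*A^2/fs
.hbar_internal <- .hbar_kcalmol_fs * .kcalmol_to_internal

# Coulomb constant, kcal/mol * A / e^2
.coulomb_k <- 332.0637133

# most-abundant-isotope masses, amu
.atomic_masses <- c(
  H = 1.00782503207, D = 2.01410177785, He = 4.002603254,
  C = 12.0, N = 14.0030740048, O = 15.99491461956,
  F = 18.99840322, Na = 22.9897692809, S = 31.97207100,
  Cl = 34.96885268, P = 30.97376163
)

# X and Q are placeholder symbols for generalized (non-atomic) coordinates
.atomic_numbers <- c(
  H = 1L, D = 1L, He = 2L, C = 6L, N = 7L, O = 8L,
  F = 9L, Na = 11L, P = 15L, S = 16L, Cl = 17L,
  X = 0L, Q = 119L
)

#' Thermal energy kB*T
#'
#' Returns the thermal energy scale \eqn{k_B T} in kcal/mol. At 300 K this is
#' approximately 0.6 kcal/mol, the scale against which torsional barriers and
#' weak non-covalent interactions are compared.
#'
#' @param T temperature in kelvin; must be positive.
#' @return thermal energy in kcal/mol.
#' @examples
#' thermal_energy(300)  # ~ 0.6 kcal/mol
#' @export
thermal_energy <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("temperature must be a single positive finite number (kelvin)")
  .kB * T
}

#' Physical constants used by the package
#'
#' @return named list with `kB` (kcal/mol/K), `hbar` (kcal/mol*fs),
#'   `kcalmol_to_internal` (conversion from kcal/mol to amu*A^2/fs^2),
#'   `coulomb` (kcal/mol*A/e^2) and the isotopic mass table (amu).
#' @export
physical_constants <- function() {
  list(kB = .kB, hbar = .hbar_kcalmol_fs,
       kcalmol_to_internal = .kcalmol_to_internal,
       coulomb = .coulomb_k, masses = .atomic_masses)
}

#' Atomic masses for element symbols
#'
#' @param species character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
atomic_masses <- function(species) {
  m <- .atomic_masses[species]
  if (anyNA(m))
    stop("unknown element symbol(s): ",
         paste(unique(species[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Map element symbols to atomic numbers and back
#'
#' @param species character vector of element symbols.
#' @return integer vector of atomic numbers.
#' @export
atomic_numbers <- function(species) {
  z <- .atomic_numbers[species]
  if (anyNA(z))
    stop("unknown element symbol(s): ",
         paste(unique(species[is.na(z)]), collapse = ", "))
  unname(z)
}

#' @param z integer vector of atomic numbers.
#' @rdname atomic_numbers
#' @export
element_symbols <- function(z) {
  tbl <- .atomic_numbers[names(.atomic_numbers) != "D"]
  sym <- names(tbl)[match(as.integer(z), tbl)]
  if (anyNA(sym)) stop("unsupported atomic number(s): ",
                       paste(unique(z[is.na(sym)]), collapse = ", "))
  sym
}
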