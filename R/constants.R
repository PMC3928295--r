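## Physical constants and per-element parameter tables.
## Internal units throughout the package: length Bohr, energy Hartree.
## All file I/O and restraint specifications are in Angstrom / kcal/mol.

#' Unit conversion constants
#'
#' Conversion factors used throughout the package.  Lengths are stored
#' internally in Bohr and energies in Hartree; files, restraints and rendered
#' tables use Angstrom and kcal/mol.
#'
#' @format A named numeric vector with elements
#'   `ang_per_bohr` (0.52917721067 Angstrom per Bohr) and
#'   `kcal_per_hartree` (627.509474 kcal/mol per Hartree).
#' @export
fragopt_units <- c(ang_per_bohr = 0.52917721067,
                   kcal_per_hartree = 627.509474)

.ang_per_bohr <- 0.52917721067
.kcal_per_hartree <- 627.509474

ang_to_bohr <- function(x) x / .ang_per_bohr
bohr_to_ang <- function(x) x * .ang_per_bohr
hartree_to_kcal <- function(x) x * .kcal_per_hartree
kcal_to_hartree <- function(x) x / .kcal_per_hartree

## Bondi van der Waals radii (Angstrom), used by the unitless relative-distance
## dimer cutoff: R_IJ = min over atom pairs of r_ab / (vdW_a + vdW_b).
.bondi_vdw_ang <- c(H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52,
                    F = 1.47, Ne = 1.54, P = 1.80, S = 1.80, Cl = 1.75,
                    Ar = 1.88, Br = 1.85)
.bondi_default_ang <- 1.70

#' Bondi van der Waals radius of an element
#'
#' Used in the relative-distance definition of the quantum-mechanical dimer
#' cutoff (the FMO-lineage unitless distance).  Elements not in the shipped
#' Bondi table fall back to 1.70 Angstrom.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .bondi_vdw_ang[element]
  r[is.na(r)] <- .bondi_default_ang
  unname(r)
}

## ---------------------------------------------------------------------------
## Mock-backend element parameters (documented closed-form model):
##   q      fixed per-element partial charge (e); per-fragment a uniform shift
##          is applied so charges sum to the declared fragment charge
##   alpha  isotropic atom-centered polarizability (Bohr^3)
##   eps    Lennard-Jones well depth (Hartree), Lorentz-Berthelot combination
##   sigma  Lennard-Jones size (Bohr)
##   c6     dispersion coefficient for the mock "MP2 correlation"
##          (Hartree * Bohr^6); pair coefficient is the geometric mean
.mock_elements <- data.frame(
  element = c("H",    "C",    "N",    "O",    "Ne",   "Ar"),
  q       = c(0.40,   0.00,  -0.40,  -0.80,   0.00,   0.00),
  alpha   = c(2.0,    8.0,    7.4,    5.4,    2.7,    11.1),
  eps     = c(1.0e-4, 2.0e-4, 2.5e-4, 3.0e-4, 0.8e-4, 3.0e-4),
  sigma   = c(4.2,    6.2,    6.0,    5.8,    5.2,    6.4),
  c6      = c(1.2,    9.0,    7.0,    5.6,    2.2,    12.0),
  stringsAsFactors = FALSE
)
.mock_default <- list(q = 0.0, alpha = 4.0, eps = 1.5e-4, sigma = 5.5, c6 = 4.0)

mock_param <- function(element, what) {
  i <- match(element, .mock_elements$element)
  out <- .mock_elements[[what]][i]
  out[is.na(i)] <- .mock_default[[what]]
  out
}

## Harmonic reference bond lengths (Angstrom) and force constants
## (Hartree / Bohr^2) for the mock intra-fragment potential, keyed by the
## alphabetically sorted element pair.  Every intra-fragment atom pair gets a
## harmonic term, so small rigid fragments (e.g. water at its reference
## geometry) are exact minima of the mock potential.
.water_r_oh_ang <- 0.9572
.water_theta_deg <- 104.52
.water_r_hh_ang <- 2 * .water_r_oh_ang * sin(.water_theta_deg * pi / 360)

.mock_r0_ang <- c("H-O" = .water_r_oh_ang, "H-H" = .water_r_hh_ang,
                  "C-C" = 1.5, "C-O" = 1.43, "C-H" = 1.09, "H-N" = 1.01,
                  "N-N" = 1.4)
.mock_r0_default_ang <- 1.5
.mock_k <- c("H-H" = 0.10)   # H-H is a geometry brace, softer than a bond
.mock_k_default <- 0.25

pair_key <- function(e1, e2) {
  paste(pmin(e1, e2), pmax(e1, e2), sep = "-")
}

mock_bond_r0_bohr <- function(e1, e2) {
  key <- pair_key(e1, e2)
  r0 <- .mock_r0_ang[key]
  r0[is.na(r0)] <- .mock_r0_default_ang
  ang_to_bohr(unname(r0))
}

mock_bond_k <- function(e1, e2) {
  key <- pair_key(e1, e2)
  k <- .mock_k[key]
  k[is.na(k)] <- .mock_k_default
  unname(k)
}

## Short-range damping length (Bohr) of the mock correlation term
## -C6/(r^6 + d^6): keeps the mock MP2 surface bounded below while leaving
## the long-range -C6/r^6 behaviour intact.
.mock_corr_damp <- 1.5

## Basis-set scaling of the mock correlation energy: larger correlation-
## consistent sets recover more of the mock dispersion-like correlation.
.mock_basis_scale <- c("6-31G(d)" = 1.00, "cc-pVDZ" = 1.15, "cc-pVTZ" = 1.30)

mock_basis_scale <- function(basis_label) {
  s <- .mock_basis_scale[basis_label]
  s[is.na(s)] <- 1.0
  unname(s)
}
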