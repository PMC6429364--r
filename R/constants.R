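# Physical constants and small lookup tables shared across modules.

# Coulomb constant in kcal*Angstrom/(mol*e^2)
K_COULOMB <- 332.0636

# SI constants used to derive electrostatic unit conversions at run time
.e_charge <- 1.602176634e-19   # C
.eps0     <- 8.8541878128e-12  # F/m
.kB       <- 1.380649e-23      # J/K
.N_A      <- 6.02214076e23     # 1/mol

#' Vacuum Bjerrum-type length e^2/(4 pi eps0 kT) in Angstrom
#'
#' Length scale at which the unscreened interaction of two unit charges in
#' vacuum equals the thermal energy; potentials in kT/e follow as
#' `lb0 * q / (eps * r)`.
#'
#' @param temperature Kelvin.
#' @return Length in Angstrom (~557 at 300 K).
#' @keywords internal
bjerrum_vacuum <- function(temperature = 300) {
  (.e_charge^2 / (4 * pi * .eps0 * .kB * temperature)) * 1e10
}

#' Inverse Debye length from ionic strength
#'
#' @param ionic_strength mol/L of a 1:1 salt.
#' @param eps_out solvent relative dielectric.
#' @param temperature Kelvin.
#' @return kappa in 1/Angstrom.
#' @export
#' @examples
#' 1 / debye_kappa(0.15)  # Debye length ~ 8 Angstrom in water
debye_kappa <- function(ionic_strength, eps_out = 80, temperature = 300) {
  stopifnot(ionic_strength >= 0, eps_out > 0)
  # ion number density in 1/A^3 (1 L = 1e27 A^3)
  n <- ionic_strength * .N_A / 1e27
  kappa2 <- 4 * pi * bjerrum_vacuum(temperature) / eps_out * 2 * n
  sqrt(kappa2)
}

# Bondi-style van der Waals radii (Angstrom) keyed by element
ELEMENT_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, FE = 1.40, ZN = 1.39,
  MG = 1.73, CA = 1.74, "NA" = 2.27, K = 2.75
)
DEFAULT_RADIUS <- 1.70

# One-letter -> three-letter residue codes
AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

# Side-chain atom that carries the formal charge of an ionizable residue
# in all-atom structures; synthetic structures use the SC pseudo-atom.
CHARGE_BEARER <- c(ASP = "CG", GLU = "CD", LYS = "NZ", ARG = "CZ", HIS = "ND1")

#' Disordered C-terminal tail sequences of alpha- and beta-tubulin (E-hooks)
#'
#' One-letter sequences of the acidic, intrinsically disordered C-terminal
#' tails of Bos taurus alpha-tubulin and beta-tubulin used as defaults by the
#' synthetic system generator.
#'
#' @format Named character vector with elements `alpha` and `beta`.
#' @export
ehook_sequences <- c(
  alpha = "VGVDSVEGEGEEEGEEY",
  beta  = "DATADEQGEFEEEGEEDEA"
)

# Segment tags recognised on atoms
SEGMENT_TAGS <- c(
  paste0("H", 1:6), "LH1", "LF", "FLAP", "CC1", "CC2",
  paste0("TAIL_", c("A", "B", "C", "D")), "BODY", "OTHER"
)

#' Round half away from zero
#'
#' Fixed-point rounding where .5 always rounds up in magnitude, matching the
#' convention used for printed contact percentages.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
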