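# Physical constants (CODATA 2018) and unit conversions.
#
# Internal convention, used everywhere in the package:
#   * quantum mechanics (DVR Hamiltonians, map features) in atomic units
#     (bohr, hartree, electron mass, elementary charge),
#   * geometry (coordinates, cutoffs, bin widths) in angstrom,
#   * frequencies at the API boundary in cm^-1,
#   * time in ps.
# All conversions live in this file so a unit bug has one home.

.hartree_to_cm <- 219474.6313632      # E_h -> cm^-1
.amu_to_me     <- 1822.888486209      # unified amu -> electron masses
.bohr_to_ang   <- 0.529177210903      # a0 -> angstrom
.ang_to_bohr   <- 1 / .bohr_to_ang
.c_cm_per_ps   <- 2.99792458e-2       # speed of light, cm / ps
.kjmol_to_hartree  <- 1 / 2625.4996394799
.kcalmol_to_hartree <- 4.184 / 2625.4996394799

#' Convert an energy in hartree to a wavenumber
#'
#' @param e Energy (or energy difference) in hartree.
#' @return Wavenumber in cm^-1.
#' @export
hartree_to_wavenumber <- function(e) e * .hartree_to_cm

#' Convert a wavenumber to an energy in hartree
#'
#' @param w Wavenumber in cm^-1.
#' @return Energy in hartree.
#' @export
wavenumber_to_hartree <- function(w) w / .hartree_to_cm

# internal helpers -----------------------------------------------------------

.energy_to_hartree <- function(x, unit) {
  switch(match.arg(unit, c("hartree", "kjmol", "kcalmol", "cm-1")),
    hartree = x,
    kjmol   = x * .kjmol_to_hartree,
    kcalmol = x * .kcalmol_to_hartree,
    `cm-1`  = x / .hartree_to_cm
  )
}

.length_to_angstrom <- function(x, unit) {
  switch(match.arg(unit, c("angstrom", "nm", "bohr")),
    angstrom = x,
    nm       = x * 10,
    bohr     = x * .bohr_to_ang
  )
}
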