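#' Unit conversion constants
#'
#' All internal computation uses Hartree atomic units (Bohr for length,
#' Hartree for energy).  File formats that conventionally use other units
#' (XYZ in angstrom, spectra in eV, reports in kcal/mol) are converted at
#' the boundary with the constants collected here.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{bohr_per_angstrom}{1 / 0.52917721067}
#'   \item{angstrom_per_bohr}{0.52917721067}
#'   \item{kcalmol_per_hartree}{627.509}
#'   \item{ev_per_hartree}{27.211386}
#' }
#' @export
mbd_units <- list(
  bohr_per_angstrom  = 1 / 0.52917721067,
  angstrom_per_bohr  = 0.52917721067,
  kcalmol_per_hartree = 627.509,
  ev_per_hartree      = 27.211386
)

#' Convert lengths between angstrom and Bohr
#'
#' @param x numeric vector or matrix of lengths.
#' @return `x` converted to the other unit.
#' @export
angstrom_to_bohr <- function(x) x * mbd_units$bohr_per_angstrom

#' @rdname angstrom_to_bohr
#' @export
bohr_to_angstrom <- function(x) x * mbd_units$angstrom_per_bohr

#' Convert energies from Hartree
#'
#' @param x numeric vector of energies in Hartree.
#' @return energies in kcal/mol or eV.
#' @export
hartree_to_kcalmol <- function(x) x * mbd_units$kcalmol_per_hartree

#' @rdname hartree_to_kcalmol
#' @export
hartree_to_ev <- function(x) x * mbd_units$ev_per_hartree
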