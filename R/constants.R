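#' Physical constants used throughout the package
#'
#' CODATA 2018 values, fixed at better than six significant figures. The
#' internal unit system is atomic units; these constants are used only at the
#' I/O boundary (eV, Debye, GM). A plain-text copy of the table ships in
#' `inst/extdata/physical_constants.tsv` for auditability.
#'
#' @return A named list:
#' \describe{
#'   \item{alpha}{fine-structure constant (dimensionless)}
#'   \item{a0_cm}{Bohr radius in cm}
#'   \item{c_cm_s}{speed of light in cm/s}
#'   \item{hartree_eV}{Hartree energy in eV}
#'   \item{au_debye}{one atomic unit of electric dipole moment in Debye}
#'   \item{t_au_s}{atomic unit of time in s}
#'   \item{gm_cm4s}{one Goeppert-Mayer unit in cm^4 s/photon}
#' }
#' @examples
#' tpa_constants()$hartree_eV
#' @export
tpa_constants <- function() {
  list(
    alpha      = 7.2973525693e-3,
    a0_cm      = 5.29177210903e-9,
    c_cm_s     = 2.99792458e10,
    hartree_eV = 27.211386245988,
    au_debye   = 2.5417464519,
    t_au_s     = 2.4188843265857e-17,
    gm_cm4s    = 1e-50
  )
}

#' Convert between the unit pairs used at the package boundary
#'
#' Exact multiplicative conversions built from [tpa_constants()]. Supported
#' unit tokens: `"eV"`, `"hartree"` (energy); `"D"`, `"au"` (electric dipole);
#' `"cm4s"`, `"GM"` (two-photon cross section).
#'
#' @param value Numeric vector to convert.
#' @param from,to Unit tokens (see above). Conversion is only defined within
#'   a pair; `convert_units(x, "eV", "D")` is an error.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_units(1, "au", "D")     # ~2.5417
#' convert_units(1e-50, "cm4s", "GM")
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), is.character(from), is.character(to))
  k <- tpa_constants()
  factors <- list(
    "eV->hartree"   = 1 / k$hartree_eV,
    "hartree->eV"   = k$hartree_eV,
    "au->D"         = k$au_debye,
    "D->au"         = 1 / k$au_debye,
    "cm4s->GM"      = 1 / k$gm_cm4s,
    "GM->cm4s"      = k$gm_cm4s
  )
  if (identical(from, to)) {
    return(value)
  }
  key <- paste0(from, "->", to)
  if (is.null(factors[[key]])) {
    stop("unsupported unit conversion: ", from, " -> ", to, call. = FALSE)
  }
  value * factors[[key]]
}

# atomic unit of the 2PA cross section, in GM: a0^4 * t_au / 1 GM
au_cross_section_gm <- function() {
  k <- tpa_constants()
  k$a0_cm^4 * k$t_au_s / k$gm_cm4s
}
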