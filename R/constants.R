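#' Physical constants and unit conversions
#'
#' All concentrations in this package are stored in mol/L and all lengths in
#' nanometres; every conversion between the two unit systems goes through the
#' factors collected here.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{avogadro}{Avogadro constant, 1/mol.}
#'   \item{litre_per_nm3}{Volume of one cubic nanometre in litres (1e-24).}
#' }
#' @export
bta_constants <- list(
  avogadro      = 6.02214076e23,
  litre_per_nm3 = 1e-24
)

#' Package default model parameters
#'
#' Central table of the calibrated defaults used throughout: fiber radius
#' 15 nm, axial rise 0.452 nm per monomer (calibrated so the cylinder model
#' reproduces the 26 uM effective-concentration anchor at 10 nM bulk protein
#' and 2 uM total BTA), handle-recruiter duplex dissociation constant
#' 0.162 uM (calibrated so 0.5 uM handles bind 75 percent of 20 nM
#' recruiter), solution inhibition constant 1.5 uM for the enzyme-inhibitor
#' pair, and duplex off-rate 0.2 1/s for a 10-bp duplex.
#'
#' @format Named list of numeric scalars: `radius_nm`, `axial_rise_nm`,
#'   `duplex_kd_M`, `ki_solution_M`, `duplex_koff_s`.
#' @export
bta_defaults <- list(
  radius_nm     = 15,
  axial_rise_nm = 0.452,
  duplex_kd_M   = 0.162e-6,
  ki_solution_M = 1.5e-6,
  duplex_koff_s = 0.2
)

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("'%s' must be a single finite number", name)
  }
  if (positive && x <= 0) stop_invalid("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stop_invalid("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}
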