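#' Cylindrical fiber model
#'
#' Describes a supramolecular polymer fiber as a cylinder in which recruited
#' proteins can reside anywhere within the volume. Each stacked monomer
#' contributes a slice of height `axial_rise`, so a known bulk monomer
#' concentration fixes the total fiber volume per litre of solution.
#'
#' @param radius Cylinder radius in nm. Default 15 nm.
#' @param axial_rise Axial rise per monomer in nm. The default, 0.452 nm, is
#'   calibrated with [calibrate_axial_rise()] against the 26 uM
#'   effective-concentration anchor (10 nM bulk protein, 2 uM total BTA).
#' @return An object of class `fiber_model` with fields `radius` and
#'   `axial_rise` (both nm).
#' @examples
#' fiber_model()
#' fiber_model(radius = 10, axial_rise = 0.5)
#' @export
fiber_model <- function(radius = bta_defaults$radius_nm,
                        axial_rise = bta_defaults$axial_rise_nm) {
  check_scalar(radius, "radius", positive = TRUE)
  check_scalar(axial_rise, "axial_rise", positive = TRUE)
  structure(list(radius = radius, axial_rise = axial_rise),
            class = "fiber_model")
}

#' @export
print.fiber_model <- function(x, ...) {
  cat(sprintf("<fiber_model> cylinder radius %g nm, axial rise %g nm/monomer (%.1f nm^3/monomer)\n",
              x$radius, x$axial_rise, monomer_volume(x)))
  invisible(x)
}

#' Assembly composition of functionalized and inert monomers
#'
#' Bulk concentrations of the DNA-handle-bearing monomer (BTA-DNA) and the
#' inert monomer (BTA-3OH) that co-assemble into the fibers. The receptor
#' density is the fraction of monomers carrying a handle.
#'
#' @param conc_btadna Bulk BTA-DNA concentration, mol/L.
#' @param conc_bta3oh Bulk BTA-3OH concentration, mol/L.
#' @return An object of class `assembly_composition` with fields
#'   `conc_btadna`, `conc_bta3oh`, `total` (mol/L) and `density_fraction`.
#' @examples
#' # 25% BTA-DNA: 0.5 uM BTA-DNA + 1.5 uM BTA-3OH
#' assembly_composition(0.5e-6, 1.5e-6)
#' @export
assembly_composition <- function(conc_btadna, conc_bta3oh) {
  check_scalar(conc_btadna, "conc_btadna", nonneg = TRUE)
  check_scalar(conc_bta3oh, "conc_bta3oh", nonneg = TRUE)
  total <- conc_btadna + conc_bta3oh
  if (total <= 0) stop_invalid("total BTA concentration must be > 0")
  structure(list(conc_btadna = conc_btadna,
                 conc_bta3oh = conc_bta3oh,
                 total = total,
                 density_fraction = conc_btadna / total),
            class = "assembly_composition")
}

#' @export
print.assembly_composition <- function(x, ...) {
  cat(sprintf("<assembly_composition> %.3g M BTA-DNA + %.3g M BTA-3OH (%.3g%% receptor density)\n",
              x$conc_btadna, x$conc_bta3oh, 100 * x$density_fraction))
  invisible(x)
}

#' Volume of one monomer slice of the fiber cylinder
#'
#' @param fiber A [fiber_model()].
#' @return Volume in nm^3: `pi * radius^2 * axial_rise`.
#' @examples
#' monomer_volume(fiber_model()) # ~319.5 nm^3
#' @export
monomer_volume <- function(fiber) {
  stopifnot(inherits(fiber, "fiber_model"))
  pi * fiber$radius^2 * fiber$axial_rise
}

total_fiber_volume_litres <- function(composition, fiber) {
  # litres of fiber interior per litre of solution
  composition$total * bta_constants$avogadro *
    monomer_volume(fiber) * bta_constants$litre_per_nm3
}

#' In-fiber effective concentration of a recruited species
#'
#' Converts a bulk concentration into the local concentration experienced
#' inside the fibers: the bulk amount of protein divided by the total fiber
#' volume per litre of solution. The result is proportional to the bulk
#' concentration and inversely proportional to the total monomer
#' concentration, so diluting the handles with inert monomer at fixed protein
#' concentrates the protein, while adding more fiber material dilutes it.
#'
#' @param bulk_conc Bulk concentration of the recruited species, mol/L.
#' @param composition An [assembly_composition()].
#' @param fiber A [fiber_model()].
#' @return Effective concentration, mol/L.
#' @examples
#' comp <- assembly_composition(0.5e-6, 1.5e-6) # 2 uM total
#' effective_concentration(10e-9, comp, fiber_model()) # ~26 uM
#' @export
effective_concentration <- function(bulk_conc, composition, fiber = fiber_model()) {
  check_scalar(bulk_conc, "bulk_conc", nonneg = TRUE)
  stopifnot(inherits(composition, "assembly_composition"))
  vol <- total_fiber_volume_litres(composition, fiber)
  if (vol <= 0) stop_invalid("total fiber volume is zero: no BTA monomers")
  bulk_conc / vol
}

#' Fold enhancement of local over bulk concentration
#'
#' Ratio of the in-fiber effective concentration to the bulk concentration.
#' A pure geometry/composition factor, independent of the bulk value itself.
#'
#' @inheritParams effective_concentration
#' @return Dimensionless enhancement factor.
#' @examples
#' comp <- assembly_composition(0.5e-6, 1.5e-6)
#' fold_enhancement(10e-9, comp, fiber_model()) # ~2600
#' @export
fold_enhancement <- function(bulk_conc, composition, fiber = fiber_model()) {
  check_scalar(bulk_conc, "bulk_conc", positive = TRUE)
  effective_concentration(bulk_conc, composition, fiber) / bulk_conc
}

#' Total fiber contour length per litre of solution
#'
#' Each monomer adds `axial_rise` nm of fiber, so the summed length of all
#' fibers in one litre is `total_BTA * N_A * axial_rise`.
#'
#' @inheritParams effective_concentration
#' @return Length in nm per litre.
#' @export
fiber_length_per_liter <- function(composition, fiber = fiber_model()) {
  stopifnot(inherits(composition, "assembly_composition"),
            inherits(fiber, "fiber_model"))
  composition$total * bta_constants$avogadro * fiber$axial_rise
}

#' Mean spacing between recruited proteins along the fibers
#'
#' Assuming every protein is recruited and proteins distribute homogeneously
#' along the fiber contour, the mean inter-protein distance is the total
#' fiber length divided by the number of proteins.
#'
#' @param protein_conc_total Total recruited protein concentration, mol/L.
#' @inheritParams effective_concentration
#' @return Mean spacing in nm.
#' @examples
#' comp <- assembly_composition(0.5e-6, 1.5e-6)
#' mean_protein_spacing(11e-9, comp, fiber_model()) # ~82 nm
#' @export
mean_protein_spacing <- function(protein_conc_total, composition,
                                 fiber = fiber_model()) {
  check_scalar(protein_conc_total, "protein_conc_total", positive = TRUE)
  fiber_length_per_liter(composition, fiber) /
    (protein_conc_total * bta_constants$avogadro)
}

#' Calibrate the axial rise from an effective-concentration anchor
#'
#' Closed-form inverse of [effective_concentration()]: given one known
#' (bulk, effective) pair and the cylinder radius, returns the axial rise per
#' monomer that makes the cylinder model reproduce the anchor exactly.
#'
#' @param anchor_ceff Known effective concentration, mol/L.
#' @param anchor_bulk Bulk concentration producing it, mol/L.
#' @param anchor_composition The [assembly_composition()] of the anchor.
#' @param radius Cylinder radius, nm.
#' @return Axial rise in nm per monomer.
#' @examples
#' comp <- assembly_composition(0.5e-6, 1.5e-6)
#' calibrate_axial_rise(26e-6, 10e-9, comp) # ~0.4518 nm
#' @export
calibrate_axial_rise <- function(anchor_ceff, anchor_bulk, anchor_composition,
                                 radius = bta_defaults$radius_nm) {
  check_scalar(anchor_ceff, "anchor_ceff", positive = TRUE)
  check_scalar(anchor_bulk, "anchor_bulk", positive = TRUE)
  check_scalar(radius, "radius", positive = TRUE)
  stopifnot(inherits(anchor_composition, "assembly_composition"))
  # ceff = bulk / (total * N_A * pi r^2 h * 1e-24)  =>  solve for h
  anchor_bulk / (anchor_ceff * anchor_composition$total *
                   bta_constants$avogadro * pi * radius^2 *
                   bta_constants$litre_per_nm3)
}
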