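#' Competitive-inhibition model for the scaffold-confined enzyme
#'
#' @param ki_solution Solution-phase inhibition constant of the
#'   enzyme-inhibitor pair, mol/L. Default 1.5 uM (the E104D
#'   beta-lactamase / wild-type BLIP pair).
#' @return An object of class `inhibition_model`.
#' @export
inhibition_model <- function(ki_solution = bta_defaults$ki_solution_M) {
  check_scalar(ki_solution, "ki_solution", positive = TRUE)
  structure(list(ki_solution = ki_solution), class = "inhibition_model")
}

#' Inhibited fraction of scaffold-bound enzyme
#'
#' Single-site competitive-inhibition occupancy of the scaffold-bound enzyme
#' by the inhibitor at its in-fiber effective concentration:
#' `theta = ceff / (ki + ceff)`.
#'
#' @param ceff_inhibitor Effective inhibitor concentration in the fiber, mol/L.
#' @param model An [inhibition_model()].
#' @return Occupied (inhibited) fraction in `[0, 1)`.
#' @examples
#' scaffold_inhibited_fraction(19.5e-6, inhibition_model(1.5e-6)) # 0.9286
#' @export
scaffold_inhibited_fraction <- function(ceff_inhibitor, model = inhibition_model()) {
  check_scalar(ceff_inhibitor, "ceff_inhibitor", nonneg = TRUE)
  stopifnot(inherits(model, "inhibition_model"))
  ceff_inhibitor / (model$ki_solution + ceff_inhibitor)
}

#' Normalized activity from known scaffold-bound fractions
#'
#' Core activity expression of the templated-inhibition model. Enzyme off the
#' scaffold is fully active; enzyme on the scaffold is inhibited with
#' probability `theta`, the occupancy at the inhibitor's effective
#' concentration:
#' `V = (1 - f_enzyme) + f_enzyme * (1 - theta)`.
#'
#' By default only the scaffold-bound inhibitor pool is concentrated, i.e.
#' the effective concentration is computed from
#' `inhibitor_bulk * f_inhibitor`; with
#' `apply_occupancy_to_inhibitor = FALSE` the bulk inhibitor concentration is
#' used directly (the convention of the printed effective-concentration
#' figures).
#'
#' @param f_enzyme Scaffold-bound enzyme fraction.
#' @param f_inhibitor Scaffold-bound inhibitor fraction.
#' @param inhibitor_bulk Bulk inhibitor concentration, mol/L.
#' @param composition An [assembly_composition()].
#' @param fiber A [fiber_model()].
#' @param model An [inhibition_model()].
#' @param apply_occupancy_to_inhibitor Multiply the bulk inhibitor by its
#'   scaffold-bound fraction before concentrating it? Default `TRUE`.
#' @return A list: `activity` (dimensionless, in `[1 - f_enzyme, 1]`),
#'   `f_enzyme`, `f_inhibitor`, `ceff_inhibitor` (mol/L) and `theta`.
#' @export
activity_from_fractions <- function(f_enzyme, f_inhibitor, inhibitor_bulk,
                                    composition, fiber = fiber_model(),
                                    model = inhibition_model(),
                                    apply_occupancy_to_inhibitor = TRUE) {
  check_scalar(f_enzyme, "f_enzyme", nonneg = TRUE)
  check_scalar(f_inhibitor, "f_inhibitor", nonneg = TRUE)
  check_scalar(inhibitor_bulk, "inhibitor_bulk", nonneg = TRUE)
  stopifnot(f_enzyme <= 1, f_inhibitor <= 1)

  bulk_eff <- inhibitor_bulk *
    (if (apply_occupancy_to_inhibitor) f_inhibitor else 1)
  ceff <- effective_concentration(bulk_eff, composition, fiber)
  theta <- scaffold_inhibited_fraction(ceff, model)
  list(activity = (1 - f_enzyme) + f_enzyme * (1 - theta),
       f_enzyme = f_enzyme,
       f_inhibitor = f_inhibitor,
       ceff_inhibitor = ceff,
       theta = theta)
}

#' Forward model of normalized enzyme activity on the scaffold
#'
#' Solves the joint hybridization equilibrium of the enzyme and inhibitor
#' recruiter strands on the shared handle pool (the BTA-DNA concentration),
#' then evaluates the templated competitive-inhibition activity via
#' [activity_from_fractions()]. Activity is normalized so a control omitting
#' the inhibitor reads 1; its plateau at saturating inhibitor is
#' `1 - f_enzyme`, the free-enzyme fraction.
#'
#' @param composition An [assembly_composition()]; its `conc_btadna` is the
#'   handle pool.
#' @param fiber A [fiber_model()].
#' @param enzyme,inhibitor [recruited_species()] for the two proteins; the
#'   inhibitor's `protein_total` is the bulk inhibitor concentration.
#' @param model An [inhibition_model()].
#' @param apply_occupancy_to_inhibitor See [activity_from_fractions()].
#' @param details Return the full list instead of just the activity?
#' @return Normalized activity (numeric scalar), or with `details = TRUE`
#'   the list from [activity_from_fractions()].
#' @examples
#' comp <- assembly_composition(0.5e-6, 1.5e-6)
#' enz <- recruited_species("enzyme", 20e-9, 1e-9)
#' inh <- recruited_species("inhibitor", 20e-9, 10e-9)
#' normalized_activity(comp, fiber_model(), enz, inh)
#' @export
normalized_activity <- function(composition, fiber, enzyme, inhibitor,
                                model = inhibition_model(),
                                apply_occupancy_to_inhibitor = TRUE,
                                details = FALSE) {
  stopifnot(inherits(composition, "assembly_composition"),
            inherits(enzyme, "recruited_species"),
            inherits(inhibitor, "recruited_species"))
  state <- solve_competition(composition$conc_btadna, list(enzyme, inhibitor))
  res <- activity_from_fractions(
    f_enzyme = protein_scaffold_fraction(enzyme, state),
    f_inhibitor = protein_scaffold_fraction(inhibitor, state),
    inhibitor_bulk = inhibitor$protein_total,
    composition = composition, fiber = fiber, model = model,
    apply_occupancy_to_inhibitor = apply_occupancy_to_inhibitor)
  if (details) res else res$activity
}

#' Noiseless inhibitor titration curve
#'
#' Evaluates the forward activity model across a grid of bulk inhibitor
#' concentrations, holding everything else fixed. Output order follows the
#' input grid.
#'
#' @param inhibitor_concs Bulk inhibitor concentrations, mol/L.
#' @inheritParams normalized_activity
#' @return A `data.frame` with columns `inhibitor_conc_M`, `activity`,
#'   `sd` (0: noiseless) and `n` (1).
#' @export
titration_curve <- function(inhibitor_concs, composition, fiber, enzyme,
                            inhibitor, model = inhibition_model(),
                            apply_occupancy_to_inhibitor = TRUE) {
  stopifnot(is.numeric(inhibitor_concs), length(inhibitor_concs) >= 1L,
            all(is.finite(inhibitor_concs)), all(inhibitor_concs >= 0))
  act <- vapply(inhibitor_concs, function(conc) {
    inh <- inhibitor
    inh$protein_total <- conc
    normalized_activity(composition, fiber, enzyme, inh, model,
                        apply_occupancy_to_inhibitor)
  }, numeric(1))
  data.frame(inhibitor_conc_M = inhibitor_concs, activity = act,
             sd = 0, n = 1L)
}

#' Predicted activity across receptor densities
#'
#' Emulates the receptor-density experiment: the handle-bearing monomer is
#' held at a fixed concentration while inert monomer is added, so a density
#' fraction `d` corresponds to a total monomer pool `fixed_btadna / d`.
#' Lowering the density dilutes the recruited inhibitor over more fiber
#' volume; activity rises once the effective inhibitor concentration drops
#' toward the solution inhibition constant.
#'
#' @param densities Receptor density fractions in `(0, 1]`.
#' @param fixed_btadna Fixed BTA-DNA concentration, mol/L.
#' @inheritParams normalized_activity
#' @return A `data.frame` with columns `density_fraction`, `total_bta_M`,
#'   `ceff_inhibitor_M`, `activity`.
#' @export
density_scan <- function(densities, fixed_btadna, fiber, enzyme, inhibitor,
                         model = inhibition_model(),
                         apply_occupancy_to_inhibitor = TRUE) {
  stopifnot(is.numeric(densities), length(densities) >= 1L,
            all(is.finite(densities)))
  if (any(densities <= 0) || any(densities > 1)) {
    stop_invalid("densities must lie in (0, 1]")
  }
  check_scalar(fixed_btadna, "fixed_btadna", positive = TRUE)
  rows <- lapply(densities, function(d) {
    comp <- assembly_composition(fixed_btadna, fixed_btadna / d - fixed_btadna)
    res <- normalized_activity(comp, fiber, enzyme, inhibitor, model,
                               apply_occupancy_to_inhibitor, details = TRUE)
    data.frame(density_fraction = d, total_bta_M = comp$total,
               ceff_inhibitor_M = res$ceff_inhibitor, activity = res$activity)
  })
  do.call(rbind, rows)
}

#' Activity through cycles of recruiter addition and toehold displacement
#'
#' Simulates the strand-exchange cycling experiment: toehold-bearing enzyme
#' recruiter (`"R_ET"`) and fully complementary displacer (`"D"`) are added
#' sequentially; at each step the cumulative totals are reduced
#' stoichiometrically ([apply_displacement()]), the competition equilibrium
#' re-solved, and the normalized activity evaluated. In this idealized model
#' a displacer excess releases the enzyme completely, restoring activity to
#' exactly 1.
#'
#' @param steps A `data.frame` with columns `strand` (`"R_ET"` or `"D"`) and
#'   `amount` (mol/L added at that step). May have zero rows.
#' @inheritParams normalized_activity
#' @param enzyme A toehold-bearing [recruited_species()]; its
#'   `recruiter_total` is the amount present before the first step.
#' @return A `data.frame` with one baseline row (step 0) plus one row per
#'   step: `step`, `strand`, `amount_M`, `recruiter_total_M`,
#'   `displacer_total_M`, `effective_recruiter_M`, `activity`.
#' @export
displacement_cycle <- function(steps, composition, fiber, enzyme, inhibitor,
                               model = inhibition_model(),
                               apply_occupancy_to_inhibitor = TRUE) {
  stopifnot(is.data.frame(steps),
            all(c("strand", "amount") %in% names(steps)),
            inherits(enzyme, "recruited_species"))
  if (nrow(steps) > 0) {
    if (!all(steps$strand %in% c("R_ET", "D"))) {
      stop_invalid("step strands must be 'R_ET' or 'D'")
    }
    if (any(!is.finite(steps$amount)) || any(steps$amount < 0)) {
      stop_invalid("step amounts must be non-negative")
    }
    if (any(steps$strand == "D") && !enzyme$has_toehold) {
      stop_invalid("species '%s' has no toehold: displacement impossible",
                   enzyme$name)
    }
  }

  cum_r <- enzyme$recruiter_total
  cum_d <- 0
  eval_step <- function(step, strand, amount) {
    base <- enzyme
    base$recruiter_total <- cum_r
    eff <- if (enzyme$has_toehold) apply_displacement(base, cum_d) else base
    act <- normalized_activity(composition, fiber, eff, inhibitor, model,
                               apply_occupancy_to_inhibitor)
    data.frame(step = step, strand = strand, amount_M = amount,
               recruiter_total_M = cum_r, displacer_total_M = cum_d,
               effective_recruiter_M = eff$recruiter_total, activity = act,
               stringsAsFactors = FALSE)
  }

  out <- list(eval_step(0L, "baseline", 0))
  for (i in seq_len(nrow(steps))) {
    if (steps$strand[[i]] == "R_ET") {
      cum_r <- cum_r + steps$amount[[i]]
    } else {
      cum_d <- cum_d + steps$amount[[i]]
    }
    out[[i + 1L]] <- eval_step(i, steps$strand[[i]], steps$amount[[i]])
  }
  do.call(rbind, out)
}
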