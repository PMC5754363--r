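#' A recruited species: protein, recruiter strand and scaffold attachment
#'
#' Bundles the concentrations and duplex affinity of one protein/recruiter
#' pair. The recruiter strand hybridizes on one side to the protein's handle
#' (a long duplex treated as fully formed) and on the other to the 10-nt
#' scaffold handle, whose dissociation constant `duplex_kd` governs the
#' attachment equilibrium. Toehold-bearing recruiters can be stripped off by
#' a fully complementary displacer strand.
#'
#' @param name Species label, e.g. `"enzyme"` or `"inhibitor"`.
#' @param recruiter_total Total recruiter strand concentration, mol/L.
#' @param protein_total Total protein concentration, mol/L.
#' @param duplex_kd Dissociation constant of the handle-recruiter duplex,
#'   mol/L. Default 0.162 uM, calibrated so that 0.5 uM handles bind 75
#'   percent of 20 nM recruiter.
#' @param has_toehold Does the recruiter carry a single-stranded toehold
#'   overhang (making it displaceable)?
#' @return An object of class `recruited_species`.
#' @examples
#' recruited_species("enzyme", recruiter_total = 20e-9, protein_total = 1e-9)
#' @export
recruited_species <- function(name, recruiter_total, protein_total = 0,
                              duplex_kd = bta_defaults$duplex_kd_M,
                              has_toehold = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  check_scalar(recruiter_total, "recruiter_total", nonneg = TRUE)
  check_scalar(protein_total, "protein_total", nonneg = TRUE)
  check_scalar(duplex_kd, "duplex_kd", positive = TRUE)
  stopifnot(is.logical(has_toehold), length(has_toehold) == 1L)
  structure(list(name = name,
                 recruiter_total = recruiter_total,
                 protein_total = protein_total,
                 duplex_kd = duplex_kd,
                 has_toehold = has_toehold),
            class = "recruited_species")
}

#' @export
print.recruited_species <- function(x, ...) {
  cat(sprintf("<recruited_species> %s: %.3g M recruiter%s, %.3g M protein, Kd %.3g M\n",
              x$name, x$recruiter_total, if (x$has_toehold) " (toehold)" else "",
              x$protein_total, x$duplex_kd))
  invisible(x)
}

new_equilibrium_state <- function(free_handle, handle_total, species_tab) {
  structure(list(free_handle = free_handle,
                 handle_total = handle_total,
                 species = species_tab),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium_state> handle total %.3g M, free %.3g M\n",
              x$handle_total, x$free_handle))
  print(x$species, row.names = FALSE)
  invisible(x)
}

#' Exact bimolecular hybridization equilibrium
#'
#' Solves the single handle + recruiter duplex equilibrium
#' `H + R <-> HR` with dissociation constant `kd` using the numerically
#' stable root of the quadratic mass-action equation, and returns the bound
#' recruiter fraction. As `recruiter_total -> 0` the fraction approaches the
#' binding isotherm `handle_total / (kd + handle_total)`.
#'
#' @param handle_total Total scaffold handle concentration, mol/L.
#' @param recruiter_total Total recruiter concentration, mol/L.
#' @param kd Duplex dissociation constant, mol/L.
#' @return A list with `fraction` (bound recruiter fraction in `[0, 1]`) and
#'   `state`, an `equilibrium_state` holding free/bound concentrations. When
#'   `recruiter_total` is zero the fraction is the dilute limit and the state
#'   carries `limit = TRUE`.
#' @examples
#' # 0.5 uM handles, 20 nM recruiter, Kd 0.162 uM: 75% bound, 25% free
#' duplex_fraction_bound(0.5e-6, 20e-9, 0.162e-6)$fraction
#' @export
duplex_fraction_bound <- function(handle_total, recruiter_total,
                                  kd = bta_defaults$duplex_kd_M) {
  check_scalar(handle_total, "handle_total", nonneg = TRUE)
  check_scalar(recruiter_total, "recruiter_total", nonneg = TRUE)
  check_scalar(kd, "kd", positive = TRUE)

  limit <- recruiter_total == 0
  if (limit) {
    fraction <- handle_total / (kd + handle_total)
    bound <- 0
  } else {
    # bound = smaller root of  b^2 - (H+R+Kd) b + H R = 0, computed stably
    s <- handle_total + recruiter_total + kd
    q <- sqrt(s^2 - 4 * handle_total * recruiter_total)
    bound <- 2 * handle_total * recruiter_total / (s + q)
    fraction <- bound / recruiter_total
  }
  tab <- data.frame(name = "recruiter",
                    recruiter_total = recruiter_total,
                    bound_recruiter = bound,
                    free_recruiter = recruiter_total - bound,
                    scaffold_fraction = fraction,
                    stringsAsFactors = FALSE)
  state <- new_equilibrium_state(handle_total - bound, handle_total, tab)
  state$limit <- limit
  list(fraction = fraction, state = state)
}

#' Competition of several recruiter strands for the shared handle pool
#'
#' Simultaneous hybridization equilibrium for any number of recruiter
#' species against one pool of scaffold handles. The free-handle
#' concentration `x` is the unique root of the handle conservation equation
#' `handle_total = x + sum_i R_i * x / (Kd_i + x)`, whose right-hand side is
#' strictly increasing in `x`; it is located by bisection on
#' `[0, handle_total]` (absolute tolerance 1e-15 M, 200 iterations).
#'
#' @param handle_total Total scaffold handle concentration, mol/L.
#' @param species A list of [recruited_species()] (a single species may be
#'   passed unwrapped).
#' @param tol Absolute bisection tolerance on free handle, mol/L.
#' @param max_iter Iteration cap.
#' @return An `equilibrium_state`: `free_handle`, `handle_total`, and a
#'   per-species data frame with `bound_recruiter`, `free_recruiter` and
#'   `scaffold_fraction` columns.
#' @examples
#' sp <- list(recruited_species("R_E", 20e-9), recruited_species("R_I", 200e-9))
#' solve_competition(0.5e-6, sp)
#' @export
solve_competition <- function(handle_total, species, tol = 1e-15,
                              max_iter = 200L) {
  check_scalar(handle_total, "handle_total", nonneg = TRUE)
  if (inherits(species, "recruited_species")) species <- list(species)
  stopifnot(is.list(species), length(species) >= 1L)
  ok <- vapply(species, inherits, logical(1), "recruited_species")
  if (!all(ok)) stop_invalid("'species' must be recruited_species objects")

  R <- vapply(species, `[[`, numeric(1), "recruiter_total")
  K <- vapply(species, `[[`, numeric(1), "duplex_kd")

  if (handle_total == 0) {
    # scaffold omitted: nothing binds
    tab <- data.frame(name = vapply(species, `[[`, character(1), "name"),
                      recruiter_total = R,
                      bound_recruiter = 0,
                      free_recruiter = R,
                      scaffold_fraction = 0,
                      stringsAsFactors = FALSE)
    return(new_equilibrium_state(0, 0, tab))
  }

  residual <- function(x) x + sum(R * x / (K + x)) - handle_total
  lo <- 0
  hi <- handle_total
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (residual(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < tol) break
  }
  x <- (lo + hi) / 2
  if ((hi - lo) >= tol) {
    stop_invalid("competition solver did not converge: residual %.3g M",
                 residual(x))
  }
  # Newton polish to machine precision (bisection guarantees the bracket,
  # Newton removes the absolute-tolerance floor when free handle is tiny)
  for (j in 1:6) {
    step <- residual(x) / (1 + sum(R * K / (K + x)^2))
    x_new <- x - step
    if (!is.finite(x_new) || x_new <= 0 || x_new > handle_total) break
    x <- x_new
    if (abs(step) <= .Machine$double.eps * x) break
  }

  frac <- x / (K + x)
  bound <- R * frac
  tab <- data.frame(name = vapply(species, `[[`, character(1), "name"),
                    recruiter_total = R,
                    bound_recruiter = bound,
                    free_recruiter = R - bound,
                    scaffold_fraction = frac,
                    stringsAsFactors = FALSE)
  new_equilibrium_state(x, handle_total, tab)
}

#' Toehold-mediated displacement of a recruiter strand
#'
#' A displacer strand fully complementary to a toehold-bearing recruiter
#' sequesters it into an inert duplex. The fully complementary duplex is
#' thermodynamically dominant over the nicked 10-bp scaffold attachment, so
#' displacement is modelled as stoichiometric: the effective recruiter pool
#' shrinks by the displacer amount, floored at zero.
#'
#' @param species A [recruited_species()] with `has_toehold = TRUE`.
#' @param displacer_total Total displacer strand concentration, mol/L.
#' @return The species with `recruiter_total` reduced to
#'   `max(0, recruiter_total - displacer_total)`.
#' @examples
#' sp <- recruited_species("R_ET", 20e-9, 1e-9, has_toehold = TRUE)
#' apply_displacement(sp, 40e-9)$recruiter_total # 0: protein released
#' @export
apply_displacement <- function(species, displacer_total) {
  stopifnot(inherits(species, "recruited_species"))
  check_scalar(displacer_total, "displacer_total", nonneg = TRUE)
  if (!species$has_toehold) {
    stop_invalid("species '%s' has no toehold: displacement impossible",
                 species$name)
  }
  species$recruiter_total <- max(0, species$recruiter_total - displacer_total)
  species
}

#' Fraction of a protein recruited on the scaffold
#'
#' The protein-recruiter duplex (long complement) is treated as fully
#' formed, so with protein sub-stoichiometric to its recruiter the fraction
#' of protein on the scaffold equals the recruiter's scaffold-bound
#' fraction from the equilibrium state.
#'
#' @param species The [recruited_species()] of interest.
#' @param state An `equilibrium_state` from [solve_competition()] or
#'   [duplex_fraction_bound()] containing this species (matched by name, or
#'   the sole species).
#' @return Scaffold-bound protein fraction in `[0, 1]`.
#' @export
protein_scaffold_fraction <- function(species, state) {
  stopifnot(inherits(species, "recruited_species"),
            inherits(state, "equilibrium_state"))
  # a fully displaced recruiter leaves the protein free regardless of protein level
  if (species$recruiter_total == 0) return(0)
  if (species$protein_total > species$recruiter_total) {
    stop_invalid("protein (%.3g M) exceeds recruiter (%.3g M): regime not modelled",
                 species$protein_total, species$recruiter_total)
  }
  tab <- state$species
  if (nrow(tab) == 1L) return(tab$scaffold_fraction[[1L]])
  i <- match(species$name, tab$name)
  if (is.na(i)) stop_invalid("species '%s' not present in equilibrium state",
                             species$name)
  tab$scaffold_fraction[[i]]
}
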