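# Shared fixtures: the standard assay conditions used across tests.

# 25% BTA-DNA assembly: 0.5 uM BTA-DNA + 1.5 uM BTA-3OH (2 uM total)
std_composition <- function() assembly_composition(0.5e-6, 1.5e-6)

std_fiber <- function() fiber_model() # r = 15 nm, h = 0.452 nm

std_enzyme <- function(recruiter = 20e-9, protein = 1e-9, ...) {
  recruited_species("enzyme", recruiter, protein, ...)
}

std_inhibitor <- function(recruiter = 20e-9, protein = 10e-9, ...) {
  recruited_species("inhibitor", recruiter, protein, ...)
}

# Independent equilibrium oracle: free handle found with uniroot (Brent) on
# the handle conservation equation, then mass-action bound amounts. Shares no
# code with solve_competition's bisection.
oracle_competition <- function(handle_total, recruiter_totals, kds) {
  f <- function(x) x + sum(recruiter_totals * x / (kds + x)) - handle_total
  x <- stats::uniroot(f, c(0, handle_total), tol = 1e-18)$root
  bound <- recruiter_totals * x / (kds + x)
  list(free_handle = x, bound = bound,
       fraction = ifelse(recruiter_totals > 0, bound / recruiter_totals, 0))
}

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected), rel_tol * abs(expected))
}
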