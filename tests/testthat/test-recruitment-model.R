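test_that("scaffold inhibited fraction is the single-site occupancy", {
  m <- inhibition_model(1.5e-6)
  expect_equal(scaffold_inhibited_fraction(1.5e-6, m), 0.5)
  expect_equal(scaffold_inhibited_fraction(0, m), 0)
  expect_equal(scaffold_inhibited_fraction(19.5e-6, m), 19.5 / 21)
  cs <- seq(0, 1e-4, length.out = 20)
  expect_true(all(diff(vapply(cs, scaffold_inhibited_fraction, numeric(1),
                              model = m)) > 0))
})

test_that("activity from known fractions matches plain arithmetic", {
  comp <- std_composition()
  fb <- std_fiber()
  res <- activity_from_fractions(0.75, 0.75, 10e-9, comp, fb,
                                 inhibition_model(1.5e-6))
  # hand-composed oracle: ceff of 7.5 nM occupancy-weighted inhibitor, then
  # occupancy at Ki = 1.5 uM, then the two-state activity sum
  ceff <- 7.5e-9 / (2e-6 * 6.02214076e23 * pi * 225 * 0.452 * 1e-24)
  theta <- ceff / (1.5e-6 + ceff)
  expect_rel_equal(res$ceff_inhibitor, ceff, 1e-12)
  expect_rel_equal(res$activity, 0.25 + 0.75 * (1 - theta), 1e-12)
  expect_equal(res$activity, 0.30357, tolerance = 1e-4)
  # without the occupancy factor the full bulk is concentrated
  res2 <- activity_from_fractions(0.75, 0.75, 10e-9, comp, fb,
                                  inhibition_model(1.5e-6),
                                  apply_occupancy_to_inhibitor = FALSE)
  expect_rel_equal(res2$ceff_inhibitor, ceff / 0.75, 1e-12)
})

test_that("forward activity model reproduces the assay endpoints", {
  comp <- std_composition()
  fb <- std_fiber()
  enz <- std_enzyme()
  # no inhibitor: normalized activity is exactly 1
  expect_equal(normalized_activity(comp, fb, enz, std_inhibitor(protein = 0)),
               1)
  # saturating inhibitor: plateau at the free-enzyme fraction (~25%),
  # i.e. ~75% maximal inhibition; enzyme hybridization from the exact
  # quadratic equilibrium, plateau from the activity expression
  f_e <- duplex_fraction_bound(0.5e-6, 20e-9)$fraction
  plat <- activity_from_fractions(f_e, 1, 1e-3, comp, fb)
  expect_equal(plat$activity, 1 - f_e, tolerance = 1e-3)
  expect_equal(1 - plat$activity, 0.75, tolerance = 0.01)
  # omitting recruiters or scaffold removes inhibition entirely
  no_re <- normalized_activity(comp, fb, std_enzyme(recruiter = 0),
                               std_inhibitor())
  expect_equal(no_re, 1)
  no_ri <- normalized_activity(comp, fb, enz, std_inhibitor(recruiter = 0))
  expect_equal(no_ri, 1)
  no_bta <- normalized_activity(assembly_composition(0, 2e-6), fb, enz,
                                std_inhibitor())
  expect_equal(no_bta, 1)
})

test_that("titration curve is monotone, bounded and ordered like its input", {
  comp <- std_composition()
  fb <- std_fiber()
  enz <- std_enzyme()
  inh <- std_inhibitor(recruiter = 200e-9)
  grid <- c(0, 0.5e-9, 1e-9, 2e-9, 5e-9, 1e-8, 2e-8, 5e-8, 1e-7)
  tc <- titration_curve(grid, comp, fb, enz, inh)
  expect_equal(tc$inhibitor_conc_M, grid)
  expect_equal(tc$activity[[1]], 1)
  expect_true(all(diff(tc$activity) < 0))
  f_e <- normalized_activity(comp, fb, enz, inh, details = TRUE)$f_enzyme
  expect_true(all(tc$activity >= 1 - f_e - 1e-12 & tc$activity <= 1))
  # shuffled input comes back in input order
  shuf <- titration_curve(rev(grid), comp, fb, enz, inh)
  expect_equal(shuf$activity, rev(tc$activity))
})

test_that("activity rises with total BTA at fixed bulk concentrations", {
  fb <- std_fiber()
  enz <- std_enzyme()
  inh <- std_inhibitor()
  totals <- c(2e-6, 5e-6, 2e-5, 1e-4)
  acts <- vapply(totals, function(tot) {
    normalized_activity(assembly_composition(0.5e-6, tot - 0.5e-6), fb, enz, inh)
  }, numeric(1))
  expect_true(all(diff(acts) > 0))
})

test_that("density scan shows dilution relief below, constancy above, the Ki crossover", {
  fb <- std_fiber()
  enz <- std_enzyme()
  inh <- std_inhibitor()
  scan <- density_scan(c(0.0025, 0.0075, 0.01, 0.05, 0.25), 0.5e-6, fb, enz, inh)
  expect_equal(scan$total_bta_M, 0.5e-6 / scan$density_fraction)
  # dilution relief: far more activity at 0.25% than at 5%
  a <- function(d) scan$activity[scan$density_fraction == d]
  expect_gt(a(0.0025), a(0.05) + 0.05)
  # effective concentration falls, and activity rises, monotonically as
  # inert monomer dilutes the receptors
  expect_true(all(diff(scan$ceff_inhibitor_M) > 0))
  expect_true(all(diff(scan$activity) < 0))
  # the crossover: at 0.75% the (bulk-convention) effective concentration
  # sits below the solution Ki, at 25% far above it
  ceff_bulk <- function(d) {
    effective_concentration(10e-9,
                            assembly_composition(0.5e-6, 0.5e-6 / d - 0.5e-6),
                            fb)
  }
  expect_lt(ceff_bulk(0.0075), 1.5e-6)
  expect_gt(ceff_bulk(0.25), 10 * 1.5e-6)
  # all activities bounded by the free-enzyme fraction and 1
  f_e <- normalized_activity(std_composition(), fb, enz, inh,
                             details = TRUE)$f_enzyme
  expect_true(all(scan$activity >= 1 - f_e - 1e-12 & scan$activity <= 1))
  expect_error(density_scan(0, 0.5e-6, fb, enz, inh), "densities")
})

test_that("displacement cycling alternates and restores full activity", {
  comp <- std_composition()
  fb <- std_fiber()
  enz <- recruited_species("enzyme", 0, 1e-9, has_toehold = TRUE)
  inh <- std_inhibitor()

  steps <- data.frame(strand = c("R_ET", "D"), amount = c(20e-9, 40e-9))
  out <- displacement_cycle(steps, comp, fb, enz, inh)
  expect_equal(out$activity[[1]], 1)         # baseline: no enzyme recruiter
  expect_lt(out$activity[[2]], 0.5)          # recruited: inhibited
  expect_equal(out$activity[[3]], 1)         # displaced: complete restoration

  # three cycles with doubling additions keep alternating; every displaced
  # step returns exactly to baseline in the idealized model
  steps3 <- data.frame(
    strand = rep(c("R_ET", "D"), 3),
    amount = c(20e-9, 40e-9, 80e-9, 160e-9, 320e-9, 640e-9))
  out3 <- displacement_cycle(steps3, comp, fb, enz, inh)
  recruited <- out3$activity[out3$strand == "R_ET"]
  displaced <- out3$activity[out3$strand == "D"]
  expect_true(all(recruited < 0.5))
  expect_equal(displaced, rep(1, 3))

  # empty step list gives just the baseline
  none <- displacement_cycle(steps[0, ], comp, fb, enz, inh)
  expect_equal(nrow(none), 1L)
  # displacement of a toehold-less recruiter is an error
  plain <- recruited_species("enzyme", 0, 1e-9)
  expect_error(displacement_cycle(steps, comp, fb, plain, inh), "toehold")
})
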