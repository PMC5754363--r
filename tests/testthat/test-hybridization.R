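test_that("bimolecular equilibrium leaves a quarter of the recruiter free at assay conditions", {
  res <- duplex_fraction_bound(0.5e-6, 20e-9, 0.162e-6)
  expect_equal(res$fraction, 0.75, tolerance = 2e-3)
  expect_equal(res$state$species$bound_recruiter, 15e-9, tolerance = 2e-3)
  # mass-action consistency of the returned state
  st <- res$state$species
  expect_rel_equal(st$free_recruiter * res$state$free_handle /
                     st$bound_recruiter, 0.162e-6, 1e-9)
})

test_that("bimolecular equilibrium limits behave", {
  # infinitely tight binding with excess handle binds everything
  expect_equal(duplex_fraction_bound(1e-6, 20e-9, 1e-18)$fraction, 1,
               tolerance = 1e-9)
  # dilute-recruiter limit is the binding isotherm; handle = kd gives 1/2
  res <- duplex_fraction_bound(0.162e-6, 0, 0.162e-6)
  expect_equal(res$fraction, 0.5)
  expect_true(res$state$limit)
  # the limit is continuous: tiny recruiter approaches it
  expect_equal(duplex_fraction_bound(0.162e-6, 1e-15, 0.162e-6)$fraction,
               0.5, tolerance = 1e-6)
})

test_that("competition solver matches an independent root-finding oracle", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(1:4, 1)
    handle <- 10^stats::runif(1, -7.5, -5.5)
    R <- 10^stats::runif(n, -9, -6.5)
    K <- 10^stats::runif(n, -8, -5.5)
    sp <- lapply(seq_len(n), function(i) {
      recruited_species(paste0("s", i), R[[i]], duplex_kd = K[[i]])
    })
    state <- solve_competition(handle, sp)
    oracle <- oracle_competition(handle, R, K)
    expect_rel_equal(state$free_handle, oracle$free_handle, 1e-9)
    expect_lt(max(abs(state$species$bound_recruiter - oracle$bound) /
                    oracle$bound), 1e-9)
    # mass conservation: handles and each recruiter
    expect_rel_equal(state$free_handle + sum(state$species$bound_recruiter),
                     handle, 1e-9)
    expect_lt(max(abs(state$species$bound_recruiter +
                        state$species$free_recruiter - R) / R), 1e-12)
    # per-species mass action at the shared free-handle concentration
    ma <- state$species$free_recruiter * state$free_handle /
      state$species$bound_recruiter
    expect_lt(max(abs(ma - K) / K), 1e-9)
  }
})

test_that("single-species competition reduces to the quadratic solution", {
  direct <- duplex_fraction_bound(0.5e-6, 20e-9, 0.162e-6)
  comp <- solve_competition(0.5e-6, recruited_species("R_E", 20e-9))
  expect_rel_equal(comp$species$scaffold_fraction, direct$fraction, 1e-9)
  expect_rel_equal(comp$free_handle, direct$state$free_handle, 1e-9)
})

test_that("a molar-Kd species barely binds and an empty handle pool binds nothing", {
  sp <- list(recruited_species("weak", 20e-9, duplex_kd = 1),
             recruited_species("R_I", 200e-9))
  state <- solve_competition(0.5e-6, sp)
  expect_lt(state$species$scaffold_fraction[[1]], 1e-6)
  empty <- solve_competition(0, sp)
  expect_equal(empty$species$scaffold_fraction, c(0, 0))
})

test_that("scaffold fraction is monotone in own affinity and in competitor load", {
  handle <- 0.5e-6
  frac_at <- function(kd_e, r_i) {
    sp <- list(recruited_species("E", 20e-9, duplex_kd = kd_e),
               recruited_species("I", r_i))
    solve_competition(handle, sp)$species$scaffold_fraction[[1]]
  }
  kds <- 10^seq(-8, -5, length.out = 8)
  expect_true(all(diff(vapply(kds, frac_at, numeric(1), r_i = 200e-9)) < 0))
  ris <- seq(0, 2e-6, length.out = 8)
  expect_true(all(diff(vapply(ris, function(r) frac_at(0.162e-6, r),
                              numeric(1))) < 0))
})

test_that("toehold displacement is stoichiometric and reversible at equilibrium", {
  sp <- recruited_species("R_ET", 20e-9, 1e-9, has_toehold = TRUE)
  expect_equal(apply_displacement(sp, 40e-9)$recruiter_total, 0)
  expect_equal(apply_displacement(sp, 0)$recruiter_total, 20e-9)
  expect_equal(apply_displacement(sp, 10e-9)$recruiter_total, 10e-9)
  plain <- recruited_species("R_E", 20e-9)
  expect_error(apply_displacement(plain, 10e-9), "toehold")

  # displacing then re-adding the same amount of recruiter restores the state
  before <- solve_competition(0.5e-6, sp)
  displaced <- apply_displacement(sp, 40e-9)
  displaced$recruiter_total <- displaced$recruiter_total + 20e-9
  after <- solve_competition(0.5e-6, displaced)
  expect_rel_equal(after$free_handle, before$free_handle, 1e-12)
  expect_equal(after$species$bound_recruiter, before$species$bound_recruiter)
})

test_that("protein scaffold fraction tracks its recruiter", {
  enz <- std_enzyme()
  state <- solve_competition(0.5e-6, list(enz, std_inhibitor()))
  f <- protein_scaffold_fraction(enz, state)
  expect_equal(f, state$species$scaffold_fraction[[1]])
  # fully displaced recruiter leaves the protein free
  gone <- recruited_species("enzyme", 0, 1e-9, has_toehold = TRUE)
  expect_equal(protein_scaffold_fraction(gone, state), 0)
  # protein above recruiter is outside the modelled regime
  heavy <- recruited_species("enzyme", 1e-9, 5e-9)
  expect_error(protein_scaffold_fraction(heavy, state), "regime")
})
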