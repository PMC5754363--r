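test_that("inhibition fit recovers noiseless hyperbolic parameters", {
  truth_vb <- 0.25
  truth_ki <- 2.32e-9
  conc <- c(0, 0.5e-9, 1e-9, 2e-9, 5e-9, 1e-8, 2e-8, 5e-8, 1e-7)
  act <- truth_vb + (1 - truth_vb) * truth_ki / (conc + truth_ki)
  fit <- fit_inhibition(data.frame(inhibitor_conc_M = conc, activity = act))
  expect_rel_equal(fit$v_b, truth_vb, 1e-6)
  expect_rel_equal(fit$ki_app, truth_ki, 1e-6)
  expect_equal(fit$v_0, 1 - fit$v_b)
  expect_lt(fit$residual_sd, 1e-8)
})

test_that("inhibition fit closes the loop with the forward titration model", {
  comp <- std_composition()
  fb <- std_fiber()
  enz <- std_enzyme()
  inh <- std_inhibitor(recruiter = 200e-9)
  grid <- c(0, 0.5e-9, 1e-9, 2e-9, 5e-9, 1e-8, 2e-8, 5e-8, 1e-7)
  tc <- titration_curve(grid, comp, fb, enz, inh)
  fit <- fit_inhibition(tc[, c("inhibitor_conc_M", "activity")])
  det <- normalized_activity(comp, fb, enz, inh, details = TRUE)
  # the forward curve is exactly hyperbolic in bulk inhibitor (the effective
  # concentration is linear in it), so the fit recovers the plateau and the
  # analytic apparent constant Ki / (fold_enhancement * f_inhibitor)
  expect_rel_equal(fit$v_b, 1 - det$f_enzyme, 1e-6)
  ki_analytic <- 1.5e-6 /
    (fold_enhancement(1e-9, comp, fb) * det$f_inhibitor)
  expect_rel_equal(fit$ki_app, ki_analytic, 1e-6)
})

test_that("inhibition fit flags degenerate and poorly designed data", {
  conc <- c(0, 1e-9, 1e-8, 1e-7)
  expect_error(fit_inhibition(data.frame(inhibitor_conc_M = conc,
                                         activity = rep(1, 4))),
               "no inhibition signal")
  expect_error(fit_inhibition(data.frame(inhibitor_conc_M = c(0, 0, 1e-9),
                                         activity = c(1, 1, 0.4))),
               "distinct")
  # top concentration far below the apparent constant: plateau unconstrained
  cc <- c(0, 2e-10, 5e-10, 1e-9)
  shallow <- data.frame(inhibitor_conc_M = cc,
                        activity = 0.25 + 0.75 * 1e-8 / (cc + 1e-8))
  expect_warning(fit_inhibition(shallow), "plateau")
})

test_that("weighting by replicate s.d. is honoured", {
  conc <- c(0, 1e-9, 2.32e-9, 5e-9, 2e-8, 1e-7)
  act <- 0.25 + 0.75 * 2.32e-9 / (conc + 2.32e-9)
  act[3] <- act[3] + 0.2 # corrupt one point
  sd <- rep(0.01, 6)
  sd[3] <- 10 # and downweight it to irrelevance
  fit_w <- fit_inhibition(data.frame(inhibitor_conc_M = conc, activity = act,
                                     sd = sd))
  fit_u <- fit_inhibition(data.frame(inhibitor_conc_M = conc, activity = act))
  expect_rel_equal(fit_w$ki_app, 2.32e-9, 1e-3)
  expect_gt(abs(fit_u$ki_app - 2.32e-9) / 2.32e-9, 0.05)
})

test_that("exchange fit is exact on noiseless data and rescales with time", {
  t <- seq(0, 5, by = 0.25)
  a <- exchange_timecourse(t, a0 = 0.3, a_inf = 1, t_half = 3)
  fit <- fit_exchange(t, a, a0 = 0.3, a_inf = 1)
  expect_rel_equal(fit$t_half, 3, 1e-9)
  expect_rel_equal(fit$rate_k, log(2) / 3, 1e-9)
  expect_equal(fit$t_half, log(2) / fit$rate_k)
  # halving all times doubles the fitted rate
  fit2 <- fit_exchange(t / 2, a, a0 = 0.3, a_inf = 1)
  expect_rel_equal(fit2$rate_k, 2 * fit$rate_k, 1e-9)
  expect_error(fit_exchange(t, a, a0 = 1, a_inf = 1), "differ")
  expect_error(fit_exchange(t[1:2], a[1:2], a0 = 0.3, a_inf = 1), "time points")
  # activities diverging from a_inf have no positive rate
  expect_error(fit_exchange(t, 1 - (a - 0.3), a0 = 0.3, a_inf = 1), "fail")
})

test_that("initial rate extracts the early slope", {
  tr <- data.frame(time_s = seq(0, 600, by = 15))
  tr$fluorescence_au <- 5 + 3 * tr$time_s
  expect_rel_equal(initial_rate(tr, dead_time = 0), 3, 1e-12)
  # baseline offsets do not change the slope
  tr2 <- tr
  tr2$fluorescence_au <- tr2$fluorescence_au + 1000
  expect_rel_equal(initial_rate(tr2, dead_time = 0), 3, 1e-12)
  # a saturating trace is concave: the early window is steeper than the whole
  sat <- data.frame(time_s = seq(0, 3600, by = 15))
  sat$fluorescence_au <- 2 * (1 - exp(-sat$time_s / 600))
  early <- initial_rate(sat, dead_time = 0)
  full <- stats::coef(stats::lm(fluorescence_au ~ time_s, data = sat))[[2]]
  expect_gt(early, full)
  # window outside the trace errors
  expect_error(initial_rate(tr[1:3, ], dead_time = 0), "window")
  expect_error(initial_rate(tr, dead_time = 1e5), "window")
})

test_that("rates normalize against the uninhibited control", {
  expect_equal(normalize_rates(c(3, 1.5), 3), c(1, 0.5))
  expect_equal(normalize_rates(3, 3), 1)
  expect_error(normalize_rates(c(1, 2), 0), "reference_rate")
})

test_that("paired traces with a known activity ratio yield that rate ratio", {
  kin <- enzyme_kinetics(kcat_over_km = 1e3)
  full <- simulate_progress_trace(1e-9, kin)
  quarter <- simulate_progress_trace(0.25e-9, kin)
  r <- initial_rate(quarter) / initial_rate(full)
  expect_equal(r, 0.25, tolerance = 1e-3)
  # in a deliberately slow (deeply linear) regime the ratio is near-exact
  slow <- enzyme_kinetics(kcat_over_km = 1e-2)
  r_slow <- initial_rate(simulate_progress_trace(4e-9, slow)) /
    initial_rate(simulate_progress_trace(1e-9, slow))
  expect_rel_equal(r_slow, 4, 1e-6)
})
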