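#' Noise model for synthetic assay data
#'
#' Gaussian, homoscedastic measurement noise on normalized activity and on
#' raw fluorescence, with a replicate count matching the triplicate
#' structure of the assays. The activity s.d. default of 0.03 is an
#' arbitrary choice resembling typical error-bar magnitudes of
#' plate-reader activity assays.
#'
#' @param sd_activity Gaussian s.d. on normalized activity (default 0.03).
#' @param sd_fluorescence Gaussian s.d. on fluorescence, AU.
#' @param n_replicates Replicates per condition (default 3).
#' @param seed Integer RNG seed; mandatory so every generated dataset is
#'   reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_activity = 0.03, sd_fluorescence = 0,
                        n_replicates = 3L, seed) {
  check_scalar(sd_activity, "sd_activity", nonneg = TRUE)
  check_scalar(sd_fluorescence, "sd_fluorescence", nonneg = TRUE)
  check_scalar(n_replicates, "n_replicates", positive = TRUE)
  if (missing(seed)) stop_invalid("a seed is required for reproducible data")
  check_scalar(seed, "seed")
  structure(list(sd_activity = sd_activity,
                 sd_fluorescence = sd_fluorescence,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "noise_model")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a noisy replicate titration dataset
#'
#' Draws `n_replicates` Gaussian observations around the noiseless forward
#' titration curve at every inhibitor concentration and reports the
#' replicate mean, s.d. and count — the structure of a triplicate
#' plate-reader titration. Deterministic per seed; with `sd_activity = 0`
#' the output equals [titration_curve()] exactly.
#'
#' @param inhibitor_concs Bulk inhibitor concentrations, mol/L.
#' @inheritParams normalized_activity
#' @param noise A [noise_model()].
#' @return A `data.frame` with columns `inhibitor_conc_M`, `activity`
#'   (replicate mean), `sd` and `n`.
#' @export
generate_titration <- function(inhibitor_concs, composition, fiber, enzyme,
                               inhibitor, model = inhibition_model(),
                               noise, apply_occupancy_to_inhibitor = TRUE) {
  stopifnot(inherits(noise, "noise_model"))
  truth <- titration_curve(inhibitor_concs, composition, fiber, enzyme,
                           inhibitor, model, apply_occupancy_to_inhibitor)
  if (noise$sd_activity == 0 && noise$n_replicates == 1L) return(truth)
  with_seed(noise$seed, {
    reps <- vapply(truth$activity, function(mu) {
      stats::rnorm(noise$n_replicates, mu, noise$sd_activity)
    }, numeric(noise$n_replicates))
    reps <- matrix(reps, nrow = noise$n_replicates)
    data.frame(inhibitor_conc_M = truth$inhibitor_conc_M,
               activity = colMeans(reps),
               sd = apply(reps, 2L, stats::sd),
               n = noise$n_replicates)
  })
}

#' Generate a noisy exchange (activity-recovery) time series
#'
#' Noisy observations of the fixed-endpoint exponential
#' [exchange_timecourse()], replicate-averaged per time point.
#'
#' @param t_grid Times, hours.
#' @param a0,a_inf,t_half Truth parameters of the relaxation.
#' @param noise A [noise_model()].
#' @return A `data.frame` with columns `time_h`, `activity`, `sd`, `n`.
#' @export
generate_exchange_series <- function(t_grid, a0, a_inf, t_half = 3, noise) {
  stopifnot(inherits(noise, "noise_model"))
  truth <- exchange_timecourse(t_grid, a0, a_inf, t_half)
  if (noise$sd_activity == 0 && noise$n_replicates == 1L) {
    return(data.frame(time_h = t_grid, activity = truth, sd = 0, n = 1L))
  }
  with_seed(noise$seed, {
    reps <- vapply(truth, function(mu) {
      stats::rnorm(noise$n_replicates, mu, noise$sd_activity)
    }, numeric(noise$n_replicates))
    reps <- matrix(reps, nrow = noise$n_replicates)
    data.frame(time_h = t_grid,
               activity = colMeans(reps),
               sd = apply(reps, 2L, stats::sd),
               n = noise$n_replicates)
  })
}

#' Generate a set of progress traces across assay conditions
#'
#' One substrate-turnover trace per condition, where each condition is
#' described by its active-enzyme fraction (1 for controls omitting
#' recruiters, scaffold or inhibitor; the forward-model activity
#' otherwise). Gaussian noise with `sd_fluorescence` is added to the
#' fluorescence readings.
#'
#' @param active_fractions Named numeric vector of active-enzyme fractions
#'   per condition.
#' @param enzyme_conc Total enzyme concentration, mol/L (default 1 nM).
#' @param kin An [enzyme_kinetics()].
#' @param noise A [noise_model()]; only `sd_fluorescence` and `seed` are
#'   used.
#' @param duration,dt,dead_time Trace timing, seconds; defaults 3600 s
#'   sampled every 15 s after a 120-s dead time.
#' @return A named list of [progress_trace()] objects.
#' @export
generate_trace_set <- function(active_fractions, enzyme_conc = 1e-9,
                               kin = enzyme_kinetics(), noise,
                               duration = 3600, dt = 15, dead_time = 120) {
  stopifnot(is.numeric(active_fractions), length(active_fractions) >= 1L,
            !is.null(names(active_fractions)),
            all(active_fractions >= 0), all(active_fractions <= 1),
            inherits(noise, "noise_model"))
  check_scalar(enzyme_conc, "enzyme_conc", positive = TRUE)
  with_seed(noise$seed, {
    out <- lapply(names(active_fractions), function(cond) {
      tr <- simulate_progress_trace(active_fractions[[cond]] * enzyme_conc,
                                    kin, duration, dt, dead_time,
                                    condition = cond)
      if (noise$sd_fluorescence > 0) {
        tr$fluorescence_au <- tr$fluorescence_au +
          stats::rnorm(nrow(tr), 0, noise$sd_fluorescence)
      }
      tr
    })
    names(out) <- names(active_fractions)
    out
  })
}
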