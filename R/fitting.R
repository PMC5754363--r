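#' Fit the apparent inhibition constant to a titration dataset
#'
#' Nonlinear least-squares fit of the hyperbolic competitive-inhibition
#' dose-response
#' \deqn{V = V_b + (1 - V_b) \frac{K_{i,app}}{[I] + K_{i,app}}}
#' to normalized activities as a function of bulk inhibitor concentration.
#' The inhibitable amplitude is constrained to `1 - V_b`, so the fit has two
#' free parameters: the residual activity at saturating inhibitor `V_b` and
#' the apparent inhibition constant. `K_i,app` is fitted on the log scale to
#' enforce positivity; starting values are `V_b = min(activity)` and the
#' concentration nearest the half-amplitude crossing.
#'
#' @param data A `data.frame` with columns `inhibitor_conc_M` and `activity`;
#'   an optional `sd` column with all-positive values triggers `1/sd^2`
#'   weighting.
#' @return An object of class `inhibition_fit`: `v_b`, `v_0` (`= 1 - v_b`),
#'   `ki_app` (mol/L), `se` (named standard errors for `v_b` and `ki_app`),
#'   `residual_sd`, `fitted` values and the underlying `nls` object.
#' @examples
#' curve <- data.frame(inhibitor_conc_M = c(0, 1e-9, 2e-9, 5e-9, 2e-8, 1e-7))
#' curve$activity <- 0.25 + 0.75 * 2.32e-9 / (curve$inhibitor_conc_M + 2.32e-9)
#' fit_inhibition(curve)
#' @export
fit_inhibition <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("inhibitor_conc_M", "activity") %in% names(data)))
  conc <- data$inhibitor_conc_M
  act <- data$activity
  if (any(!is.finite(conc)) || any(!is.finite(act)) || any(conc < 0)) {
    stop_invalid("titration data must be finite with non-negative concentrations")
  }
  if (length(unique(conc)) < 3L) {
    stop_invalid("need >= 3 distinct inhibitor concentrations")
  }
  amplitude <- max(act) - min(act)
  if (amplitude < 0.01) {
    stop_invalid("no inhibition signal: activity range %.3g is flat", amplitude)
  }

  vb0 <- max(min(act), 1e-6)
  half <- (max(act) + min(act)) / 2
  pos <- conc > 0
  ki0 <- conc[pos][which.min(abs(act[pos] - half))]

  w <- NULL
  if ("sd" %in% names(data) && all(is.finite(data$sd)) && all(data$sd > 0)) {
    w <- 1 / data$sd^2
  }
  df <- data.frame(conc = conc, act = act)
  args <- list(act ~ vb + (1 - vb) * exp(lki) / (conc + exp(lki)),
               data = df, start = list(vb = vb0, lki = log(ki0)),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(w)) args$weights <- w
  fit <- do.call(minpack.lm::nlsLM, args)

  est <- stats::coef(fit)
  vb <- unname(est[["vb"]])
  ki <- exp(unname(est[["lki"]]))
  if (vb < -0.05 || vb > 1.05) {
    warning("fitted residual activity outside [0, 1]: check the data")
  }
  se_raw <- summary(fit)$coefficients[, "Std. Error"]
  se <- c(v_b = unname(se_raw[["vb"]]),
          ki_app = ki * unname(se_raw[["lki"]]))  # delta method off log scale
  if (max(conc) < 10 * ki) {
    warning(sprintf(
      "top concentration %.3g M is < 10x the fitted K_i,app (%.3g M): plateau poorly constrained",
      max(conc), ki))
  }
  if (min(conc) > ki / 10) {
    warning("no near-zero inhibitor concentration: baseline poorly constrained")
  }

  structure(list(v_b = vb, v_0 = 1 - vb, ki_app = ki, se = se,
                 residual_sd = summary(fit)$sigma,
                 fitted = stats::fitted(fit), nls = fit),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("<inhibition_fit> K_i,app = %.3g +/- %.2g M, V_b = %.3f +/- %.3f (V_0 = %.3f)\n",
              x$ki_app, x$se[["ki_app"]], x$v_b, x$se[["v_b"]], x$v_0))
  invisible(x)
}

#' Fixed-endpoint single-exponential fit of an exchange time course
#'
#' Fits `A(t) = a_inf + (a0 - a_inf) * exp(-k t)` with the endpoints `a0`
#' and `a_inf` held fixed at independently measured reference activities and
#' only the rate `k` free. The rate is fitted on the log scale; the start
#' value comes from a log-linear regression of the normalized departure from
#' `a_inf`.
#'
#' @param times Time points, hours.
#' @param activities Normalized activities at `times`.
#' @param a0 Activity at `t = 0` (fixed; e.g. the undiluted reference).
#' @param a_inf Activity at `t = Inf` (fixed; e.g. the inhibitor-free
#'   reference).
#' @return An object of class `exchange_fit`: `a0`, `a_inf`, `rate_k`
#'   (1/hour), `t_half` (`log(2)/rate_k`, hours), `se_rate_k` and the `nls`
#'   object.
#' @examples
#' t <- seq(0, 5, by = 0.5)
#' a <- 1 - 0.7 * 2^(-t / 3)
#' fit_exchange(t, a, a0 = 0.3, a_inf = 1)$t_half # 3 h
#' @export
fit_exchange <- function(times, activities, a0, a_inf) {
  stopifnot(is.numeric(times), is.numeric(activities),
            length(times) == length(activities))
  check_scalar(a0, "a0")
  check_scalar(a_inf, "a_inf")
  if (a0 == a_inf) stop_invalid("a0 and a_inf must differ")
  if (length(times) < 3L) stop_invalid("need >= 3 time points")
  if (any(!is.finite(times)) || any(!is.finite(activities))) {
    stop_invalid("times and activities must be finite")
  }

  ratio <- (activities - a_inf) / (a0 - a_inf)
  usable <- ratio > 0 & times >= 0
  if (sum(usable) < 2L) {
    stop_invalid("exchange fit failed: no decaying signal toward a_inf")
  }
  slope <- stats::coef(stats::lm(log(ratio[usable]) ~ times[usable]))[[2L]]
  if (!is.finite(slope) || slope >= 0) {
    stop_invalid("exchange fit failed: non-positive rate estimate")
  }
  departure <- diff(ratio)
  if (any(departure > 0.2)) {
    warning("activities are grossly non-monotone toward a_inf")
  }

  df <- data.frame(t = times, a = activities)
  fit <- minpack.lm::nlsLM(
    a ~ a_inf + (a0 - a_inf) * exp(-exp(lk) * t),
    data = df, start = list(lk = log(-slope)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  k <- exp(stats::coef(fit)[["lk"]])
  se_lk <- summary(fit)$coefficients["lk", "Std. Error"]

  structure(list(a0 = a0, a_inf = a_inf, rate_k = k,
                 t_half = log(2) / k, se_rate_k = k * se_lk, nls = fit),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf("<exchange_fit> k = %.3g /h (t1/2 = %.2f h), endpoints %.3f -> %.3f\n",
              x$rate_k, x$t_half, x$a0, x$a_inf))
  invisible(x)
}

#' Initial rate from a substrate-turnover progress trace
#'
#' Ordinary least-squares slope of fluorescence against time over the
#' initial portion of the trace: after discarding the instrument dead time,
#' the window covers the first 10 percent of the trace duration or the first
#' 20 points, whichever is larger.
#'
#' @param trace A [progress_trace()] or a `data.frame` with columns `time_s`
#'   and `fluorescence_au`.
#' @param dead_time Seconds to discard from the start of the time axis
#'   (sample handling before the first usable reading). Default 120 s; a
#'   `progress_trace` supplies its own recorded dead time.
#' @param window_fraction Fraction of the post-dead-time duration in the
#'   fitting window.
#' @param min_points Minimum number of points in the window.
#' @return Slope in fluorescence units per second.
#' @examples
#' tr <- data.frame(time_s = 0:100, fluorescence_au = 5 + 3 * (0:100))
#' initial_rate(tr, dead_time = 0) # 3
#' @export
initial_rate <- function(trace, dead_time = NULL, window_fraction = 0.1,
                         min_points = 20L) {
  if (inherits(trace, "progress_trace")) {
    if (is.null(dead_time)) dead_time <- attr(trace, "dead_time")
    df <- as.data.frame(trace)
  } else {
    df <- trace
    if (is.null(dead_time)) dead_time <- 120
  }
  stopifnot(is.data.frame(df),
            all(c("time_s", "fluorescence_au") %in% names(df)))
  check_scalar(dead_time, "dead_time", nonneg = TRUE)

  df <- df[df$time_s >= dead_time, , drop = FALSE]
  if (nrow(df) < 5L) {
    stop_invalid("initial-rate window outside trace: only %d points after dead time",
                 nrow(df))
  }
  dur <- max(df$time_s) - min(df$time_s)
  in_window <- df$time_s <= min(df$time_s) + window_fraction * dur
  n <- max(sum(in_window), min(min_points, nrow(df)))
  window <- df[seq_len(n), , drop = FALSE]
  if (nrow(window) < 5L) {
    stop_invalid("initial-rate window has %d points; need >= 5", nrow(window))
  }
  stats::coef(stats::lm(fluorescence_au ~ time_s, data = window))[[2L]]
}

#' Normalize rates to a reference condition
#'
#' @param rates Numeric vector of initial rates.
#' @param reference_rate Rate of the control (e.g. inhibitor omitted); maps
#'   to a normalized activity of 1.
#' @return `rates / reference_rate`.
#' @export
normalize_rates <- function(rates, reference_rate) {
  stopifnot(is.numeric(rates))
  check_scalar(reference_rate, "reference_rate", positive = TRUE)
  rates / reference_rate
}
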