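#' Numerical integration settings
#'
#' @param rel_tol,abs_tol Relative and absolute solver tolerances. The system
#'   is stiff during the phage burst (densities span ten orders of
#'   magnitude), so the default relative tolerance is tight (`1e-8`) and the
#'   absolute tolerance is 0.01 cells/ml.
#' @param t_end Integration horizon (h); default 24, the competition-assay
#'   window. Long-run fixation analyses raise it.
#' @param max_step Maximum internal step size (h), or `NULL` for unlimited.
#' @param clip_negative If `TRUE` (default), tiny negative densities produced
#'   by the solver are clipped to zero in the reported trajectory. The raw
#'   solver state is never clipped mid-integration, which would alter the
#'   dynamics.
#' @param fixation_threshold Density (cells/ml) below which the sensitive
#'   pool is considered collapsed; default 1, below one cell per assay
#'   volume.
#' @param grid_dt Spacing of the reported output grid (h). Densely spaced
#'   output (default 0.02 h) lets trajectory series drive the reduced model
#'   through spline interpolants with negligible interpolation error.
#' @return An object of class `"integration_settings"`.
#' @export
integration_settings <- function(rel_tol = 1e-8, abs_tol = 1e-2, t_end = 24,
                                 max_step = NULL, clip_negative = TRUE,
                                 fixation_threshold = 1, grid_dt = 0.02) {
  stopifnot(rel_tol > 0, abs_tol > 0, t_end > 0, grid_dt > 0,
            fixation_threshold >= 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, t_end = t_end,
                 max_step = max_step, clip_negative = clip_negative,
                 fixation_threshold = fixation_threshold, grid_dt = grid_dt),
            class = "integration_settings")
}

#' Integrate the full five-genotype bacteria-phage system
#'
#' Solves the six-ODE system with an adaptive stiff-capable method
#' (`deSolve::lsoda`). Optionally augments the dynamics with mass-action
#' horizontal transfer of the CRISPR locus (see [hgt_derivatives()]).
#'
#' @param initial A [pop_state()] giving densities at `t = 0`.
#' @param params A [model_params()].
#' @param settings An [integration_settings()].
#' @param hgt Optional [hgt_settings()]; `NULL` disables horizontal transfer.
#' @param times Optional explicit output time grid; defaults to
#'   `seq(0, t_end, by = grid_dt)`.
#' @return A `"phage_traj"` object: a data frame with columns
#'   `time, S_minus, R_minus, S_plus, R_plus, C_plus, V` plus derived series
#'   `N_total, N_plus_freq, f_delta, resistance_freq, sel_coeff`, all
#'   recomputed from the states. Parameters and settings are kept as
#'   attributes.
#' @examples
#' traj <- integrate_full(pop_state(S_minus = 9e5, S_plus = 1e5, V = 1e4),
#'                        model_params(), integration_settings(t_end = 5))
#' tail(as.data.frame(traj), 2)
#' @export
integrate_full <- function(initial, params, settings = integration_settings(),
                           hgt = NULL, times = NULL) {
  validate_state(initial)
  validate_params(params)
  stopifnot(inherits(settings, "integration_settings"))
  if (is.null(times))
    times <- seq(0, settings$t_end, by = settings$grid_dt)
  if (is.unsorted(times, strictly = TRUE))
    stop("output times must be strictly increasing", call. = FALSE)
  pv <- unlist(params[param_names], use.names = FALSE)
  if (is.null(hgt)) {
    func <- function(t, y, parms) list(rhs_raw(y, parms))
  } else {
    stopifnot(inherits(hgt, "hgt_settings"))
    gam <- hgt$gamma
    q <- hgt$spacer_transfer_fraction
    func <- function(t, y, parms)
      list(rhs_raw(y, parms) + hgt_flux_raw(y, gam, q))
  }
  y0 <- as.numeric(initial[state_names]) + 0  # strip t
  sol <- deSolve::lsoda(
    y = y0, times = times, func = func, parms = pv,
    rtol = settings$rel_tol, atol = settings$abs_tol,
    hmax = if (is.null(settings$max_step)) NULL else settings$max_step)
  attr_di <- attributes(sol)
  istate <- attr_di$istate[1L]
  if (istate < 0 || nrow(sol) < length(times)) {
    t_fail <- if (nrow(sol) >= 1) sol[nrow(sol), 1L] else times[1L]
    stop(sprintf("integration failed near t = %.4f h (lsoda istate = %d)",
                 t_fail, istate), call. = FALSE)
  }
  build_trajectory(sol, params, settings, hgt)
}

build_trajectory <- function(sol, params, settings, hgt = NULL) {
  df <- as.data.frame(unclass(sol)[, 1:7, drop = FALSE])
  names(df) <- c("time", state_names)
  if (isTRUE(settings$clip_negative))
    for (nm in state_names) df[[nm]] <- pmax(df[[nm]], 0)
  Np <- df$S_plus + df$R_plus + df$C_plus
  df$N_total <- df$S_minus + df$R_minus + Np
  df$N_plus_freq <- ifelse(df$N_total > 0, Np / df$N_total, NA_real_)
  df$f_delta <- f_delta_or_na(df$S_minus, df$R_minus, df$S_plus, df$R_plus,
                              df$C_plus)
  df$resistance_freq <- ifelse(df$N_total > 0,
                               (df$R_minus + df$R_plus + df$C_plus) /
                                 df$N_total, NA_real_)
  df$sel_coeff <- params$alpha * df$V * df$f_delta
  structure(df, class = c("phage_traj", "data.frame"),
            params = params, settings = settings, hgt = hgt)
}

#' Fixed-step Euler integration of the full system
#'
#' A deliberately simple forward-Euler scheme used as an independent
#' cross-check of the adaptive solver: the two share only the right-hand
#' side, not the stepping logic.
#'
#' @inheritParams integrate_full
#' @param t_end Horizon (h).
#' @param dt Fixed step (h); default `1e-4`.
#' @return A [pop_state()] at `t_end` (negative underflow clipped to 0).
#' @export
integrate_euler <- function(initial, params, t_end = 24, dt = 1e-4,
                            hgt = NULL) {
  validate_state(initial)
  validate_params(params)
  stopifnot(t_end > 0, dt > 0)
  pv <- unlist(params[param_names], use.names = FALSE)
  use_hgt <- !is.null(hgt)
  if (use_hgt) {
    stopifnot(inherits(hgt, "hgt_settings"))
    gam <- hgt$gamma
    q <- hgt$spacer_transfer_fraction
  }
  y <- as.numeric(initial[state_names])
  n <- floor(t_end / dt + 1e-9)
  for (i in seq_len(n)) {
    d <- rhs_raw(y, pv)
    if (use_hgt) d <- d + hgt_flux_raw(y, gam, q)
    y <- y + dt * d
  }
  rem <- t_end - n * dt
  if (rem > 1e-12) {
    d <- rhs_raw(y, pv)
    if (use_hgt) d <- d + hgt_flux_raw(y, gam, q)
    y <- y + rem * d
  }
  y <- pmax(y, 0)
  pop_state(y[1L], y[2L], y[3L], y[4L], y[5L], y[6L], t = t_end)
}

#' Integrate the reduced CRISPR-frequency equation
#'
#' Solves `dN+/dt = alpha * V(t) * f_delta(t) * N+ (1 - N+)` driven by
#' externally supplied series -- typically spline interpolants extracted from
#' a full-model trajectory (see [reduced_from_trajectory()]), which is the
#' derivation the reduced equation rests on.
#'
#' @param N_plus0 Initial CRISPR-positive frequency, in \[0, 1\].
#' @param f_delta_fun,V_fun Functions of time (h) returning `f_delta(t)` and
#'   `V(t)` on `[0, t_end]`.
#' @param alpha Adsorption rate constant (ml/h).
#' @param settings An [integration_settings()].
#' @param times Optional output grid.
#' @return A data frame with columns `time` and `N_plus`.
#' @export
integrate_reduced <- function(N_plus0, f_delta_fun, V_fun, alpha,
                              settings = integration_settings(),
                              times = NULL) {
  if (N_plus0 < 0 || N_plus0 > 1)
    stop("N_plus0 must be in [0, 1]", call. = FALSE)
  stopifnot(is.function(f_delta_fun), is.function(V_fun))
  if (is.null(times))
    times <- seq(0, settings$t_end, by = settings$grid_dt)
  rhs <- function(t, y, parms) {
    x <- min(max(y[1L], 0), 1)  # guard solver overshoot at the boundaries
    list(alpha * V_fun(t) * f_delta_fun(t) * x * (1 - x))
  }
  sol <- deSolve::lsoda(y = N_plus0, times = times, func = rhs, parms = NULL,
                        rtol = settings$rel_tol, atol = 1e-12)
  data.frame(time = sol[, 1L], N_plus = pmin(pmax(sol[, 2L], 0), 1))
}

#' Drive the reduced equation with series from a full-model trajectory
#'
#' Builds cubic-spline interpolants of `V(t)` and `f_delta(t)` from a
#' trajectory and integrates the reduced frequency equation from the
#' trajectory's initial CRISPR-positive frequency. With zero costs, mutation
#' and spacer acquisition the result reproduces the full model's
#' `N_plus_freq` series.
#'
#' @param traj A `"phage_traj"` from [integrate_full()].
#' @param settings Optional [integration_settings()]; defaults to those of
#'   the trajectory.
#' @return A data frame with columns `time` and `N_plus`.
#' @export
reduced_from_trajectory <- function(traj, settings = NULL) {
  stopifnot(inherits(traj, "phage_traj"))
  if (is.null(settings)) settings <- attr(traj, "settings")
  if (anyNA(traj$f_delta))
    stop("trajectory contains states with undefined f_delta", call. = FALSE)
  V_fun <- stats::splinefun(traj$time, traj$V, method = "fmm")
  f_fun <- stats::splinefun(traj$time, traj$f_delta, method = "fmm")
  p <- attr(traj, "params")
  integrate_reduced(traj$N_plus_freq[1L], f_fun, V_fun, p$alpha,
                    settings = settings, times = traj$time)
}

#' Classify the direction of CRISPR-frequency change over a run
#'
#' Integrates the full system and compares the CRISPR-positive frequency at
#' the horizon against its initial value, with a small dead-band absorbing
#' solver noise. With zero costs and phage present the outcome equals the
#' sign of `f_delta` at time 0.
#'
#' @inheritParams integrate_full
#' @param dead_band Absolute frequency change below which the outcome is
#'   `"no_change"`; default `1e-6`.
#' @return One of `"increase"`, `"decrease"`, `"no_change"`.
#' @export
sign_outcome <- function(initial, params, settings = integration_settings(),
                         hgt = NULL, dead_band = 1e-6) {
  f_delta(initial)  # errors early if undefined
  traj <- integrate_full(initial, params, settings, hgt = hgt)
  d <- traj$N_plus_freq[nrow(traj)] - traj$N_plus_freq[1L]
  if (abs(d) < dead_band) "no_change" else if (d > 0) "increase" else "decrease"
}

#' Detect collapse of the phage-sensitive pool and the frequency plateau
#'
#' During a phage epidemic the sensitive cells (`S_minus + S_plus`) are
#' driven out; once only protected cells remain, `f_delta` returns to zero
#' (provided protection is present on both sides) and the CRISPR-positive
#' frequency stops changing.
#'
#' @param traj A `"phage_traj"` from [integrate_full()].
#' @param plateau_tol Threshold on `|dN_plus/dt|` at the final state for the
#'   plateau flag (1/h); default `1e-9`.
#' @return A list: `collapse_reached` (logical), `collapse_time` (h, `NA` if
#'   not reached), `f_delta_end` (`f_delta` at the final time), `dNplus_end`
#'   (analytic `dN+/dt` at the final state) and `plateau` (logical).
#' @export
fixation_check <- function(traj, plateau_tol = 1e-9) {
  stopifnot(inherits(traj, "phage_traj"))
  settings <- attr(traj, "settings")
  params <- attr(traj, "params")
  sens <- traj$S_minus + traj$S_plus
  idx <- which(sens < settings$fixation_threshold)
  collapse_reached <- length(idx) > 0
  last <- nrow(traj)
  y_end <- as.numeric(traj[last, state_names])
  d <- rhs_raw(y_end, unlist(params[param_names], use.names = FALSE))
  hgt <- attr(traj, "hgt")
  if (!is.null(hgt))
    d <- d + hgt_flux_raw(y_end, hgt$gamma, hgt$spacer_transfer_fraction)
  N <- sum(y_end[1:5])
  Np_freq <- traj$N_plus_freq[last]
  dNp <- (d[3L] + d[4L] + d[5L] - Np_freq * sum(d[1:5])) / N
  list(collapse_reached = collapse_reached,
       collapse_time = if (collapse_reached) traj$time[idx[1L]] else NA_real_,
       f_delta_end = traj$f_delta[last],
       dNplus_end = dNp,
       plateau = abs(dNp) < plateau_tol)
}

#' Build a population state from genotype frequencies
#'
#' @param freqs Numeric vector of five genotype frequencies in the order
#'   `S_minus, R_minus, S_plus, R_plus, C_plus` (names, if present, are
#'   checked); must sum to 1 within `tol`.
#' @param N0 Total bacterial density (cells/ml).
#' @param V Free phage density (pfu/ml).
#' @param t Time (h).
#' @param tol Tolerance on the frequency sum.
#' @return A [pop_state()].
#' @export
state_from_frequencies <- function(freqs, N0, V = 0, t = 0, tol = 1e-6) {
  freqs <- check_frequencies(freqs, tol)
  pop_state(S_minus = N0 * freqs[[1L]], R_minus = N0 * freqs[[2L]],
            S_plus = N0 * freqs[[3L]], R_plus = N0 * freqs[[4L]],
            C_plus = N0 * freqs[[5L]], V = V, t = t)
}

check_frequencies <- function(freqs, tol = 1e-6) {
  if (length(freqs) != 5L)
    stop("expected five genotype frequencies", call. = FALSE)
  if (!is.null(names(freqs)) && !identical(names(freqs), state_names[1:5]) &&
      all(state_names[1:5] %in% names(freqs)))
    freqs <- freqs[state_names[1:5]]
  freqs <- as.numeric(freqs)
  if (any(freqs < 0)) stop("frequencies must be non-negative", call. = FALSE)
  if (abs(sum(freqs) - 1) > tol)
    stop("frequencies must sum to 1 (got ", format(sum(freqs)), ")",
         call. = FALSE)
  freqs
}

#' Predicted relative change in CRISPR-positive frequency under phage
#'
#' Runs paired 24 h integrations from the same initial genotype mix, one arm
#' with phage at density `V0` and one without, and returns the competition
#' response variable
#' `(N+ frequency with phage - N+ frequency without) / N+ frequency without`
#' at the horizon. This is the model prediction matched against observed
#' competition outcomes.
#'
#' @inheritParams state_from_frequencies
#' @param N0 Initial total bacterial density (cells/ml); default `1e6`.
#' @param V0 Phage dose in the phage arm (pfu/ml); default `1e4`.
#' @param params A [model_params()].
#' @param settings An [integration_settings()].
#' @return The predicted relative change (dimensionless).
#' @export
predict_experiment <- function(freqs, N0 = 1e6, V0 = 1e4,
                               params = model_params(),
                               settings = integration_settings()) {
  freqs <- check_frequencies(freqs)
  run_np <- function(V) {
    # only the endpoint frequency is needed
    traj <- integrate_full(state_from_frequencies(freqs, N0, V), params,
                           settings, times = c(0, settings$t_end))
    traj$N_plus_freq[nrow(traj)]
  }
  np_phage <- run_np(V0)
  np_none <- run_np(0)
  if (!is.finite(np_none) || np_none <= 0)
    stop("no-phage arm ended with zero CRISPR+ frequency; relative change ",
         "undefined", call. = FALSE)
  (np_phage - np_none) / np_none
}
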