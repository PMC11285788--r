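#' Population state of the mixed bacteria-phage system
#'
#' One time point of the five-genotype system: bacterial densities split by
#' CRISPR-Cas carriage (`+`/`-`) and phage-protection phenotype, plus the
#' free-phage density. Genotypes: `S_minus` (no CRISPR, phage-sensitive),
#' `R_minus` (no CRISPR, surface-resistant), `S_plus` (CRISPR, sensitive),
#' `R_plus` (CRISPR, surface-resistant), `C_plus` (CRISPR, spacer-immune).
#'
#' @param S_minus,R_minus,S_plus,R_plus,C_plus Bacterial densities (cells/ml),
#'   all >= 0.
#' @param V Free phage density (pfu/ml), >= 0.
#' @param t Time (h).
#' @return An object of class `"pop_state"`: a named numeric vector with
#'   components `S_minus, R_minus, S_plus, R_plus, C_plus, V, t`.
#' @examples
#' s <- pop_state(S_minus = 5e5, S_plus = 3e5, C_plus = 2e5, V = 1e4)
#' crispr_frequency(s)
#' @export
pop_state <- function(S_minus = 0, R_minus = 0, S_plus = 0, R_plus = 0,
                      C_plus = 0, V = 0, t = 0) {
  x <- c(S_minus = S_minus, R_minus = R_minus, S_plus = S_plus,
         R_plus = R_plus, C_plus = C_plus, V = V, t = t)
  validate_state(x)
  structure(x, class = "pop_state")
}

state_names <- c("S_minus", "R_minus", "S_plus", "R_plus", "C_plus", "V")

validate_state <- function(x) {
  if (!all(state_names %in% names(x)))
    stop("state must have components ", paste(state_names, collapse = ", "),
         call. = FALSE)
  v <- x[state_names]
  if (any(!is.finite(v))) stop("state densities must be finite", call. = FALSE)
  if (any(v < 0)) stop("state densities must be non-negative", call. = FALSE)
  invisible(x)
}

#' @export
print.pop_state <- function(x, ...) {
  cat("Population state at t =", unname(x["t"]), "h\n")
  print(unclass(x)[state_names])
  invisible(x)
}

# Raw right-hand side of the six-ODE system; y and out are unnamed numeric
# vectors ordered (S-, R-, S+, R+, C+, V). No validation: hot path for the
# integrators. pv is unlist(params)[param_names].
rhs_raw <- function(y, pv) {
  Sm <- y[1L]; Rm <- y[2L]; Sp <- y[3L]; Rp <- y[4L]; Cp <- y[5L]; V <- y[6L]
  r <- pv[1L]; K <- pv[2L]; mb <- pv[3L]; mv <- pv[4L]; al <- pv[5L]
  B <- pv[6L]; mu <- pv[7L]; A <- pv[8L]; cR <- pv[9L]; cI <- pv[10L]
  g <- r * (1 - (Sm + Rm + Sp + Rp + Cp) / K)
  c((g * (1 - mu) - al * V - mb) * Sm,
    mu * g * Sm + (g * (1 - cR) - mb) * Rm,
    (g * (1 - mu) - al * V - mb) * Sp,
    mu * g * Sp + (g * (1 - cR) - mb) * Rp,
    al * A * V * Sp + (g * (1 - cI) - mb) * Cp,
    (al * B * (Sm + Sp * (1 - A)) - mv - al * (Sp + Sm + Cp)) * V)
}

#' Right-hand sides of the five-genotype bacteria-phage ODE system
#'
#' Evaluates the instantaneous rates of change (per hour) of the six state
#' variables. Bacteria divide logistically at rate `r (1 - N/K)`; division of
#' sensitive cells yields surface-resistant mutants with probability `mu`;
#' resistant and immune cells pay division-rate costs `c_R` and `c_I`. Phage
#' infect sensitive cells by mass action (`alpha V S`), and an infected
#' CRISPR-positive sensitive cell becomes spacer-immune with probability `A`
#' (otherwise it lyses). Lysis of `S_minus` and of non-acquiring `S_plus`
#' releases `B` phage each; free phage decay at `m_v` and are lost by
#' adsorption to `S_minus`, `S_plus` and `C_plus` cells (surface-resistant
#' cells do not adsorb phage).
#'
#' @param state A [pop_state()].
#' @param params A [model_params()].
#' @return Named numeric vector of length 6 (same component order as the
#'   state, units per hour).
#' @examples
#' derivatives(pop_state(S_minus = 1e6, V = 1e4), model_params())
#' @export
derivatives <- function(state, params) {
  validate_state(state)
  validate_params(params)
  d <- rhs_raw(as.numeric(state[state_names]),
               unlist(params[param_names], use.names = FALSE))
  names(d) <- state_names
  d
}

#' Difference in protection frequency between CRISPR+ and CRISPR- cells
#'
#' The statistic whose sign determines the direction of selection on
#' CRISPR-positive cells during a phage epidemic:
#' \deqn{f_\Delta = \frac{R^+ + C^+}{S^+ + R^+ + C^+} - \frac{R^-}{R^- + S^-}}
#' i.e. the phage-protected fraction (surface-resistant or spacer-immune) of
#' the CRISPR-positive subpopulation minus the resistant fraction of the
#' CRISPR-negative subpopulation. Always in \[-1, 1\].
#'
#' The statistic is undefined when either subpopulation is empty; this is an
#' error rather than a silent `NaN`/0, since the missing denominator carries
#' no information about selection. Grid scans must filter such states.
#'
#' @inheritParams derivatives
#' @return A number in \[-1, 1\].
#' @examples
#' # 30% protected among CRISPR+, 15% resistant among CRISPR-:
#' f_delta(pop_state(S_minus = 8.5e5, R_minus = 1.5e5,
#'                   S_plus = 7e5, R_plus = 1e5, C_plus = 2e5))
#' @export
f_delta <- function(state) {
  validate_state(state)
  plus <- state[["S_plus"]] + state[["R_plus"]] + state[["C_plus"]]
  minus <- state[["S_minus"]] + state[["R_minus"]]
  if (plus <= 0)
    stop("f_delta undefined: CRISPR+ subpopulation is empty", call. = FALSE)
  if (minus <= 0)
    stop("f_delta undefined: CRISPR- subpopulation is empty", call. = FALSE)
  (state[["R_plus"]] + state[["C_plus"]]) / plus - state[["R_minus"]] / minus
}

# f_delta that returns NA instead of erroring; used for trajectory series.
f_delta_or_na <- function(Sm, Rm, Sp, Rp, Cp) {
  plus <- Sp + Rp + Cp
  minus <- Sm + Rm
  out <- rep(NA_real_, length(Sm))
  ok <- plus > 0 & minus > 0
  out[ok] <- (Rp[ok] + Cp[ok]) / plus[ok] - Rm[ok] / minus[ok]
  out
}

#' Frequency of CRISPR-positive cells
#'
#' `(S_plus + R_plus + C_plus) / N`, with `N` the total bacterial density.
#'
#' @inheritParams derivatives
#' @return A number in \[0, 1\].
#' @export
crispr_frequency <- function(state) {
  validate_state(state)
  N <- sum(state[c("S_minus", "R_minus", "S_plus", "R_plus", "C_plus")])
  if (N <= 0)
    stop("crispr_frequency undefined: total bacterial density is zero",
         call. = FALSE)
  unname((state[["S_plus"]] + state[["R_plus"]] + state[["C_plus"]]) / N)
}

#' Derived summary statistics of a population state
#'
#' @inheritParams derivatives
#' @param params A [model_params()], used for the selection coefficient
#'   `alpha * V * f_delta`; if `NULL` the coefficient is omitted.
#' @return A list with `N_total`, `N_plus_freq`, `f_delta` (`NA` when
#'   undefined), `resistance_freq` (overall protected fraction
#'   `(R_minus + R_plus + C_plus)/N`) and, when `params` is given,
#'   `sel_coeff` (1/h).
#' @export
derived_stats <- function(state, params = NULL) {
  validate_state(state)
  N <- sum(state[c("S_minus", "R_minus", "S_plus", "R_plus", "C_plus")])
  fd <- f_delta_or_na(state[["S_minus"]], state[["R_minus"]],
                      state[["S_plus"]], state[["R_plus"]], state[["C_plus"]])
  out <- list(
    N_total = N,
    N_plus_freq = if (N > 0)
      (state[["S_plus"]] + state[["R_plus"]] + state[["C_plus"]]) / N
    else NA_real_,
    f_delta = fd,
    resistance_freq = if (N > 0)
      (state[["R_minus"]] + state[["R_plus"]] + state[["C_plus"]]) / N
    else NA_real_)
  if (!is.null(params)) {
    validate_params(params)
    out$sel_coeff <- params$alpha * state[["V"]] * fd
  }
  out
}

#' Reduced frequency dynamics of the CRISPR-positive subpopulation
#'
#' The collapsed one-dimensional dynamics obtained from the full system when
#' costs, mutation and spacer acquisition are negligible:
#' \deqn{\frac{dN^+}{dt} = \alpha V f_\Delta N^+ (1 - N^+)}
#' A logistic change in frequency with per-hour selection coefficient
#' `alpha * V * f_delta`: its sign -- and hence whether CRISPR-positive cells
#' spread or decline -- is set by the sign of `f_delta`, not by the current
#' frequency `N_plus`.
#'
#' @param N_plus CRISPR-positive frequency, in \[0, 1\].
#' @param f_delta Protection-difference statistic (see [f_delta()]).
#' @param V Free phage density (pfu/ml).
#' @param alpha Adsorption rate constant (ml/h).
#' @return `dN_plus/dt` in 1/h.
#' @examples
#' reduced_rhs(0.5, 0.15, 1e4, 1e-9)
#' @export
reduced_rhs <- function(N_plus, f_delta, V, alpha) {
  if (any(N_plus < 0 | N_plus > 1))
    stop("N_plus must be in [0, 1]", call. = FALSE)
  alpha * V * f_delta * N_plus * (1 - N_plus)
}

#' Selection coefficient for CRISPR-positive cells
#'
#' `alpha * V * f_delta(state)`, the per-hour rate constant of the reduced
#' frequency dynamics ([reduced_rhs()]). Positive when the CRISPR-positive
#' subpopulation carries the larger protected fraction and phage are present.
#'
#' @inheritParams derivatives
#' @return Selection coefficient (1/h).
#' @export
selection_coefficient <- function(state, params) {
  validate_params(params)
  params$alpha * state[["V"]] * f_delta(state)
}
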