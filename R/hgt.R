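#' Horizontal gene transfer settings
#'
#' Mass-action transfer of the CRISPR locus from CRISPR-positive donors to
#' CRISPR-negative recipients, the standard conjugation kinetics
#' `gamma * donor * recipient`. Recipients keep their surface phenotype:
#' `S_minus` becomes `S_plus` (or spacer-immune `C_plus`, see below) and
#' `R_minus` becomes `R_plus`; the double-protected genotype (surface
#' resistance plus spacers) is outside the five-genotype state space and is
#' never created. Transfer relabels cells, so total bacterial density is
#' conserved exactly.
#'
#' A transfer to a sensitive recipient delivers a phage-targeting spacer
#' along with the locus with probability
#' `spacer_transfer_fraction * C_plus / (S_plus + R_plus + C_plus)`,
#' i.e. proportional to the immune share of the donor pool; otherwise the
#' recipient becomes `S_plus`.
#'
#' @param gamma Transfer rate constant (ml/h), >= 0.
#' @param spacer_transfer_fraction Probability that a transfer from an
#'   immune donor makes the recipient immune, in \[0, 1\].
#' @return An object of class `"hgt_settings"`.
#' @export
hgt_settings <- function(gamma = 0, spacer_transfer_fraction = 0) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0)
    stop("gamma must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(spacer_transfer_fraction) ||
      length(spacer_transfer_fraction) != 1L ||
      !is.finite(spacer_transfer_fraction) ||
      spacer_transfer_fraction < 0 || spacer_transfer_fraction > 1)
    stop("spacer_transfer_fraction must be in [0, 1]", call. = FALSE)
  structure(list(gamma = gamma,
                 spacer_transfer_fraction = spacer_transfer_fraction),
            class = "hgt_settings")
}

# HGT-only flux on the raw state vector (S-, R-, S+, R+, C+, V).
# Conserves the bacterial total by construction; no effect on V.
hgt_flux_raw <- function(y, gamma, q) {
  if (gamma == 0) return(numeric(6L))
  Sm <- y[1L]; Rm <- y[2L]; Sp <- y[3L]; Rp <- y[4L]; Cp <- y[5L]
  D <- Sp + Rp + Cp
  if (D <= 0) return(numeric(6L))
  to_immune <- q * Cp / D              # share of S- conversions landing in C+
  fS <- gamma * D * Sm                 # S- recipients converted per hour
  fR <- gamma * D * Rm                 # R- recipients converted per hour
  c(-fS, -fR, fS * (1 - to_immune), fR, fS * to_immune, 0)
}

#' Right-hand sides of the system extended with horizontal transfer
#'
#' The base dynamics ([derivatives()]) plus the mass-action transfer terms of
#' [hgt_settings()]. With `gamma = 0` this reduces exactly to the base model.
#'
#' @inheritParams derivatives
#' @param hgt An [hgt_settings()].
#' @return Named numeric vector of length 6 (per hour).
#' @export
hgt_derivatives <- function(state, params, hgt) {
  stopifnot(inherits(hgt, "hgt_settings"))
  d <- derivatives(state, params)
  d + hgt_flux_raw(as.numeric(state[state_names]), hgt$gamma,
                   hgt$spacer_transfer_fraction)
}

#' Contribution of horizontal transfer to the rate of change of f_delta
#'
#' Chain-rule derivative of the protection-difference statistic along the
#' HGT-only flux. Because transfer removes `S_minus` and `R_minus` at the
#' same per-capita rate, the CRISPR-negative resistance fraction is invariant
#' and the whole effect acts through the CRISPR-positive side. With no spacer
#' co-transfer the flux reduces to
#' `-gamma * D * (S_minus + R_minus) * f_delta / (S_plus + R_plus + C_plus)`
#' (with `D` the donor density): early in an epidemic, when resistance is
#' rare and concentrated in the incoming CRISPR-positive cells
#' (`f_delta > 0`), transfer mostly converts `S_minus` to `S_plus`, diluting
#' the protected fraction of the CRISPR-positive pool and driving `f_delta`
#' down. With abundant immune donors and a high spacer-transfer probability
#' the contribution can turn positive.
#'
#' @inheritParams hgt_derivatives
#' @return `d f_delta / dt` due to HGT alone (1/h).
#' @export
fdelta_hgt_flux <- function(state, params, hgt) {
  stopifnot(inherits(hgt, "hgt_settings"))
  f_delta(state)  # errors if undefined
  validate_params(params)
  y <- as.numeric(state[state_names])
  d <- hgt_flux_raw(y, hgt$gamma, hgt$spacer_transfer_fraction)
  Sm <- y[1L]; Rm <- y[2L]; Sp <- y[3L]; Rp <- y[4L]; Cp <- y[5L]
  Bp <- Sp + Rp + Cp
  Bm <- Sm + Rm
  dprot <- d[4L] + d[5L]               # d(R+ + C+)
  dBp <- d[3L] + d[4L] + d[5L]
  term_plus <- (dprot * Bp - (Rp + Cp) * dBp) / Bp^2
  term_minus <- (d[2L] * Bm - Rm * (d[1L] + d[2L])) / Bm^2
  unname(term_plus - term_minus)
}
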