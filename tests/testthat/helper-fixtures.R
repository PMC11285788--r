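# Shared fixtures: all synthetic, generated in code.

# Reference parameter set (the package defaults): r = 0.5, K = 1e9,
# alpha = 1e-9, B = 100, c_R = 0.05, c_I = 0, mu = A = 0, m_b = m_v = 0.
ref_params <- function(...) model_params(...)

zero_cost_params <- function(...) model_params(c_R = 0, c_I = 0, ...)

# Reference scenario mix: 50% CRISPR+; 30% of the CRISPR+ subpopulation
# protected (split equally between surface-resistant and spacer-immune),
# 15% of the CRISPR- subpopulation resistant => f_delta(0) = +0.15.
# mirror = TRUE swaps the protected fractions => f_delta(0) = -0.15.
scenario_freqs <- function(n_plus0 = 0.5, rho_plus = 0.3, rho_minus = 0.15,
                           immune_share = 0.5, mirror = FALSE) {
  if (mirror) { tmp <- rho_plus; rho_plus <- rho_minus; rho_minus <- tmp }
  c(S_minus = (1 - n_plus0) * (1 - rho_minus),
    R_minus = (1 - n_plus0) * rho_minus,
    S_plus = n_plus0 * (1 - rho_plus),
    R_plus = n_plus0 * rho_plus * (1 - immune_share),
    C_plus = n_plus0 * rho_plus * immune_share)
}

scenario_state <- function(N0 = 1e6, V0 = 1e4, ...) {
  state_from_frequencies(scenario_freqs(...), N0, V0)
}

# Random valid state with every compartment present.
random_state <- function(V_max = 1e6) {
  pop_state(S_minus = 10^runif(1, 3, 8), R_minus = 10^runif(1, 3, 8),
            S_plus = 10^runif(1, 3, 8), R_plus = 10^runif(1, 3, 8),
            C_plus = 10^runif(1, 3, 8), V = runif(1, 0, V_max))
}

# Random five-genotype frequency mix (Dirichlet-uniform over the simplex).
random_mix_freqs <- function() {
  g <- rgamma(5, shape = 1)
  f <- g / sum(g)
  names(f) <- c("S_minus", "R_minus", "S_plus", "R_plus", "C_plus")
  f
}

# Epidemic-onset state for the HGT sign analysis: total protection rare
# (< 1e-3 of cells) and concentrated in the CRISPR+ invaders, so the
# CRISPR+ protected fraction exceeds the CRISPR- resistant fraction
# (f_delta > 0), the regime in which transfer dilutes CRISPR+ protection.
rare_resistance_state <- function() {
  B_plus <- 10^runif(1, 5, 7)
  B_minus <- 10^runif(1, 5, 7)
  rho_plus <- runif(1, 1e-6, 1e-3)
  rho_minus <- runif(1, 0, 0.9) * rho_plus
  imm <- runif(1)
  pop_state(S_minus = B_minus * (1 - rho_minus),
            R_minus = B_minus * rho_minus,
            S_plus = B_plus * (1 - rho_plus),
            R_plus = B_plus * rho_plus * (1 - imm),
            C_plus = B_plus * rho_plus * imm,
            V = 10^runif(1, 2, 5))
}

final_state_vec <- function(traj) {
  as.numeric(traj[nrow(traj),
                  c("S_minus", "R_minus", "S_plus", "R_plus", "C_plus", "V")])
}
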