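# Derive a reproducible 31-bit sub-seed from a global seed and a stream
# index, so every stage / replicate draws from its own named stream.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483629
}

# One draw from a Dirichlet(alpha) distribution via independent gammas.
# Components with alpha = 0 stay exactly 0 (a genotype absent from the mix
# is never observed), matching compositional qPCR quantification.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) stop("degenerate Dirichlet draw: all concentrations zero",
                   call. = FALSE)
  g / s
}

# Logistic-normal jitter of a composition: multiplicative log-normal
# perturbation of the positive components followed by renormalization.
# Zero components stay zero.
jitter_composition <- function(p, sd) {
  if (sd <= 0) return(p)
  pos <- p > 0
  z <- log(p[pos]) + stats::rnorm(sum(pos), mean = 0, sd = sd)
  z <- exp(z - max(z))
  p[pos] <- z / sum(z)
  p
}
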