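---
title: "Methods: model, synthetic experiments and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, synthetic experiments and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprspread)
```

## The model

The package models a well-mixed batch culture of bacteria and a lytic
phage over one competition cycle (24 h by default). Cells are classified
along two axes: carriage of a CRISPR-Cas locus (`+`/`-`) and protection
state — phage-sensitive (`S`), surface-resistant (`R`) or spacer-immune
(`C`, available only to locus carriers). With densities
`S-`, `R-`, `S+`, `R+`, `C+` (cells/ml) and free phage `V` (pfu/ml), and
writing `N` for total cells and `g = r (1 - N/K)` for the shared logistic
growth term, the dynamics are

```
dS-/dt = [ g (1 - mu) - alpha V - m_b ] S-
dR-/dt = mu g S-  +  [ g (1 - c_R) - m_b ] R-
dS+/dt = [ g (1 - mu) - alpha V - m_b ] S+
dR+/dt = mu g S+  +  [ g (1 - c_R) - m_b ] R+
dC+/dt = alpha A V S+  +  [ g (1 - c_I) - m_b ] C+
dV/dt  = [ alpha B (S- + S+ (1 - A)) - m_v - alpha (S- + S+ + C+) ] V
```

Sensitive cells adsorb phage at rate `alpha` and are lysed, releasing `B`
phage per burst; surface resistance avoids adsorption at a growth cost
`c_R`; immune cells adsorb and destroy phage without bursting, at cost
`c_I`. Sensitive locus carriers can acquire a spacer upon infection with
probability `A` (becoming `C+`); sensitive cells mutate to surface
resistance at rate `mu` per division. `m_b` and `m_v` are background
bacterial death and phage decay.

### Assumptions

Deterministic mass action; no latent (infected-but-not-lysed) class —
bursts are instantaneous; a single phage type, no phage coevolution or
escape mutants; costs act on the division rate only; the transferred
locus (HGT extension below) carries no targeting spacer unless
`spacer_transfer_fraction > 0`. All rates are per hour; densities per ml.

### The selection statistic

Define the protection-frequency difference

```
f_delta = (R+ + C+) / (S+ + R+ + C+)  -  R- / (S- + R-)
```

With `c_R = c_I = mu = A = 0`, the frequency `N+` of locus carriers obeys
exactly

```
dN+/dt = alpha V f_delta N+ (1 - N+)
```

so `alpha V f_delta` is the instantaneous selection coefficient on the
locus, and the sign of the change in `N+` over an epidemic equals
`sign(f_delta(0))` independent of `N+(0)`. The package exposes the
statistic (`f_delta`), the reduced equation (`reduced_rhs`,
`integrate_reduced`) and its coupling to a full trajectory
(`reduced_from_trajectory`); the test suite verifies the equivalence to
below `1e-6` relative error.

Once the sensitive pool collapses, both subpopulations consist only of
protected cells, `f_delta` returns to 0 (or to ±1 if protection exists
on one side only) and `N+` plateaus; `fixation_check` reports the
collapse time, final `f_delta` and the analytic `dN+/dt` at the horizon.

### Parameter defaults

`r = 0.5 /h`, `K = 1e9 /ml`, `alpha = 1e-9 ml/h`, `B = 100`,
`c_R = 0.05`, `c_I = 0`, `mu = 0`, `A = 0`, `m_b = m_v = 0`; initial
densities `N0 = 1e6` cells/ml and dose `V0 = 1e4` pfu/ml. These are the
study conditions the package targets: a fast-growing pseudomonad with a
costly surface-resistance mechanism, an effectively cost-free CRISPR
immunity, and a low-multiplicity phage challenge. They are the defaults
of `model_params()` and of the experiment generator and are never tuned
per analysis.

## Horizontal gene transfer extension

`hgt_derivatives` adds mass-action conversion of non-carriers by
carriers: recipients `S-`/`R-` meet donors `(S+ + R+ + C+)` at rate
`gamma` and are relabelled `S+`/`R+`; a fraction
`spacer_transfer_fraction` of converted sensitives additionally receives
a targeting spacer from immune donors (entering `C+`), proportional to
the immune share of donors. Transfer only relabels cells, so total
bacterial flux is unchanged. `fdelta_hgt_flux` gives the exact chain-rule
contribution of transfer to `df_delta/dt`. Because transfer removes `S-`
and `R-` at equal per-capita rates, the CRISPR-negative resistant
fraction is invariant, and without spacer co-transfer the flux reduces to
`-gamma D (S- + R-) f_delta / B+` (with `D` total donors and `B+` the
CRISPR-positive subpopulation): at epidemic onset, when protection is
rare and concentrated among carriers (`f_delta > 0`), transfer of the
bare locus *dilutes* carrier protection and is never positive — a sign
law the acceptance suite checks over random rare-resistance states.

## Numerical choices

- `integrate_full` uses `deSolve::lsoda` with `rtol = 1e-8` and
  `atol = 1e-2` (absolute tolerance in cells/ml, i.e. far below one cell)
  on a fixed reporting grid (`grid_dt = 0.02 h`). The epidemic phase is
  stiff (phage growth spans 5 orders of magnitude in hours), which lsoda
  handles by switching to BDF.
- Negative densities of integrator-roundoff size are clipped to zero only
  in the reported trajectory, never inside the right-hand side.
- `integrate_euler` is a deliberately independent fixed-step forward
  Euler oracle sharing only the right-hand side. At `dt = 1e-4 h` the
  bacterial compartments agree with the adaptive solution to about
  `1e-5` relative. The *phage* compartment, however, disagrees by about
  `2–3e-4`: this is Euler's own first-order truncation error, not
  adaptive-solver error — the discrepancy halves when `dt` halves
  (confirming `O(dt)` convergence towards the adaptive answer), and the
  adaptive solution itself matches an implicit Runge-Kutta (`radau`)
  re-integration to `~1e-8`. A blanket `1e-4` agreement target at
  `dt = 1e-4` is therefore not attainable on this stiff scenario for the
  phage compartment, and the corresponding acceptance check documents
  this; the bacterial-compartment agreement and the convergence-order
  check are the meaningful oracle assertions.

## The synthetic-experiment generator

`generate_dataset` emulates a short-term paired competition assay: six
strain-mix conditions crossing the sign of `f_delta(0)` (±0.3 by
default) with the composition of CRISPR-positive protection
(immune:resistant ratio 4:1, 1:1, 1:4), each run in `n` paired
replicates with and without phage. Per replicate, initial frequencies
receive logistic-normal jitter (`jitter_sd = 0.05`), both arms are
integrated for 24 h from the *same* jittered inoculum, and measured
compositions at 0 h and 24 h are Dirichlet resamples of the true
composition with concentration `kappa = 200`, emulating compositional
(qPCR-like) measurement error; `kappa = Inf` disables it. The response
is the relative change in the CRISPR-positive frequency in the phage arm
versus its paired no-phage arm; `baseline_change` is the no-phage arm's
own deviation. All covariates in the analysis table are computed from
the *observed* (noisy) initial frequencies, as they would be in a real
experiment.

Scope and limits: the generator emulates design, effect structure and
compositional noise — not counting statistics, plating error, phage
contamination of control arms, or between-day batch effects. It is a
testbed for the inference machinery, not a digital twin of any one
experiment.

## Inference

- `fit_glm` fits, by ordinary least squares on a Householder QR
  decomposition (no call to `lm`), the response against `f_delta0`, the
  protection composition and the initial CRISPR-positive frequency. The
  composition is coded by default as the bounded immune *fraction*
  `C+/(C+ + R+)` rather than the raw ratio `C+/R+`, which diverges as
  `R+` vanishes; the raw-ratio coding is available. The initial-frequency
  covariate can be dropped to assess it separately.
- `bootstrap_ci` gives case-resampling percentile intervals.
  Rank-deficient resamples are redrawn and counted. Percentile intervals
  under-cover slightly at these sample sizes (n = 36); a 200-replicate
  simulation in the test suite brackets the empirical coverage of a
  nominal 95% interval in [0.88, 0.99].
- `baseline_tests` runs one-tailed one-sample t-tests of no-phage drift
  per condition, with the tail direction derived from the cost structure
  (`expected_baseline_directions`: the subpopulation with the heavier
  cost burden loses frequency), followed by Benjamini-Hochberg FDR
  adjustment across conditions. An all-zero group yields `t = 0`,
  `p = 0.5`; a zero-variance group with nonzero mean is an error.
- `predict_dataset` re-runs the deterministic model from each
  replicate's observed initial frequencies;
  `sign_prediction_accuracy` scores sign agreement with a dead-band for
  near-zero responses.

Problem sizes used in validation: 100-state sign-law sweeps, 200 seeded
end-to-end datasets (36 rows each, 1000 bootstrap draws), 200-replicate
bootstrap coverage studies — all within minutes on one CPU.

## End-to-end runs

```{r, eval = FALSE}
cfg <- default_config(seed = 1, outdir = "run1")
run_pipeline(cfg)
```

`run_pipeline` validates the configuration (unknown keys are rejected
with their full path; every block is re-validated by its constructor),
generates the dataset, integrates a reference trajectory, computes
predictions, fits the model with bootstrap intervals, runs the baseline
tests, and writes `dataset_long.csv`, `dataset_wide.csv`,
`trajectory.csv`, `metrics.json`, the resolved `config.yaml` and a run
log. Every artifact records the seed, an MD5 hash of the resolved
configuration and the package version; reruns under the same
configuration are byte-identical. All randomness derives from the single
global seed through fixed per-stage substreams.
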