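#' Design of the six-condition short-term competition experiment
#'
#' The experimental design crosses the sign of the initial
#' protection-difference statistic `f_delta` (positive / negative) with the
#' composition of protection inside the CRISPR-positive subpopulation: the
#' spacer-immune cells outnumber (`CgtR`), equal (`CeqR`) or are outnumbered
#' by (`CltR`) the surface-resistant cells. The exact strain frequencies used
#' in the laboratory mixes are not published numerically, so the defaults
#' here are chosen to produce `|f_delta| = 0.3` at a 50% initial
#' CRISPR-positive frequency; every knob is configurable and all downstream
#' checks are property-based rather than curve-matching.
#'
#' @param n_plus0 Initial CRISPR-positive frequency of each mix, in (0, 1).
#' @param res_frac_high,res_frac_low Protected fractions assigned to the
#'   subpopulation on the high and low side of the `f_delta` contrast, in
#'   (0, 1) with `res_frac_high > res_frac_low`. For `f_delta`-positive
#'   conditions the CRISPR-positive side gets `res_frac_high`; for negative
#'   conditions the CRISPR-negative side does.
#' @param immune_resistant_ratios Named numeric vector of `C_plus : R_plus`
#'   ratios for the three composition levels; defaults
#'   `c(CgtR = 4, CeqR = 1, CltR = 0.25)`.
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(n_plus0 = 0.5, res_frac_high = 0.4,
                              res_frac_low = 0.1,
                              immune_resistant_ratios = c(CgtR = 4, CeqR = 1,
                                                          CltR = 0.25)) {
  if (n_plus0 <= 0 || n_plus0 >= 1)
    stop("n_plus0 must be in (0, 1)", call. = FALSE)
  if (res_frac_high <= 0 || res_frac_high >= 1 ||
      res_frac_low <= 0 || res_frac_low >= 1)
    stop("protected fractions must be in (0, 1)", call. = FALSE)
  if (res_frac_high <= res_frac_low)
    stop("res_frac_high must exceed res_frac_low (infeasible f_delta ",
         "contrast otherwise)", call. = FALSE)
  if (length(immune_resistant_ratios) != 3L ||
      is.null(names(immune_resistant_ratios)) ||
      !identical(sort(names(immune_resistant_ratios)),
                 sort(c("CgtR", "CeqR", "CltR"))))
    stop("immune_resistant_ratios must be named CgtR, CeqR, CltR",
         call. = FALSE)
  if (any(immune_resistant_ratios <= 0))
    stop("immune:resistant ratios must be > 0", call. = FALSE)
  if (immune_resistant_ratios[["CgtR"]] <= 1)
    stop("CgtR ratio must be > 1", call. = FALSE)
  if (immune_resistant_ratios[["CltR"]] >= 1)
    stop("CltR ratio must be < 1", call. = FALSE)
  structure(list(n_plus0 = n_plus0, res_frac_high = res_frac_high,
                 res_frac_low = res_frac_low,
                 immune_resistant_ratios =
                   immune_resistant_ratios[c("CgtR", "CeqR", "CltR")]),
            class = "experiment_design")
}

condition_labels <- c("fpos_CgtR", "fpos_CeqR", "fpos_CltR",
                      "fneg_CgtR", "fneg_CeqR", "fneg_CltR")

#' Build the six initial strain mixes of the competition design
#'
#' @param design An [experiment_design()].
#' @return A named list of six `"strain_mix"` objects (one per condition
#'   label `fpos_CgtR, fpos_CeqR, fpos_CltR, fneg_CgtR, fneg_CeqR,
#'   fneg_CltR`), each holding the five genotype frequencies, the recomputed
#'   initial `f_delta` and the immune:resistant ratio within the
#'   CRISPR-positive subpopulation.
#' @examples
#' mixes <- build_initial_mixes(experiment_design())
#' sapply(mixes, function(m) m$f_delta0)
#' @export
build_initial_mixes <- function(design = experiment_design()) {
  stopifnot(inherits(design, "experiment_design"))
  out <- list()
  for (sgn in c("fpos", "fneg")) {
    rho_plus <- if (sgn == "fpos") design$res_frac_high else design$res_frac_low
    rho_minus <- if (sgn == "fpos") design$res_frac_low else design$res_frac_high
    for (lev in c("CgtR", "CeqR", "CltR")) {
      k <- design$immune_resistant_ratios[[lev]]
      np <- design$n_plus0
      freqs <- c(S_minus = (1 - np) * (1 - rho_minus),
                 R_minus = (1 - np) * rho_minus,
                 S_plus = np * (1 - rho_plus),
                 R_plus = np * rho_plus / (1 + k),
                 C_plus = np * rho_plus * k / (1 + k))
      label <- paste(sgn, lev, sep = "_")
      fd <- f_delta(state_from_frequencies(freqs, N0 = 1))
      if ((sgn == "fpos") != (fd > 0))
        stop("infeasible design: condition ", label,
             " does not realise the requested f_delta sign", call. = FALSE)
      out[[label]] <- structure(
        list(condition_label = label, frequencies = freqs, f_delta0 = fd,
             immune_resistant_ratio = unname(freqs["C_plus"] /
                                               freqs["R_plus"])),
        class = "strain_mix")
    }
  }
  out[condition_labels]
}

#' @export
print.strain_mix <- function(x, ...) {
  cat("Strain mix '", x$condition_label, "': f_delta0 = ",
      format(signif(x$f_delta0, 4)), ", C+:R+ = ",
      format(signif(x$immune_resistant_ratio, 4)), "\n", sep = "")
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Measurement and replicate noise for synthetic competition data
#'
#' Two noise layers emulate the laboratory workflow: a logistic-normal
#' jitter of each replicate's inoculum mix (pipetting variation when the
#' strains are combined), and Dirichlet resampling of every measured
#' frequency vector around the true composition with concentration `kappa`
#' (compositional qPCR quantification error; larger `kappa` means less
#' noise).
#'
#' @param kappa Dirichlet concentration of the measurement noise; `Inf`
#'   disables it. Default 200, giving a standard deviation of roughly 0.035
#'   on a frequency of 0.5.
#' @param jitter_sd Standard deviation of the log-scale replicate jitter;
#'   0 disables it. Default 0.05.
#' @return An object of class `"noise_settings"`.
#' @export
noise_settings <- function(kappa = 200, jitter_sd = 0.05) {
  if (!(is.numeric(kappa) && length(kappa) == 1L && kappa > 0))
    stop("kappa must be a single number > 0 (Inf disables noise)",
         call. = FALSE)
  if (!(is.numeric(jitter_sd) && length(jitter_sd) == 1L &&
        is.finite(jitter_sd) && jitter_sd >= 0))
    stop("jitter_sd must be a single finite number >= 0", call. = FALSE)
  structure(list(kappa = kappa, jitter_sd = jitter_sd),
            class = "noise_settings")
}

observe_composition <- function(p, kappa) {
  if (!is.finite(kappa)) return(p)
  out <- rdirichlet1(kappa * p)
  names(out) <- names(p)
  out
}

#' Simulate one replicate of the paired (phage / no-phage) competition
#'
#' Jitters the inoculum mix once (both arms are inoculated from the same
#' culture), integrates the full model for `settings$t_end` hours from
#' `N0 * frequencies` with `V(0) = V0` in the phage arm and `V(0) = 0` in
#' the control arm, then applies Dirichlet measurement noise to the observed
#' frequency vectors at 0 and 24 h. The initial mix is measured once per
#' replicate, so both arms share the same observed `t = 0` composition.
#'
#' @param mix A `"strain_mix"` from [build_initial_mixes()].
#' @param params A [model_params()].
#' @param N0 Inoculum density (cells/ml); default `1e6`.
#' @param V0 Phage dose (pfu/ml); default `1e4`.
#' @param noise A [noise_settings()].
#' @param seed Integer seed; the simulation is bit-reproducible under it.
#' @param settings An [integration_settings()].
#' @param replicate Replicate index recorded in the output.
#' @return A list of two `"competition_record"` objects, `phage` and
#'   `no_phage`, each with the condition label, replicate index,
#'   `phage_added`, observed `freqs_t0` / `freqs_t24`, `total_cells_t24` and
#'   `phage_titre_t24`.
#' @export
simulate_competition <- function(mix, params = model_params(), N0 = 1e6,
                                 V0 = 1e4, noise = noise_settings(),
                                 seed = 1, settings = integration_settings(),
                                 replicate = 1L) {
  stopifnot(inherits(mix, "strain_mix"), inherits(noise, "noise_settings"))
  set.seed(seed)
  true_t0 <- jitter_composition(mix$frequencies, noise$jitter_sd)
  obs_t0 <- observe_composition(true_t0, noise$kappa)
  run_arm <- function(V, phage_added) {
    # only the endpoint is observed; skip the dense output grid
    traj <- integrate_full(state_from_frequencies(true_t0, N0, V), params,
                           settings, times = c(0, settings$t_end))
    last <- nrow(traj)
    true_t24 <- as.numeric(traj[last, state_names[1:5]])
    true_t24 <- true_t24 / sum(true_t24)
    names(true_t24) <- state_names[1:5]
    structure(list(condition_label = mix$condition_label,
                   replicate = as.integer(replicate),
                   phage_added = phage_added,
                   freqs_t0 = obs_t0,
                   freqs_t24 = observe_composition(true_t24, noise$kappa),
                   total_cells_t24 = traj$N_total[last],
                   phage_titre_t24 = traj$V[last]),
              class = "competition_record")
  }
  list(phage = run_arm(V0, TRUE), no_phage = run_arm(0, FALSE))
}

#' Competition response: relative change in CRISPR-positive frequency
#'
#' `(frequency with phage - frequency without phage) / frequency without
#' phage`, computed from the observed CRISPR-positive frequencies at the end
#' of the paired arms.
#'
#' @param pair A list with elements `phage` and `no_phage` as returned by
#'   [simulate_competition()].
#' @return The response value (dimensionless).
#' @export
relative_change <- function(pair) {
  ph <- pair$phage
  np <- pair$no_phage
  stopifnot(inherits(ph, "competition_record"),
            inherits(np, "competition_record"))
  if (!identical(ph$condition_label, np$condition_label) ||
      !identical(ph$replicate, np$replicate))
    stop("records are not a matched (condition, replicate) pair",
         call. = FALSE)
  npf <- function(rec) sum(rec$freqs_t24[c("S_plus", "R_plus", "C_plus")])
  denom <- npf(np)
  if (denom <= 0)
    stop("no-phage CRISPR+ frequency is zero; relative change undefined",
         call. = FALSE)
  (npf(ph) - denom) / denom
}

crispr_freq_of <- function(freqs) sum(freqs[c("S_plus", "R_plus", "C_plus")])

#' Generate a full synthetic competition dataset
#'
#' Six conditions x `n_replicates` replicates x two arms (phage / no phage),
#' with per-replicate inoculum jitter and per-measurement compositional
#' noise. All randomness flows from `seed` through per-replicate derived
#' sub-seeds, so the output is byte-identical under the same inputs.
#'
#' @param design An [experiment_design()].
#' @param params A [model_params()].
#' @param noise A [noise_settings()].
#' @param n_replicates Replicates per condition, >= 2; default 6.
#' @param seed Global integer seed.
#' @param N0,V0 Inoculum density and phage dose.
#' @param settings An [integration_settings()].
#' @return An object of class `"competition_dataset"`: a list with
#'   * `records`: nested list of record pairs by condition and replicate;
#'   * `wide`: one row per condition x replicate with the observed initial
#'     predictors (`f_delta0`, `immune_resistant_ratio`, `immune_fraction`,
#'     `initial_crispr_freq`), the phage response (`response`) and the
#'     no-phage baseline change (`baseline_change`);
#'   * `long`: the flat per-genotype table mirrored by the CSV format;
#'   * `mixes`, `seed`: provenance.
#' @export
generate_dataset <- function(design = experiment_design(),
                             params = model_params(),
                             noise = noise_settings(), n_replicates = 6,
                             seed = 1, N0 = 1e6, V0 = 1e4,
                             settings = integration_settings()) {
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  mixes <- build_initial_mixes(design)
  records <- list()
  wide <- list()
  k <- 0L
  for (ci in seq_along(mixes)) {
    mix <- mixes[[ci]]
    for (rep_j in seq_len(n_replicates)) {
      k <- k + 1L
      pair <- simulate_competition(
        mix, params = params, N0 = N0, V0 = V0, noise = noise,
        seed = derive_seed(seed, (ci - 1L) * n_replicates + rep_j),
        settings = settings, replicate = rep_j)
      records[[mix$condition_label]][[rep_j]] <- pair
      obs0 <- pair$phage$freqs_t0
      st0 <- state_from_frequencies(obs0, N0 = 1, tol = 1e-6)
      np_np <- pair$no_phage
      np0 <- crispr_freq_of(np_np$freqs_t0)
      wide[[k]] <- data.frame(
        condition = mix$condition_label,
        replicate = rep_j,
        f_delta0 = f_delta(st0),
        immune_resistant_ratio = unname(obs0["C_plus"] / obs0["R_plus"]),
        immune_fraction = unname(obs0["C_plus"] /
                                   (obs0["C_plus"] + obs0["R_plus"])),
        initial_crispr_freq = crispr_freq_of(obs0),
        response = relative_change(pair),
        baseline_change = (crispr_freq_of(np_np$freqs_t24) - np0) / np0,
        stringsAsFactors = FALSE)
    }
  }
  wide <- do.call(rbind, wide)
  structure(list(records = records, wide = wide,
                 long = records_to_long(records), mixes = mixes,
                 seed = seed),
            class = "competition_dataset")
}

records_to_long <- function(records) {
  rows <- list()
  k <- 0L
  for (cond in names(records)) {
    for (pair in records[[cond]]) {
      for (rec in pair) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          condition = rec$condition_label,
          replicate = rec$replicate,
          phage_added = rec$phage_added,
          genotype = state_names[1:5],
          freq_t0 = as.numeric(rec$freqs_t0),
          freq_t24 = as.numeric(rec$freqs_t24),
          total_cells_t24 = rec$total_cells_t24,
          phage_titre_t24 = rec$phage_titre_t24,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.competition_dataset <- function(x, ...) {
  cat("Synthetic competition dataset:",
      length(unique(x$wide$condition)), "conditions x",
      max(x$wide$replicate), "replicates x 2 arms (seed", x$seed, ")\n")
  agg <- stats::aggregate(response ~ condition, data = x$wide, FUN = mean)
  print(agg)
  invisible(x)
}

#' Write / read a competition dataset as CSV
#'
#' The long file has one row per condition x replicate x arm x genotype with
#' columns `condition,replicate,phage_added,genotype,freq_t0,freq_t24,`
#' `total_cells_t24,phage_titre_t24`. The optional wide companion carries one
#' row per condition x replicate with the derived predictors and responses.
#' `read_dataset_csv()` also accepts externally produced tables of the same
#' long shape (e.g. real qPCR quantification data) and rebuilds the wide
#' table from them.
#'
#' @param dataset A `"competition_dataset"`.
#' @param path Long-format CSV path.
#' @param wide_path Optional wide companion CSV path.
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` returns a list with `long` and `wide` data frames.
#' @export
write_dataset_csv <- function(dataset, path, wide_path = NULL) {
  stopifnot(inherits(dataset, "competition_dataset"))
  utils::write.csv(dataset$long, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(wide_path))
    utils::write.csv(dataset$wide, wide_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, wide_path = NULL) {
  long <- utils::read.csv(path, fileEncoding = "UTF-8")
  needed <- c("condition", "replicate", "phage_added", "genotype", "freq_t0",
              "freq_t24", "total_cells_t24", "phage_titre_t24")
  missing <- setdiff(needed, names(long))
  if (length(missing))
    stop("dataset CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  wide <- if (!is.null(wide_path)) utils::read.csv(wide_path,
                                                   fileEncoding = "UTF-8")
          else wide_from_long(long)
  list(long = long, wide = wide)
}

# Rebuild the wide predictor/response table from a long-format table.
wide_from_long <- function(long) {
  key <- unique(long[, c("condition", "replicate")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- long[long$condition == key$condition[i] &
                  long$replicate == key$replicate[i], ]
    get_arm <- function(phage) {
      arm <- sub[sub$phage_added == phage, ]
      arm <- arm[match(state_names[1:5], arm$genotype), ]
      arm
    }
    ph <- get_arm(TRUE)
    np <- get_arm(FALSE)
    if (nrow(ph) != 5L || nrow(np) != 5L || anyNA(ph$genotype) ||
        anyNA(np$genotype))
      stop("incomplete genotype rows for condition ", key$condition[i],
           " replicate ", key$replicate[i], call. = FALSE)
    f0 <- ph$freq_t0
    names(f0) <- state_names[1:5]
    npf <- function(v) sum(v[3:5])
    np0 <- npf(np$freq_t0)
    data.frame(
      condition = key$condition[i], replicate = key$replicate[i],
      f_delta0 = f_delta(state_from_frequencies(f0, N0 = 1, tol = 1e-3)),
      immune_resistant_ratio = f0[["C_plus"]] / f0[["R_plus"]],
      immune_fraction = f0[["C_plus"]] / (f0[["C_plus"]] + f0[["R_plus"]]),
      initial_crispr_freq = npf(f0),
      response = (npf(ph$freq_t24) - npf(np$freq_t24)) / npf(np$freq_t24),
      baseline_change = (npf(np$freq_t24) - np0) / np0,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
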