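#' Default end-to-end run configuration
#'
#' A nested list with one block per pipeline stage: `model` (see
#' [model_params()]), `integration` ([integration_settings()]), optional
#' `hgt` ([hgt_settings()]), `experiment` (design, noise, replicate count,
#' inoculum density and phage dose) and `inference` (bootstrap draws and
#' confidence level), plus the global `seed` and `outdir`. All randomness in
#' a run flows from the single seed through named per-stage substreams.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory for [run_pipeline()] artifacts.
#' @return A list of class `"run_config"`.
#' @export
default_config <- function(seed = 1, outdir = "crisprspread-run") {
  structure(list(
    seed = seed,
    outdir = outdir,
    model = as_plain_list(model_params()),
    integration = as_plain_list(integration_settings()),
    hgt = NULL,
    experiment = list(
      design = as_plain_list(experiment_design()),
      noise = as_plain_list(noise_settings()),
      n_replicates = 6,
      N0 = 1e6,
      V0 = 1e4),
    inference = list(n_boot = 10000, level = 0.95)),
    class = "run_config")
}

as_plain_list <- function(x) {
  out <- lapply(unclass(x), function(v) if (is.numeric(v)) unname(v) else v)
  # named numeric sub-vectors survive as lists in YAML; keep names
  if (!is.null(x$immune_resistant_ratios))
    out$immune_resistant_ratios <- as.list(x$immune_resistant_ratios)
  out
}

# Recursively check cfg against the default template: unknown keys are
# rejected with their full path, absent keys inherit defaults. NULL template
# entries (hgt) accept any sub-keys of hgt_settings.
merge_config <- function(template, cfg, path = "") {
  if (!is.list(cfg))
    stop("config block '", path, "' must be a mapping", call. = FALSE)
  if (is.null(names(cfg)) && length(cfg))
    stop("config block '", path, "' must have named keys", call. = FALSE)
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^/", "", paste0(path, "/", unknown)), collapse = ", "),
         call. = FALSE)
  out <- template
  for (nm in names(cfg)) {
    if (is.null(cfg[[nm]])) next     # explicit null inherits the default
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      out[[nm]] <- merge_config(template[[nm]], cfg[[nm]],
                                paste0(path, "/", nm))
    } else {
      out[[nm]] <- cfg[[nm]]
    }
  }
  out
}

#' Load and validate a run configuration file
#'
#' Reads a YAML or JSON config, rejects unknown keys (reporting the full key
#' path) and fills every unset key with its default from [default_config()].
#' Each block is then validated by its constructor, so a structurally valid
#' file with out-of-range values still fails fast.
#'
#' @param path Config file (`.yaml`, `.yml` or `.json`).
#' @return A validated `"run_config"` list.
#' @export
load_config <- function(path) {
  raw <- read_flat_config(path)
  if (is.null(raw)) raw <- list()
  template <- unclass(default_config())
  hgt_block <- NULL
  if (!is.null(raw$hgt)) {
    template$hgt <- list(gamma = 0, spacer_transfer_fraction = 0)
    hgt_block <- raw$hgt
  }
  cfg <- merge_config(template, raw)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  do.call(model_params, cfg$model)
  do.call(integration_settings, cfg$integration)
  if (!is.null(cfg$hgt)) do.call(hgt_settings, cfg$hgt)
  design <- cfg$experiment$design
  design$immune_resistant_ratios <- unlist(design$immune_resistant_ratios)
  do.call(experiment_design, design)
  do.call(noise_settings, cfg$experiment$noise)
  if (cfg$experiment$n_replicates < 2)
    stop("experiment/n_replicates must be >= 2", call. = FALSE)
  if (cfg$inference$n_boot < 1000)
    stop("inference/n_boot must be >= 1000", call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop("seed must be a single integer", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param config A `"run_config"` list.
#' @param path Output file (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  write_flat_config(unclass(config), path)
  invisible(path)
}

config_objects <- function(cfg) {
  design <- cfg$experiment$design
  design$immune_resistant_ratios <- unlist(design$immune_resistant_ratios)
  list(params = do.call(model_params, cfg$model),
       settings = do.call(integration_settings, cfg$integration),
       hgt = if (is.null(cfg$hgt)) NULL else do.call(hgt_settings, cfg$hgt),
       design = do.call(experiment_design, design),
       noise = do.call(noise_settings, cfg$experiment$noise))
}

#' Run the full synthetic-experiment / prediction / inference pipeline
#'
#' Executes, from one validated configuration: dataset generation
#' ([generate_dataset()]), per-replicate model predictions
#' ([predict_dataset()]), the linear model with bootstrap intervals
#' ([fit_glm()], [bootstrap_ci()]) and the FDR-corrected baseline tests
#' ([baseline_tests()]). Writes the dataset CSVs, a trajectory CSV of the
#' reference scenario, a fit/metrics JSON and a run log into `outdir`. Every
#' artifact records the seed, a config hash and the package version; reruns
#' with the same config are byte-identical.
#'
#' @param config A `"run_config"` (see [load_config()], [default_config()]).
#' @param outdir Output directory; defaults to `config$outdir`.
#' @return Invisibly, the metrics list (also written as JSON).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  config <- validate_config(unclass(config))
  if (is.null(outdir)) outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "run.log")
  log_line <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", sep = "")
    cat(msg, "\n", sep = "", file = logfile, append = TRUE)
  }
  cat("", file = logfile)

  cfg_path <- file.path(outdir, "config.yaml")
  save_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  version <- as.character(utils::packageVersion("crisprspread"))
  stamp <- list(seed = config$seed, config_hash = cfg_hash,
                version = version)
  obj <- config_objects(config)

  run_stage <- function(name, expr) {
    log_line("[", name, "] starting")
    res <- tryCatch(force(expr), error = function(e) {
      log_line("[", name, "] FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line("[", name, "] done")
    res
  }

  dataset <- run_stage("emulate", generate_dataset(
    design = obj$design, params = obj$params, noise = obj$noise,
    n_replicates = config$experiment$n_replicates,
    seed = derive_seed(config$seed, 1), N0 = config$experiment$N0,
    V0 = config$experiment$V0, settings = obj$settings))
  write_dataset_csv(dataset, file.path(outdir, "dataset_long.csv"),
                    file.path(outdir, "dataset_wide.csv"))

  traj <- run_stage("simulate", integrate_full(
    state_from_frequencies(dataset$mixes[[1]]$frequencies,
                           config$experiment$N0, config$experiment$V0),
    obj$params, obj$settings, hgt = obj$hgt))
  write_trajectory_csv(traj, file.path(outdir, "trajectory.csv"))

  predicted <- run_stage("predict", predict_dataset(
    dataset, params = obj$params, N0 = config$experiment$N0,
    V0 = config$experiment$V0, settings = obj$settings))
  accuracy <- sign_prediction_accuracy(dataset$wide$response, predicted)

  fit <- run_stage("fit", fit_glm(dataset$wide))
  ci <- run_stage("bootstrap", bootstrap_ci(
    fit, n_boot = config$inference$n_boot,
    seed = derive_seed(config$seed, 2), level = config$inference$level))
  baseline <- run_stage("baseline", baseline_tests(
    dataset$wide,
    directions = expected_baseline_directions(dataset$mixes, obj$params)))

  metrics <- c(stamp, list(
    sign_prediction_accuracy = accuracy,
    coefficients = as.list(fit$coefficients),
    adj_r_squared = fit$adj_r_squared,
    f_statistic = as.list(fit$fstatistic),
    f_p_value = fit$p_value,
    bootstrap_ci = list(lower = as.list(ci[, "lower"]),
                        upper = as.list(ci[, "upper"]),
                        n_boot = attr(ci, "n_boot"),
                        level = attr(ci, "level")),
    baseline_tests = baseline))
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_line("pipeline complete: seed ", config$seed, ", config ", cfg_hash)
  invisible(metrics)
}
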