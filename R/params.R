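#' Model parameters for the five-genotype bacteria-phage system
#'
#' Bundles all rate constants, costs and probabilities of the deterministic
#' model. Time is measured in hours and densities per millilitre throughout
#' the package, matching the 24 h competition-experiment window.
#'
#' Defaults are the reference scenario used for all illustrative dynamics and
#' experiment predictions: `r = 0.5`, `K = 1e9`, `alpha = 1e-9`, `B = 100`,
#' `c_R = 0.05`, `c_I = 0`, `mu = A = 0`, `m_b = m_v = 0`.
#'
#' @param r Maximum per-capita division rate (1/h). Must be > 0.
#' @param K Carrying capacity (cells/ml). Must be > 0.
#' @param m_b Per-capita bacterial death rate (1/h), >= 0.
#' @param m_v Per-capita free-phage decay rate (1/h), >= 0.
#' @param alpha Mass-action adsorption/infection rate constant (ml/h), >= 0.
#' @param B Burst size: free phage released per lysed cell, >= 0.
#' @param mu Probability of a surface-resistance mutation per division, in
#'   \[0, 1\].
#' @param A Probability of spacer acquisition per phage infection of a
#'   CRISPR-positive sensitive cell, in \[0, 1\].
#' @param c_R Fitness cost of surface resistance (reduces division rate), in
#'   \[0, 1).
#' @param c_I Fitness cost of CRISPR immunity, in \[0, 1).
#' @return An object of class `"model_params"` (a validated named list).
#' @examples
#' p <- model_params()
#' p2 <- model_params(c_R = 0, mu = 1e-7)
#' @export
model_params <- function(r = 0.5, K = 1e9, m_b = 0, m_v = 0, alpha = 1e-9,
                         B = 100, mu = 0, A = 0, c_R = 0.05, c_I = 0) {
  p <- list(r = r, K = K, m_b = m_b, m_v = m_v, alpha = alpha, B = B,
            mu = mu, A = A, c_R = c_R, c_I = c_I)
  validate_params(p)
  structure(p, class = "model_params")
}

param_names <- c("r", "K", "m_b", "m_v", "alpha", "B", "mu", "A", "c_R", "c_I")

validate_params <- function(p) {
  for (nm in param_names) {
    v <- p[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (p$r <= 0) stop("r must be > 0", call. = FALSE)
  if (p$K <= 0) stop("K must be > 0", call. = FALSE)
  for (nm in c("m_b", "m_v", "alpha", "B"))
    if (p[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  for (nm in c("mu", "A"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must be in [0, 1]", call. = FALSE)
  for (nm in c("c_R", "c_I"))
    if (p[[nm]] < 0 || p[[nm]] >= 1)
      stop(nm, " must be in [0, 1)", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Bacteria-phage model parameters (hours, per ml):\n")
  v <- unlist(x[param_names])
  print(v)
  invisible(x)
}

#' Read or write a parameter set as a flat key-value config file
#'
#' Parameter sets serialize to a flat mapping using the field names of
#' [model_params()] (`r, K, m_b, m_v, alpha, B, mu, A, c_R, c_I`). The format
#' is chosen from the file extension: `.yaml`/`.yml` or `.json`. Unknown keys
#' are rejected; missing keys take their default values.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param params A `"model_params"` object.
#' @return `read_params()` returns a `"model_params"` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- read_flat_config(path)
  unknown <- setdiff(names(vals), param_names)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(model_params, vals)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  write_flat_config(lapply(unclass(params), identity), path)
  invisible(path)
}

read_flat_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: '", ext, "'", call. = FALSE)
  }
}

# Canonical serialized form: unset (NULL) keys are omitted and inherit
# their defaults on load.
drop_nulls <- function(x) {
  if (!is.list(x) || is.null(names(x))) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

write_flat_config <- function(x, path) {
  x <- drop_nulls(x)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config extension: '", ext, "'", call. = FALSE)
  }
  invisible(path)
}
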