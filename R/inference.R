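# Ordinary least squares on a prebuilt design matrix via Householder QR.
# Returns NULL on rank deficiency if allow_singular, else stops naming the
# offending columns.
ols_qr <- function(X, y, allow_singular = FALSE) {
  qrx <- qr(X)
  p <- ncol(X)
  if (qrx$rank < p) {
    if (allow_singular) return(NULL)
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qrx, y)
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  n <- length(y)
  df_res <- n - p
  rss <- sum(resid^2)
  sigma2 <- rss / df_res
  # (X'X)^-1 from the R factor
  Rinv <- backsolve(qr.R(qrx), diag(p))
  xtx_inv <- Rinv %*% t(Rinv)
  # undo column pivoting
  unpiv <- order(qrx$pivot)
  xtx_inv <- xtx_inv[unpiv, unpiv, drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(X)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  adj_r2 <- if (tss > 0) 1 - (1 - r2) * (n - 1) / df_res else 1
  k <- p - 1L  # slope count, assuming an intercept column
  fstat <- if (k > 0 && rss > 0) ((tss - rss) / k) / sigma2 else Inf
  list(coefficients = coef, se = se, residuals = resid, fitted = fitted,
       sigma = sqrt(sigma2), df_residual = df_res, r_squared = r2,
       adj_r_squared = adj_r2,
       fstatistic = c(value = fstat, numdf = k, dendf = df_res))
}

#' Linear model of the CRISPR-positive frequency change
#'
#' Fits, by ordinary least squares on a Householder QR decomposition, the
#' competition response (relative change in CRISPR-positive frequency under
#' phage) against the observed initial conditions: the
#' protection-difference statistic `f_delta0`, the composition of protection
#' within the CRISPR-positive subpopulation, and the initial CRISPR-positive
#' frequency.
#'
#' The immune-vs-resistant composition can be coded either as the bounded
#' immune fraction `C+ / (C+ + R+)` (default; the raw ratio `C+/R+` is
#' unbounded as `R+` vanishes) or as the raw ratio. The initial
#' CRISPR-positive frequency covariate can be dropped to assess it
#' separately.
#'
#' @param data Data frame with the response and predictor columns (the
#'   `wide` table of [generate_dataset()] fits directly).
#' @param response Name of the response column; default `"response"`.
#' @param predictors Character vector of predictor column names; default
#'   `c("f_delta0", <composition>, "initial_crispr_freq")` where
#'   `<composition>` follows `ratio_coding`.
#' @param ratio_coding `"fraction"` (default) or `"ratio"`.
#' @return An object of class `"crispr_glm"` with `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `fitted` and `confint` methods.
#' @examples
#' d <- data.frame(f_delta0 = seq(-0.3, 0.3, length.out = 12),
#'                 immune_fraction = rep(c(0.2, 0.8), 6),
#'                 initial_crispr_freq = 0.5)
#' d$response <- 1.5 * d$f_delta0 + 0.1 * d$immune_fraction
#' coef(fit_glm(d))
#' @export
fit_glm <- function(data, response = "response", predictors = NULL,
                    ratio_coding = c("fraction", "ratio")) {
  ratio_coding <- match.arg(ratio_coding)
  if (is.null(predictors)) {
    comp <- if (ratio_coding == "fraction") "immune_fraction"
            else "immune_resistant_ratio"
    predictors <- c("f_delta0", comp, "initial_crispr_freq")
  }
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  mf <- data[, cols, drop = FALSE]
  if (anyNA(mf)) stop("missing values in response or predictors",
                      call. = FALSE)
  y <- as.numeric(mf[[response]])
  n <- length(y)
  if (n <= length(predictors) + 1L)
    stop("need more observations than predictors + 1", call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(mf[, predictors, drop = FALSE]))
  fit <- ols_qr(X, y)
  pf <- stats::pf(fit$fstatistic[["value"]], fit$fstatistic[["numdf"]],
                  fit$fstatistic[["dendf"]], lower.tail = FALSE)
  structure(c(fit, list(p_value = pf, n_obs = n, response = response,
                        predictors = predictors, X = X, y = y,
                        model = mf, call = match.call())),
            class = "crispr_glm")
}

#' @export
print.crispr_glm <- function(x, ...) {
  cat("Linear model of CRISPR+ frequency change (", x$n_obs,
      " observations)\n", sep = "")
  print(round(x$coefficients, 6))
  cat(sprintf("adj R-squared: %.4f, F(%d, %d) = %.2f, p = %.3g\n",
              x$adj_r_squared, x$fstatistic[["numdf"]],
              x$fstatistic[["dendf"]], x$fstatistic[["value"]], x$p_value))
  invisible(x)
}

#' @export
summary.crispr_glm <- function(object, ...) {
  tval <- object$coefficients / object$se
  pval <- 2 * stats::pt(abs(tval), object$df_residual, lower.tail = FALSE)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = tval, `Pr(>|t|)` = pval)
  out <- list(coefficients = tab, adj_r_squared = object$adj_r_squared,
              r_squared = object$r_squared, sigma = object$sigma,
              fstatistic = object$fstatistic, p_value = object$p_value,
              n_obs = object$n_obs)
  class(out) <- "summary.crispr_glm"
  out
}

#' @export
print.summary.crispr_glm <- function(x, ...) {
  stats::printCoefmat(x$coefficients, digits = 5)
  cat(sprintf("\nResidual SE %.5f, R-squared %.4f (adjusted %.4f)\n",
              x$sigma, x$r_squared, x$adj_r_squared))
  cat(sprintf("F(%d, %d) = %.2f, p = %.3g on %d observations\n",
              x$fstatistic[["numdf"]], x$fstatistic[["dendf"]],
              x$fstatistic[["value"]], x$p_value, x$n_obs))
  invisible(x)
}

#' @export
coef.crispr_glm <- function(object, ...) object$coefficients

#' @export
residuals.crispr_glm <- function(object, ...) object$residuals

#' @export
fitted.crispr_glm <- function(object, ...) object$fitted

#' @export
predict.crispr_glm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols))
    stop("newdata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  X <- cbind(1, as.matrix(newdata[, object$predictors, drop = FALSE]))
  drop(X %*% object$coefficients)
}

#' @export
confint.crispr_glm <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  a <- (1 - level) / 2
  tq <- stats::qt(1 - a, object$df_residual)
  out <- cbind(cf[parm] - tq * object$se[parm],
               cf[parm] + tq * object$se[parm])
  colnames(out) <- paste0(100 * c(a, 1 - a), " %")
  out
}

#' Case-resampling bootstrap confidence intervals for the linear model
#'
#' Nonparametric bootstrap of [fit_glm()]: rows of the model frame are
#' resampled with replacement, the model refitted, and percentile intervals
#' taken per coefficient. Resamples whose design matrix is rank deficient
#' are redrawn (the redraw count is reported).
#'
#' @param object A `"crispr_glm"` fit.
#' @param n_boot Number of bootstrap draws, >= 1000; default 10000.
#' @param seed Integer seed; intervals are reproducible under it.
#' @param level Confidence level; default 0.95.
#' @return A matrix with one row per coefficient and columns `lower`,
#'   `upper`, with attributes `n_boot`, `level`, `n_redraws` and
#'   `estimates` (the bootstrap coefficient draws).
#' @export
bootstrap_ci <- function(object, n_boot = 10000, seed = 1, level = 0.95) {
  stopifnot(inherits(object, "crispr_glm"))
  if (n_boot < 1000) stop("n_boot must be >= 1000", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  X <- object$X
  y <- object$y
  n <- nrow(X)
  p <- ncol(X)
  draws <- matrix(NA_real_, n_boot, p, dimnames = list(NULL, colnames(X)))
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- ols_qr(X[idx, , drop = FALSE], y[idx], allow_singular = TRUE)
      if (!is.null(fit)) break
      redraws <- redraws + 1L
      if (redraws > 100L * n_boot)
        stop("bootstrap resamples persistently rank deficient", call. = FALSE)
    }
    draws[b, ] <- fit$coefficients
  }
  a <- (1 - level) / 2
  ci <- t(apply(draws, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE,
                type = 7))
  colnames(ci) <- c("lower", "upper")
  attr(ci, "n_boot") <- n_boot
  attr(ci, "level") <- level
  attr(ci, "n_redraws") <- redraws
  attr(ci, "estimates") <- draws
  ci
}

#' Expected no-phage drift direction per condition under cost asymmetry
#'
#' Without phage, frequency change in the model is driven entirely by the
#' division-rate costs: each subpopulation loses growth in proportion to its
#' cost burden (`c_R` on the surface-resistant share, `c_I` on the immune
#' share). The CRISPR-positive frequency drifts up when the CRISPR-negative
#' subpopulation carries the heavier burden, and down in the opposite case.
#'
#' @param mixes List of `"strain_mix"` objects ([build_initial_mixes()]).
#' @param params A [model_params()].
#' @return Named character vector over conditions with values `"greater"`,
#'   `"less"` or `"two.sided"` (equal burdens).
#' @export
expected_baseline_directions <- function(mixes, params = model_params()) {
  out <- vapply(mixes, function(m) {
    f <- m$frequencies
    np <- sum(f[c("S_plus", "R_plus", "C_plus")])
    nm <- sum(f[c("S_minus", "R_minus")])
    burden_plus <- (params$c_R * f[["R_plus"]] +
                      params$c_I * f[["C_plus"]]) / np
    burden_minus <- params$c_R * f[["R_minus"]] / nm
    if (burden_minus > burden_plus) "greater"
    else if (burden_minus < burden_plus) "less"
    else "two.sided"
  }, character(1))
  names(out) <- vapply(mixes, function(m) m$condition_label, character(1))
  out
}

#' One-tailed baseline tests of no-phage drift with FDR correction
#'
#' For each condition, a one-sample t-test of the mean no-phage deviation of
#' the CRISPR-positive frequency from zero, one-tailed in the stated
#' direction, followed by Benjamini-Hochberg adjustment across conditions.
#'
#' @param baseline Data frame with columns `condition` and the deviation
#'   column named by `value`; the `wide` table of [generate_dataset()] works
#'   directly with `value = "baseline_change"`.
#' @param directions Named character vector over conditions with elements
#'   `"greater"`, `"less"` or `"two.sided"` (alternative hypotheses for the
#'   mean deviation). See [expected_baseline_directions()].
#' @param value Name of the deviation column; default `"baseline_change"`.
#' @param alpha FDR level used for the `significant` flag; default 0.05.
#' @return Data frame with one row per condition: `condition`, `n`, `mean`,
#'   `t`, `df`, `direction`, `p_value`, `p_adjusted`, `significant`.
#' @export
baseline_tests <- function(baseline, directions, value = "baseline_change",
                           alpha = 0.05) {
  if (!all(c("condition", value) %in% names(baseline)))
    stop("baseline needs columns 'condition' and '", value, "'",
         call. = FALSE)
  conds <- unique(baseline$condition)
  if (missing(directions) || is.null(directions))
    stop("directions must be supplied (see expected_baseline_directions)",
         call. = FALSE)
  missing_dir <- setdiff(conds, names(directions))
  if (length(missing_dir))
    stop("no direction given for condition(s): ",
         paste(missing_dir, collapse = ", "), call. = FALSE)
  rows <- lapply(conds, function(cond) {
    x <- baseline[[value]][baseline$condition == cond]
    n <- length(x)
    if (n < 2) stop("condition ", cond, " has fewer than 2 replicates",
                    call. = FALSE)
    m <- mean(x)
    s <- stats::sd(x)
    dir <- directions[[cond]]
    if (s == 0) {
      if (m != 0)
        stop("zero-variance group with nonzero mean in condition ", cond,
             call. = FALSE)
      tstat <- 0
    } else {
      tstat <- m / (s / sqrt(n))
    }
    p <- switch(dir,
                greater = stats::pt(tstat, n - 1, lower.tail = FALSE),
                less = stats::pt(tstat, n - 1, lower.tail = TRUE),
                two.sided = 2 * stats::pt(abs(tstat), n - 1,
                                          lower.tail = FALSE),
                stop("direction must be 'greater', 'less' or 'two.sided'",
                     call. = FALSE))
    data.frame(condition = cond, n = n, mean = m, t = tstat, df = n - 1,
               direction = dir, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out
}

#' Per-replicate model predictions for a competition dataset
#'
#' Re-runs the deterministic model from each replicate's *observed* initial
#' genotype frequencies (phage arm, `t = 0`) and returns the predicted
#' relative change in CRISPR-positive frequency, aligned with the rows of
#' the dataset's wide table.
#'
#' @param dataset A `"competition_dataset"` or the list returned by
#'   [read_dataset_csv()].
#' @param params A [model_params()].
#' @param N0,V0 Density and dose used for the prediction runs.
#' @param settings An [integration_settings()].
#' @return Numeric vector of predicted responses.
#' @export
predict_dataset <- function(dataset, params = model_params(), N0 = 1e6,
                            V0 = 1e4, settings = integration_settings()) {
  long <- dataset$long
  wide <- dataset$wide
  vapply(seq_len(nrow(wide)), function(i) {
    sub <- long[long$condition == wide$condition[i] &
                  long$replicate == wide$replicate[i] & long$phage_added, ]
    f0 <- sub$freq_t0[match(state_names[1:5], sub$genotype)]
    names(f0) <- state_names[1:5]
    predict_experiment(f0 / sum(f0), N0 = N0, V0 = V0, params = params,
                       settings = settings)
  }, numeric(1))
}

#' Fraction of replicates whose predicted and observed responses agree in sign
#'
#' Signs are taken with a dead-band: values with absolute magnitude below
#' `dead_band` count as zero, and two zeros agree.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param dead_band Magnitude below which a response counts as no change.
#' @return Fraction in \[0, 1\].
#' @export
sign_prediction_accuracy <- function(observed, predicted,
                                     dead_band = 1e-6) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have the same length", call. = FALSE)
  s <- function(x) ifelse(abs(x) < dead_band, 0, sign(x))
  mean(s(observed) == s(predicted))
}
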