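test_that("noise-free linear data are recovered exactly", {
  set.seed(301)
  d <- data.frame(f_delta0 = runif(24, -0.3, 0.3),
                  immune_fraction = runif(24),
                  initial_crispr_freq = runif(24))
  d$response <- 0.2 + 1.6 * d$f_delta0 + 0.05 * d$immune_fraction
  fit <- fit_glm(d)
  expect_equal(unname(coef(fit)), c(0.2, 1.6, 0.05, 0), tolerance = 1e-8)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-10)
})

test_that("QR-based least squares matches the closed form and stats::lm", {
  set.seed(302)
  x <- runif(30)
  y <- 2 + 3 * x + rnorm(30, sd = 0.5)
  d <- data.frame(response = y, f_delta0 = x)
  fit <- fit_glm(d, predictors = "f_delta0")
  slope_cf <- cov(x, y) / var(x)                 # textbook closed form
  expect_equal(coef(fit)[["f_delta0"]], slope_cf, tolerance = 1e-12)
  # independent route: the formula-interface fitter
  ref <- stats::lm(response ~ f_delta0, data = d)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, summary(ref)$adj.r.squared,
               tolerance = 1e-10)
  expect_equal(fit$fstatistic[["value"]],
               unname(summary(ref)$fstatistic["value"]), tolerance = 1e-8)
})

test_that("pure-noise responses yield a non-significant fit covering zero", {
  set.seed(7)
  d <- data.frame(response = rnorm(36), f_delta0 = runif(36),
                  immune_fraction = runif(36),
                  initial_crispr_freq = runif(36))
  fit <- fit_glm(d)
  expect_gt(fit$p_value, 0.05)
  ci <- bootstrap_ci(fit, n_boot = 2000, seed = 8)
  expect_lt(ci["f_delta0", "lower"], 0)
  expect_gt(ci["f_delta0", "upper"], 0)
})

test_that("degenerate designs raise informative errors", {
  d <- data.frame(response = rnorm(12), f_delta0 = runif(12))
  d$immune_fraction <- 2 * d$f_delta0        # exactly collinear
  d$initial_crispr_freq <- runif(12)
  expect_error(fit_glm(d), "collinear.*immune_fraction|immune_fraction")
  expect_error(fit_glm(d[1:3, ], predictors = c("f_delta0",
                                                "initial_crispr_freq")),
               "more observations")
  d2 <- data.frame(response = c(NA, rnorm(11)), f_delta0 = runif(12))
  expect_error(fit_glm(d2, predictors = "f_delta0"), "missing")
})

test_that("bootstrap intervals are seed-deterministic and collapse with noise", {
  set.seed(303)
  d <- data.frame(f_delta0 = runif(24, -0.3, 0.3),
                  immune_fraction = runif(24))
  d$response <- 1.5 * d$f_delta0 + 0.1 * d$immune_fraction +
    rnorm(24, sd = 0.05)
  fit <- fit_glm(d, predictors = c("f_delta0", "immune_fraction"))
  ci1 <- bootstrap_ci(fit, n_boot = 1000, seed = 99)
  ci2 <- bootstrap_ci(fit, n_boot = 1000, seed = 99)
  expect_identical(ci1, ci2)
  expect_error(bootstrap_ci(fit, n_boot = 10), ">= 1000")

  # interval width shrinks towards zero as residual noise vanishes
  widths <- vapply(c(0.1, 1e-3, 1e-6), function(s) {
    d$response <- 1.5 * d$f_delta0 + rnorm(24, sd = s)
    f <- fit_glm(d, predictors = c("f_delta0", "immune_fraction"))
    ci <- bootstrap_ci(f, n_boot = 1000, seed = 1)
    ci["f_delta0", "upper"] - ci["f_delta0", "lower"]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], 1e-5)

  # percentile endpoints are monotone in the confidence level
  lv <- c(0.5, 0.8, 0.95)
  cis <- lapply(lv, function(l) bootstrap_ci(fit, 1000, seed = 4, level = l))
  lo <- vapply(cis, function(ci) ci["f_delta0", "lower"], numeric(1))
  hi <- vapply(cis, function(ci) ci["f_delta0", "upper"], numeric(1))
  expect_true(all(diff(lo) <= 0))
  expect_true(all(diff(hi) >= 0))
})

test_that("bootstrap intervals approximately attain nominal coverage", {
  # 200 linear datasets (n = 36, true slope 2); percentile intervals at
  # this sample size are expected to sit slightly below 95%, so the band
  # is the nominal rate +/- binomial noise widened for that known bias
  set.seed(1)
  cover <- 0
  for (i in 1:200) {
    x <- runif(36)
    y <- 1 + 2 * x + rnorm(36)
    fit <- fit_glm(data.frame(response = y, f_delta0 = x),
                   predictors = "f_delta0")
    ci <- bootstrap_ci(fit, n_boot = 1000, seed = i)
    if (ci["f_delta0", "lower"] <= 2 && ci["f_delta0", "upper"] >= 2)
      cover <- cover + 1
  }
  expect_gte(cover / 200, 0.88)
  expect_lte(cover / 200, 0.99)
})

test_that("Benjamini-Hochberg adjustment matches the hand step-up rule", {
  hand_bh <- function(p) {           # independent step-up implementation
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  p1 <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)
  expect_equal(stats::p.adjust(p1, "BH"), rep(0.06, 6))
  expect_equal(stats::p.adjust(p1, "BH"), hand_bh(p1))
  p2 <- c(0.005, 0.011, 0.02, 0.04, 0.04, 0.5)
  expect_equal(stats::p.adjust(p2, "BH"),
               c(0.030, 0.033, 0.040, 0.048, 0.048, 0.500))
  # adjustment never decreases a p-value and preserves ordering
  set.seed(304)
  for (i in 1:20) {
    p <- runif(8)
    adj <- stats::p.adjust(p, "BH")
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_equal(adj, hand_bh(p))
  }
})

test_that("baseline tests handle degenerate groups as specified", {
  d0 <- data.frame(condition = rep("a", 4), baseline_change = rep(0, 4))
  out <- baseline_tests(d0, directions = c(a = "less"))
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 0.5)
  expect_false(out$significant)
  dbad <- data.frame(condition = rep("a", 4), baseline_change = rep(0.2, 4))
  expect_error(baseline_tests(dbad, directions = c(a = "less")),
               "zero-variance")
  expect_error(baseline_tests(d0, directions = c(b = "less")),
               "no direction")
  expect_error(baseline_tests(data.frame(condition = "a",
                                         baseline_change = 1),
                              directions = c(a = "less")), "2 replicates")
})

test_that("a surface-resistance cost produces detectable no-phage drift", {
  # c_R = 0.05, c_I = 0: the subpopulation carrying more costly surface
  # resistance loses ground without phage. Conditions where the CRISPR+
  # protection is not immune-dominated (C+ <= R+, f_delta positive) must
  # drift downward and be flagged at FDR 0.05.
  ds <- generate_dataset(noise = noise_settings(kappa = 2000, jitter_sd = 0),
                         n_replicates = 10, seed = 13)
  dirs <- expected_baseline_directions(ds$mixes, model_params())
  expect_identical(unname(dirs[c("fpos_CeqR", "fpos_CltR")]),
                   c("less", "less"))
  bt <- baseline_tests(ds$wide, dirs)
  flagged <- bt$condition[bt$significant]
  expect_true(all(c("fpos_CeqR", "fpos_CltR") %in% flagged))
  expect_true(all(bt$mean[bt$condition %in% c("fpos_CeqR", "fpos_CltR")] < 0))
})

test_that("sign_prediction_accuracy scores matched signs with a dead-band", {
  x <- c(-0.2, 0.3, 0.5, -0.1)
  expect_equal(sign_prediction_accuracy(x, x), 1)
  expect_equal(sign_prediction_accuracy(c(0, 1e-9), c(1e-8, -1e-9)), 1)
  expect_error(sign_prediction_accuracy(1:3, 1:2), "length")
  # random guessing against symmetric noise sits at chance level
  set.seed(305)
  acc <- replicate(200, sign_prediction_accuracy(rnorm(50),
                                                 sample(c(-1, 1), 50,
                                                        replace = TRUE)))
  expect_equal(mean(acc), 0.5, tolerance = 0.05)
})

test_that("the fitted model recovers the f_delta-driven effect on synthetic
           datasets", {
  for (s in c(21, 22, 23)) {
    ds <- generate_dataset(seed = s)
    fit <- fit_glm(ds$wide)
    expect_gt(coef(fit)[["f_delta0"]], 0)
    ci <- bootstrap_ci(fit, n_boot = 1000, seed = s)
    expect_gt(ci["f_delta0", "lower"], 0)
  }
})
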