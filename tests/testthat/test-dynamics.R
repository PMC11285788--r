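test_that("without phage or costs the CRISPR+ frequency is conserved", {
  traj <- integrate_full(scenario_state(V0 = 0), zero_cost_params(),
                         integration_settings())
  expect_lt(max(abs(traj$N_plus_freq - traj$N_plus_freq[1])), 1e-9)
})

test_that("frequency change over an epidemic follows the sign of f_delta(0)", {
  p <- ref_params()
  set <- integration_settings()
  pos <- integrate_full(scenario_state(), p, set)
  expect_gt(pos$N_plus_freq[nrow(pos)], pos$N_plus_freq[1])
  neg <- integrate_full(scenario_state(mirror = TRUE), p, set)
  expect_lt(neg$N_plus_freq[nrow(neg)], neg$N_plus_freq[1])
})

test_that("monotone sign law: change keeps one sign before fixation", {
  set <- integration_settings()
  for (mirror in c(FALSE, TRUE)) {
    traj <- integrate_full(scenario_state(mirror = mirror),
                           zero_cost_params(), set)
    pre <- traj$S_minus + traj$S_plus >= set$fixation_threshold
    d <- diff(traj$N_plus_freq[pre])
    d <- d[abs(d) > 1e-12]
    expect_true(all(d > 0) || all(d < 0))
    expect_equal(unique(sign(d)), if (mirror) -1 else 1)
  }
})

test_that("adaptive trajectory reports non-negative densities and a sane N", {
  traj <- integrate_full(scenario_state(), ref_params(),
                         integration_settings(t_end = 48))
  expect_true(all(as.matrix(traj[, c("S_minus", "R_minus", "S_plus",
                                     "R_plus", "C_plus", "V")]) >= 0))
  # carrying-capacity bound with m_b = 0 and N(0) < K
  expect_lt(max(traj$N_total), 1e9 * (1 + 1e-6))
})

test_that("solver failure is reported with the failing time", {
  suppressWarnings(expect_error(   # deSolve also warns before our error
    integrate_full(pop_state(S_minus = 1e6, V = 1e4),
                   model_params(B = 1e8, m_v = 0),
                   integration_settings(rel_tol = 1e-13, abs_tol = 1e-300)),
    "failed near t"))
})

test_that("reduced equation matches the constant-coefficient closed form", {
  s <- 1e-9 * 1e4 * 0.2              # alpha V f_delta
  settings <- integration_settings(t_end = 24)
  out <- integrate_reduced(0.3, function(t) 0.2, function(t) 1e4, 1e-9,
                           settings)
  analytic <- function(t, x0) x0 * exp(s * t) / (1 + x0 * (exp(s * t) - 1))
  expect_lt(max(abs(out$N_plus - analytic(out$time, 0.3))), 1e-8)

  # f_delta = 0 keeps the frequency fixed
  flat <- integrate_reduced(0.4, function(t) 0, function(t) 1e5, 1e-9,
                            settings)
  expect_equal(flat$N_plus, rep(0.4, nrow(flat)), tolerance = 1e-12)
})

test_that("reduced dynamics driven by a full run reproduce the full N+(t)", {
  p0 <- zero_cost_params()
  for (mirror in c(FALSE, TRUE)) {
    traj <- integrate_full(scenario_state(mirror = mirror), p0,
                           integration_settings())
    red <- reduced_from_trajectory(traj)
    rel <- abs(red$N_plus - traj$N_plus_freq) / traj$N_plus_freq
    expect_lt(max(rel), 1e-6)
  }
})

test_that("sign_outcome classifies the direction of selection", {
  p0 <- zero_cost_params()
  set <- integration_settings()
  expect_identical(sign_outcome(scenario_state(), p0, set), "increase")
  expect_identical(sign_outcome(scenario_state(mirror = TRUE), p0, set),
                   "decrease")
  # symmetric protection on both sides: f_delta = 0 exactly, no change
  sym <- state_from_frequencies(scenario_freqs(rho_plus = 0.2,
                                               rho_minus = 0.2), 1e6, 1e4)
  expect_identical(sign_outcome(sym, p0, set), "no_change")
  expect_error(sign_outcome(pop_state(S_minus = 1, V = 1), p0, set),
               "undefined")
})

test_that("sign outcome does not depend on the initial CRISPR+ frequency", {
  p <- ref_params()
  set <- integration_settings()
  for (mirror in c(FALSE, TRUE)) {
    outs <- vapply(c(0.01, 0.1, 0.5, 0.9), function(np) {
      st <- state_from_frequencies(scenario_freqs(n_plus0 = np,
                                                  mirror = mirror), 1e6, 1e4)
      sign_outcome(st, p, set)
    }, character(1))
    expect_length(unique(outs), 1L)
  }
})

test_that("fixation_check finds the sensitive collapse and the plateau", {
  p <- ref_params()
  traj <- integrate_full(scenario_state(), p,
                         integration_settings(t_end = 200))
  fx <- fixation_check(traj)
  expect_true(fx$collapse_reached)
  expect_lt(fx$collapse_time, 24)
  expect_lt(abs(fx$f_delta_end), 1e-3)
  expect_true(fx$plateau)

  # no phage: collapse never reached
  fx0 <- fixation_check(integrate_full(scenario_state(V0 = 0), p,
                                       integration_settings(t_end = 48)))
  expect_false(fx0$collapse_reached)
  expect_true(is.na(fx0$collapse_time))

  # protection only on the CRISPR+ side: f_delta tends to 1 at collapse
  one_sided <- state_from_frequencies(
    c(S_minus = 0.5, R_minus = 0, S_plus = 0.35, R_plus = 0.075,
      C_plus = 0.075), 1e6, 1e4)
  fx1 <- fixation_check(integrate_full(one_sided, p,
                                       integration_settings(t_end = 200)))
  expect_true(fx1$collapse_reached)
  expect_lt(abs(fx1$f_delta_end - 1), 1e-3)
  expect_true(fx1$plateau)
})

test_that("fixed-step Euler converges linearly to the adaptive solution", {
  p <- ref_params()
  st <- scenario_state()
  fin <- final_state_vec(integrate_full(st, p, integration_settings()))
  err <- vapply(c(2e-4, 1e-4), function(dt) {
    eu <- as.numeric(integrate_euler(st, p, t_end = 24, dt = dt)[1:6])
    max(abs(fin - eu) / pmax(abs(fin), 1))
  }, numeric(1))
  # first-order convergence towards the adaptive answer
  expect_lt(err[2], err[1])
  expect_equal(err[1] / err[2], 2, tolerance = 0.15)
  # the bacterial compartments agree tightly at dt = 1e-4
  eu <- as.numeric(integrate_euler(st, p, t_end = 24, dt = 1e-4)[1:6])
  expect_lt(max(abs(fin[1:5] - eu[1:5]) / pmax(abs(fin[1:5]), 1)), 1e-4)
})

test_that("predict_experiment returns the paired-arm relative change", {
  p <- ref_params()
  set <- integration_settings()
  expect_gt(predict_experiment(scenario_freqs(), params = p, settings = set),
            0)
  expect_lt(predict_experiment(scenario_freqs(mirror = TRUE), params = p,
                               settings = set), 0)
  # no phage in either arm: exactly no relative change
  expect_equal(predict_experiment(scenario_freqs(), V0 = 0, params = p,
                                  settings = set), 0, tolerance = 1e-9)
  expect_error(predict_experiment(c(0.5, 0.2, 0.2, 0.2, 0.2)), "sum to 1")
})

test_that("trajectory CSV round-trips with the fixed column contract", {
  traj <- integrate_full(scenario_state(), ref_params(),
                         integration_settings(t_end = 2))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- read_trajectory_csv(f)
  expect_identical(names(back),
                   c("time", "S_minus", "R_minus", "S_plus", "R_plus",
                     "C_plus", "V", "N_total", "N_plus_freq", "f_delta"))
  expect_equal(back$N_plus_freq, traj$N_plus_freq, tolerance = 1e-12)
  unlink(f)
})
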