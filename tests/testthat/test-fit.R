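# Decomposition fitting: recovery against generator ground truth.

test_that("noiseless windows are recovered to high relative accuracy", {
  sched <- schedule_A(spacing = 1200, n = 3)
  sim <- simulate_experiment(sched, truth_params(), noise_drift_spec())
  fit <- fit_dissolution_series(sim$trace)
  tab <- fit$table[order(fit$table$injection), ]
  for (i in 1:3) {
    kin <- sim$truth$kinetics[[i]]
    expect_equal(tab$k_inv[i], 1 / kin$k, tolerance = 1e-3)
    expect_equal(tab$alpha[i], kin$alpha, tolerance = 1e-3)
    expect_equal(tab$enthalpy_dis_uJ[i], dissolution_enthalpy(kin),
                 tolerance = 1e-3)
  }
  # calibrated shape constants match the generator (omega within 1 %)
  expect_equal(fit$shape$omega, pi / 30, tolerance = 0.01)
  expect_equal(fit$shape$delta, 0.2, tolerance = 0.05)
})

test_that("dilution-only windows show no significant dissolution amplitude", {
  # start the cell above the solubility: nothing dissolves
  sched <- injection_schedule(30, 10, 1460, spacing = 600, n_injections = 2,
                              c0_cell = 6)
  sim <- simulate_experiment(sched, truth_params(),
                             noise_drift_spec(noise_sd = 0.05, seed = 21))
  expect_null(sim$truth$kinetics[[1]])
  # force the dissolution component into the model and test its amplitude;
  # k_inv is capped at the reliability horizon (spacing/3) because slower
  # kinetics are indistinguishable from baseline within one window
  cfg <- fit_config(include_dissolution = "always",
                    k_inv_bounds = c(1, 600 / 3),
                    shape_constants = list(omega = pi / 30, delta = 0.2,
                                           w = 0.01, delta_L = 15))
  fit <- fit_dissolution_series(sim$trace, config = cfg)
  f1 <- fit$fits[[1]]
  expect_true(f1$converged)
  # physically negligible: peak power below 3x the noise floor and the
  # amplitude statistically consistent with zero
  comp <- predict(fit, injection = 1, components = TRUE)
  expect_lt(max(abs(comp$dissolution)), 3 * 0.05)
  expect_lt(abs(f1$estimates[["A"]]) / f1$se[["A"]], 3)
  # the dilution amplitudes themselves are recovered
  expect_equal(f1$estimates[["B"]], -2, tolerance = 0.05)
  expect_equal(f1$estimates[["C"]], 1.5, tolerance = 0.05)
})

test_that("noisy recovery at 2 percent noise stays within 10 percent on k_inv", {
  sched <- schedule_A(spacing = 600, n = 3)
  truth <- truth_params()
  clean <- simulate_experiment(sched, truth, noise_drift_spec())
  sd2pct <- 0.02 * max(abs(clean$trace$values))
  sim <- simulate_experiment(sched, truth,
                             noise_drift_spec(noise_sd = sd2pct, seed = 42))
  fit <- fit_dissolution_series(sim$trace)
  tab <- fit$table[order(fit$table$injection), ]
  for (i in 1:3) {
    kin <- sim$truth$kinetics[[i]]
    expect_equal(tab$k_inv[i], 1 / kin$k, tolerance = 0.1)
  }
})

test_that("dilution shape calibration recovers omega and fails on flat windows", {
  sched <- schedule_A(spacing = 800, n = 1)
  sim <- simulate_experiment(sched, truth_params(), noise_drift_spec())
  corr <- correct_baseline(sim$trace)
  win <- segment_injections(corr)[[1]]
  shape <- calibrate_dilution_shape(win, 0, sched)
  expect_equal(shape$omega, pi / 30, tolerance = 0.01)

  flat <- power_trace(0:599, rep(0, 600),
                      annotations = list(injection = 1, onset = 0))
  expect_error(calibrate_dilution_shape(flat, 0, sched), "resolvable")
})

test_that("closed-form and quadrature enthalpies of the fitted model agree", {
  sched <- schedule_A(spacing = 1200, n = 1)
  sim <- simulate_experiment(sched, truth_params(), noise_drift_spec())
  fit <- fit_dissolution_series(sim$trace)
  f1 <- fit$fits[[1]]
  # quadrature oracle over a long grid of the fitted dissolution component
  comp <- predict(fit, injection = 1, t = seq(0, 3000, by = 0.25),
                  components = TRUE)
  expect_equal(trapz(comp$t, comp$dissolution),
               f1$enthalpies[["dis_uJ"]], tolerance = 1e-3)
  # molar enthalpy recovered within 5 percent of the -1.4 kJ/mol truth
  expect_equal(f1$enthalpies[["dis_kJ_per_mol"]], -1.4, tolerance = 0.05)
})

test_that("series assembly orders by concentration and flags slow injections", {
  mk <- function(i, c_b, c_a, k_inv, conv = TRUE) {
    structure(list(injection = i, c_before = c_b, c_after = c_a,
                   converged = conv, include_dis = TRUE, include_lor = FALSE,
                   estimates = c(A = -2000, k_inv = k_inv, alpha = 2, B = -2),
                   enthalpies = c(dis_uJ = -350, dil_exo_uJ = -38,
                                  dil_endo_uJ = 0, dis_kJ_per_mol = -1.4,
                                  dis_kJ_per_mol_injected = -1.2),
                   rss = 1), class = "injection_fit")
  }
  fits <- list(mk(1, 0.4, 0.6, 100), mk(2, 0.2, 0.4, 250), mk(3, 0, 0.2, 30))
  tab <- assemble_series(fits, spacing = 600)
  expect_equal(tab$injection, c(3, 2, 1))       # ordered by c_after
  expect_equal(tab$unreliable, c(FALSE, TRUE, FALSE))  # 250 > 600/3
  expect_error(assemble_series(list(), 600), "at least one")
})

test_that("the fitted series reproduces the corrected trace per window", {
  sched <- schedule_A(spacing = 600, n = 2)
  sim <- simulate_experiment(sched, truth_params(), noise_drift_spec())
  fit <- fit_dissolution_series(sim$trace)
  res <- residuals(fit)
  # floor set by the affine window nuisance approximating the cubic baseline
  for (i in 1:2)
    expect_lt(max(abs(res[[i]])), 5e-3 * max(abs(fit$fits[[i]]$window$values)))
})
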