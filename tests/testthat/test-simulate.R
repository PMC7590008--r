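test_that("concentration-dependent truth kinetics follow the rate law and lag interpolation", {
  dc0 <- 30 * 10 / 1460
  f <- 1 - 5 / 30
  expect_null(kinetics_for_concentration(5, 30, 5, 10, -2044, f, dc0))
  expect_null(kinetics_for_concentration(7, 30, 5, 10, -2044, f, dc0))
  k0 <- kinetics_for_concentration(0, 30, 5, 10, -2044, f, dc0)
  expect_equal(1 / k0$k, 30)
  expect_equal(k0$alpha, 10)
  khalf <- kinetics_for_concentration(2.5, 30, 5, 10, -2044, f, dc0)
  expect_equal(1 / khalf$k, 60)      # rate law at half-solubility
  expect_equal(khalf$alpha, 5.5)     # linear midpoint of 10 -> 1
})

test_that("noiseless trace equals the forward model at the sample points", {
  sched <- schedule_A(spacing = 400, n = 4)
  sim <- simulate_experiment(sched, truth_params(), noise_drift_spec())
  tr <- sim$trace
  expect_equal(length(tr$times), 5 * 400 + 1)  # null lead-in + 4 windows
  manual <- numeric(length(tr$times))
  for (i in seq_len(4)) {
    on <- sim$truth$onset[i]
    idx <- tr$times >= on
    manual[idx] <- manual[idx] +
      injection_power(tr$times[idx] - on, sim$truth$kinetics[[i]],
                      sim$truth$peaks[[i]])
  }
  # null-injection blip: volume-scaled half-sine at t = 0
  null_peak <- sim$truth$peaks[[1]][[1]]
  null_peak$B <- null_peak$B * sched$null_injection[1] / sched$V_inj
  manual <- manual + dilution_power(tr$times, null_peak)
  expect_equal(tr$values, manual, tolerance = 1e-12)
})

test_that("simulation is deterministic in the seed and noise-only across seeds", {
  sched <- schedule_A(spacing = 400, n = 2)
  ns <- noise_drift_spec(noise_sd = 0.1, drift_coeffs = c(0.5, 1e-4), seed = 11)
  s1 <- simulate_experiment(sched, truth_params(), ns)
  s2 <- simulate_experiment(sched, truth_params(), ns)
  expect_identical(s1$trace$values, s2$trace$values)
  s3 <- simulate_experiment(sched, truth_params(),
                            noise_drift_spec(0.1, c(0.5, 1e-4), seed = 12))
  diffs <- s3$trace$values - s1$trace$values
  expect_gt(stats::sd(diffs), 0.1)          # different noise realisation
  expect_lt(abs(mean(diffs)), 0.01)         # same underlying signal + drift
})

test_that("per-injection truth enthalpies match window quadrature", {
  # generous spacing so each window contains essentially the whole decay
  sched <- schedule_A(spacing = 1200, n = 3)
  sim <- simulate_experiment(sched, truth_params(), noise_drift_spec(),
                             dt = 0.5)
  tr <- sim$trace
  for (i in 1:3) {
    on <- sim$truth$onset[i]
    idx <- which(tr$times >= on & tr$times < on + sched$spacing)
    # isolate this injection: subtract everything else analytically
    rest <- numeric(length(idx))
    for (j in seq_len(3)) {
      if (j == i) next
      sel <- tr$times[idx] >= sim$truth$onset[j]
      rest[sel] <- rest[sel] +
        injection_power(tr$times[idx][sel] - sim$truth$onset[j],
                        sim$truth$kinetics[[j]], sim$truth$peaks[[j]])
    }
    own <- tr$values[idx] - rest
    # strip the null blip from the first window
    np <- sim$truth$peaks[[1]][[1]]
    np$B <- np$B * sched$null_injection[1] / sched$V_inj
    own <- own - dilution_power(tr$times[idx], np)
    H_total <- sim$truth$enthalpy_dis[i] + sim$truth$enthalpy_dil_exo[i] +
      sim$truth$enthalpy_dil_endo[i]
    expect_equal(trapz(tr$times[idx], own), H_total, tolerance = 5e-3)
  }
})

test_that("straddling injections scale the dissolution amplitude by the undersaturated fraction", {
  sched <- schedule_B(spacing = 400, n = 3)
  sim <- simulate_experiment(sched, truth_params(), noise_drift_spec())
  conc <- cell_concentration_series(sched)
  dc0 <- step_concentration(sched)
  A_full <- -1.4 * sched$V_cell
  for (i in 1:3) {
    kin <- sim$truth$kinetics[[i]]
    scale <- min(1, max(0, (5 - conc$c_before[i]) / dc0))
    if (scale == 0) expect_null(kin)
    else expect_equal(kin$A, A_full * scale)
  }
  # injection 3 straddles c_s = 5 (c_before 4.81): partial amplitude
  expect_lt(abs(sim$truth$kinetics[[3]]$A), abs(A_full))
})

test_that("too-coarse sampling is a configuration error", {
  sched <- schedule_A(spacing = 400, n = 2)
  expect_error(simulate_experiment(sched, truth_params(), noise_drift_spec(),
                                   dt = 5), "resolve")
})

test_that("traces round-trip through CSV with the schedule sidecar", {
  sched <- schedule_A(spacing = 400, n = 2)
  sim <- simulate_experiment(sched, truth_params(),
                             noise_drift_spec(noise_sd = 0.05, seed = 3))
  path <- file.path(withr::local_tempdir(), "trace.csv")
  write_trace(sim$trace, path)
  back <- read_trace(path)
  expect_identical(back$times, sim$trace$times)
  expect_identical(back$values, sim$trace$values)
  expect_equal(unclass(back$schedule)[c("c_inj", "V_inj", "V_cell", "spacing")],
               unclass(sched)[c("c_inj", "V_inj", "V_cell", "spacing")])

  # missing sidecar: readable, schedule absent, with a warning
  file.remove(paste0(path, ".json"))
  expect_warning(noside <- read_trace(path), "sidecar")
  expect_null(noside$schedule)

  # non-monotone time column is a parse error naming the line
  df <- utils::read.csv(path)
  df$time_s[3] <- df$time_s[5]
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_trace(path), "line")
})
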