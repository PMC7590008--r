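test_that("peak detection brackets the true peak and ignores flat traces", {
  sched <- schedule_A(spacing = 600, n = 1)
  sim <- simulate_experiment(sched, truth_params(), noise_drift_spec())
  b <- detect_peak_bounds(sim$trace)
  expect_equal(nrow(b), 1)
  # the detected support contains the injection ramp and the dissolution
  # minimum, and starts within 2 samples of the true signal onset
  on <- sim$truth$onset[1]
  t_min <- sim$trace$times[which.min(sim$trace$values)]
  expect_lte(abs(b$start_s - on), 2)
  expect_gt(b$end_s, t_min)

  flat <- power_trace(0:499, rep(1.5, 500))
  expect_equal(nrow(detect_peak_bounds(flat, onsets = 0)), 0)
  # threshold above the maximum derivative: nothing found
  expect_equal(nrow(detect_peak_bounds(sim$trace, threshold = 1e9)), 0)
})

test_that("peak detection is invariant under a constant offset", {
  sched <- schedule_A(spacing = 600, n = 2)
  sim <- simulate_experiment(sched, truth_params(),
                             noise_drift_spec(noise_sd = 0.05, seed = 5))
  b1 <- detect_peak_bounds(sim$trace)
  shifted <- power_trace(sim$trace$times, sim$trace$values + 17,
                         schedule = sim$trace$schedule,
                         annotations = sim$trace$annotations)
  b2 <- detect_peak_bounds(shifted)
  expect_identical(b1, b2)
})

test_that("baseline correction recovers a pure cubic drift exactly", {
  tt <- seq(0, 2000, by = 1)
  drift <- 2 + 3e-3 * tt - 4e-7 * tt^2 + 5e-11 * tt^3
  tr <- power_trace(tt, drift)
  corr <- correct_baseline(tr, bounds = data.frame(window = integer(0),
                                                   start = integer(0),
                                                   end = integer(0)))
  expect_lt(max(abs(corr$values)), 1e-9 * max(abs(drift)))

  zero <- power_trace(tt, numeric(length(tt)))
  czero <- correct_baseline(zero, bounds = data.frame(window = integer(0),
                                                      start = integer(0),
                                                      end = integer(0)))
  expect_equal(czero$values, numeric(length(tt)))
})

test_that("peak integrals survive cubic drift within 1 percent", {
  sched <- schedule_A(spacing = 1200, n = 3)
  truth <- truth_params()
  clean <- simulate_experiment(sched, truth, noise_drift_spec())
  T_end <- max(clean$trace$times)
  drift_cf <- c(1, 0.8 / T_end, -0.6 / T_end^2, 0.4 / T_end^3)
  drifted <- simulate_experiment(sched, truth, noise_drift_spec(
    noise_sd = 0, drift_coeffs = drift_cf))
  corr <- correct_baseline(drifted$trace)
  ref <- correct_baseline(clean$trace)
  b <- corr$annotations$peak_bounds
  expect_equal(nrow(b), 3)
  for (i in 1:3) {
    idx <- b$start[i]:b$end[i]
    got <- trapz(corr$times[idx], corr$values[idx])
    want <- trapz(ref$times[idx], ref$values[idx])
    expect_equal(got, want, tolerance = 0.01)
    # and the corrected integral sits close to the truth enthalpy: the chord
    # rule clips the sub-threshold tail, a small known bias (few percent)
    H <- drifted$truth$enthalpy_dis[i] + drifted$truth$enthalpy_dil_exo[i]
    expect_equal(got, H, tolerance = 0.05)
  }
})

test_that("baseline correction is idempotent and zero-mean off-peak", {
  # drift only: with heavy noise the derivative threshold marks whole
  # windows as peaks and there is no off-peak region to speak of
  sched <- schedule_A(spacing = 800, n = 2)
  sim <- simulate_experiment(sched, truth_params(), noise_drift_spec(
    noise_sd = 0, drift_coeffs = c(1, 5e-4), seed = 8))
  c1 <- correct_baseline(sim$trace)
  in_peak <- rep(FALSE, length(c1$times))
  b <- c1$annotations$peak_bounds
  for (i in seq_len(nrow(b))) in_peak[b$start[i]:b$end[i]] <- TRUE
  # zero-mean residual over the baseline's support (the null-injection blip
  # at the start of the lead-in is excluded from the fit)
  support <- !in_peak & c1$times >= 3 * sched$t_inj
  expect_lt(abs(mean(c1$values[support])), 1e-10)
  c2 <- correct_baseline(c1, bounds = b)
  expect_equal(c2$values, c1$values, tolerance = 1e-6)

  # a peak spanning the whole trace leaves no baseline support
  allpeak <- data.frame(window = 1L, start = 1L,
                        end = length(sim$trace$times))
  expect_error(correct_baseline(sim$trace, bounds = allpeak), "support")
})

test_that("segmentation partitions the trace at the schedule onsets", {
  sched <- schedule_A(spacing = 500, n = 27)
  sim <- simulate_experiment(sched, truth_params(), noise_drift_spec())
  wins <- segment_injections(sim$trace)
  expect_length(wins, 27)
  onsets <- sim$truth$onset
  for (i in c(1, 13, 27))
    expect_equal(wins[[i]]$annotations$onset, onsets[i])
  # concatenating windows reproduces every sample from the first onset on
  cat_vals <- unlist(lapply(wins, function(w) w$values))
  expect_identical(cat_vals,
                   sim$trace$values[sim$trace$times >= onsets[1]])
  # windows are onset-referenced
  expect_equal(wins[[2]]$times[1], 0)
  # trace/schedule mismatch
  short <- power_trace(0:99, rnorm(100))
  expect_error(segment_injections(short, sched), "injections")
})

test_that("peak bounds export as a 3-column BED-like table", {
  b <- data.frame(window = 1:2, start = c(10L, 40L), end = c(20L, 60L),
                  start_s = c(9, 39), end_s = c(19, 59))
  path <- tempfile(fileext = ".bed")
  write_peak_bounds(b, path)
  got <- utils::read.table(path)
  expect_equal(ncol(got), 3)
  expect_equal(got$V2, b$start_s)
})
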