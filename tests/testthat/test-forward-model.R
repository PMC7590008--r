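test_that("injection ramps behave at their landmarks", {
  dc0 <- 0.21
  expect_equal(delta_c_ideal(0, dc0), 0)
  expect_equal(delta_c_ideal(30, dc0, t_inj = 30), dc0)
  expect_equal(delta_c_ideal(15, dc0, t_inj = 30), dc0 / 2)
  expect_error(delta_c_ideal(-1, dc0), ">= 0")

  expect_equal(delta_c_smooth(0, dc0), 0)
  expect_equal(delta_c_smooth(15, dc0, k_inj = 1 / 15), dc0 * (1 - exp(-1)))
  expect_equal(delta_c_smooth(1e6, dc0), dc0)
  # monotone increasing and bounded by dc0
  tt <- seq(0, 400, by = 0.5)
  v <- delta_c_smooth(tt, dc0)
  expect_true(all(diff(v) > 0))
  expect_true(all(v <= dc0))
})

test_that("monomer concentration is sigmoidal, monotone and saturates", {
  kin <- ref_kinetics(alpha = 4)
  expect_equal(monomer_concentration(0, kin), kin$c_mon0)
  expect_equal(monomer_concentration(1e7, kin), kin$c_mon0 + kin$delta_c0,
               tolerance = 1e-12)
  tt <- seq(0, 2000, by = 1)
  v <- monomer_concentration(tt, kin)
  expect_true(all(diff(v) >= 0))
  # no aggregates: pure monomer addition
  kin0 <- dissolution_kinetics(A = -100, k = 1 / 30, alpha = 2, f_agg = 0,
                               delta_c0 = 0.21, c_mon0 = 1)
  expect_equal(monomer_concentration(tt, kin0),
               1 + delta_c_smooth(tt, 0.21))
  expect_error(dissolution_kinetics(A = 1, k = 1, alpha = 0.5, f_agg = 0.5,
                                    delta_c0 = 0.2), "alpha")
})

test_that("dissolution power is the time derivative of the dissolution term", {
  for (prm in list(c(k_inv = 30, alpha = 10), c(k_inv = 120, alpha = 2),
                   c(k_inv = 60, alpha = 1), c(k_inv = 300, alpha = 1.5))) {
    kin <- ref_kinetics(k_inv = prm[["k_inv"]], alpha = prm[["alpha"]])
    # independent oracle: central finite differences of A * (third term of the
    # monomer-production function)
    g <- function(t) kin$A * kin$f_agg *
      delta_c_smooth(t, kin$delta_c0, kin$k_inj) *
      (1 - exp(-kin$k * t))^kin$alpha
    tt <- seq(0.1, 10 / kin$k, length.out = 400)
    h <- 1e-4 * min(1 / kin$k, 1 / kin$k_inj)
    fd <- (g(tt + h) - g(tt - h)) / (2 * h)
    expect_lt(max(abs(dissolution_power(tt, kin) - fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("dissolution power has a lag and conserves the closed-form enthalpy", {
  kin <- ref_kinetics(k_inv = 30, alpha = 3)
  expect_equal(dissolution_power(0, kin), 0)
  tt <- seq(0, -log(1e-10) / kin$k, by = 0.02)
  v <- dissolution_power(tt, kin)
  # single interior minimum for exothermic A < 0, away from t = 0
  expect_gt(tt[which.min(v)], 0)
  sg <- sign(diff(v[tt > 0.1]))
  expect_equal(sum(diff(sg[sg != 0]) != 0), 1)  # one sign change of the slope
  # quadrature oracle against A * f_agg * dc0
  expect_equal(trapz(tt, v), dissolution_enthalpy(kin), tolerance = 1e-3)
  expect_equal(dissolution_enthalpy(kin), kin$A * kin$f_agg * kin$delta_c0)
  # identity cases
  expect_equal(dissolution_enthalpy(dissolution_kinetics(
    A = -7, k = 1, alpha = 2, f_agg = 1, delta_c0 = 1)), -7)
  expect_equal(dissolution_enthalpy(dissolution_kinetics(
    A = 0, k = 1, alpha = 2, f_agg = 0.5, delta_c0 = 1)), 0)
})

test_that("dilution peaks have the stated shapes, supports and areas", {
  hs <- dilution_peak("half_sine", B = -2, omega = pi / 30, delta = 0.3)
  t0 <- hs$delta / hs$omega
  t1 <- (hs$delta + pi) / hs$omega
  expect_equal(dilution_power(t0, hs), 0, tolerance = 1e-12)
  expect_equal(dilution_power(t1, hs), 0, tolerance = 1e-12)
  expect_equal(dilution_power(t1 + 1, hs), 0)  # zero outside the half period
  mid <- (t0 + t1) / 2
  expect_equal(dilution_power(mid, hs), hs$B)
  tt <- seq(0, 200, by = 0.001)
  expect_equal(trapz(tt, dilution_power(tt, hs)), 2 * hs$B / hs$omega,
               tolerance = 1e-6)

  lor <- dilution_peak("lorentzian", C = 1.5, w = 0.01, delta = 15)
  expect_equal(dilution_power(15, lor), 1.5)
  expect_equal(dilution_power(25, lor), 1.5 / 2)  # half max at delta + 1/sqrt(w)
  expect_error(dilution_peak("triangle"), "arg")
})

test_that("injection power is the sum of its components", {
  kin <- ref_kinetics(k_inv = 40, alpha = 2)
  hs <- dilution_peak("half_sine", B = -2, omega = pi / 30, delta = 0.2)
  lor <- dilution_peak("lorentzian", C = 1, w = 0.02, delta = 10)
  tt <- seq(0, 300, by = 1)
  expect_equal(injection_power(tt), numeric(length(tt)))
  expect_equal(injection_power(tt, peaks = list(hs)), dilution_power(tt, hs))
  expect_equal(injection_power(tt, kin, list(hs, lor)),
               dissolution_power(tt, kin) + dilution_power(tt, hs) +
                 dilution_power(tt, lor))
})

test_that("molar enthalpy normalisations convert amplitude to kJ/mol", {
  # -1.4 kJ/mol in a 1460 uL cell corresponds to A = -2044 uJ/mM
  expect_equal(molar_enthalpy(A_ref(), 1460), -1.4)
  expect_equal(molar_enthalpy(A_ref(), 1460, f_agg = 0.5, per = "injected"),
               -0.7)
  kin <- ref_kinetics()
  expect_equal(molar_enthalpy(kin, 1460), -1.4)
})
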