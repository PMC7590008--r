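# Shared fixtures: the two reference experiments and a desk-scale variant
# with compressed spacing for fast fitting tests.

schedule_A <- function(spacing = 3600, n = 27)
  injection_schedule(c_inj = 30, V_inj = 10, V_cell = 1460, t_inj = 30,
                     spacing = spacing, n_injections = n, c0_cell = 0)

schedule_B <- function(spacing = 3600, n = 27)
  injection_schedule(c_inj = 30, V_inj = 10, V_cell = 1460, t_inj = 30,
                     spacing = spacing, n_injections = n, c0_cell = 4.4)

# Amplitude (uJ/mM) equivalent to the -1.4 kJ/mol molar dissolution enthalpy
# in the 1.46 mL cell.
A_ref <- function(V_cell = 1460, dH = -1.4) dH * V_cell

ref_kinetics <- function(A = A_ref(), k_inv = 30, alpha = 10,
                         f_agg = 1 - 5 / 30, delta_c0 = 30 * 10 / 1460)
  dissolution_kinetics(A = A, k = 1 / k_inv, alpha = alpha,
                       f_agg = f_agg, delta_c0 = delta_c0)

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
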