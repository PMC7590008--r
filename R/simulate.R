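#' Noise and baseline-drift specification for the generator
#'
#' Real thermograms carry i.i.d. instrument noise and a slow baseline drift;
#' the generator adds both on top of the noiseless forward model. The drift is
#' a polynomial in time of degree at most 3 (matching the cubic baseline model
#' used by the preprocessing).
#'
#' @param noise_sd standard deviation of the Gaussian sample noise (uJ/s).
#' @param drift_coeffs polynomial coefficients of the drift, lowest order
#'   first (`drift(t) = sum(drift_coeffs[k] * t^(k-1))`, uJ/s with t in s);
#'   at most 4 coefficients (degree 3).
#' @param seed integer random seed; the simulation is deterministic given it.
#' @return An object of class `noise_drift_spec`.
#' @export
noise_drift_spec <- function(noise_sd = 0, drift_coeffs = 0, seed = 1L) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (length(drift_coeffs) > 4L) stop("drift polynomial degree must be <= 3")
  structure(list(noise_sd = noise_sd, drift_coeffs = as.numeric(drift_coeffs),
                 seed = as.integer(seed)),
            class = "noise_drift_spec")
}

drift_eval <- function(t, coeffs) {
  out <- numeric(length(t))
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * t^(k - 1)
  out
}

#' Ground-truth parameters for a synthetic experiment
#'
#' Physical truth from which [simulate_experiment()] builds a trace: the
#' monomer solubility, the infinite-dilution inverse dissolution rate, the
#' low-concentration lag exponent, the molar dissolution enthalpy, and the
#' empirical dilution peak shapes. Defaults are the values reported for the
#' A8K fibril system: `c_s = 5` mM, `k0_inv = 30` s, `alpha_low = 10`,
#' `dH_dis_molar = -1.4` kJ/mol.
#'
#' @param c_s monomer solubility (mM).
#' @param k0_inv infinite-dilution inverse dissolution rate (s).
#' @param alpha_low lag exponent at infinite dilution; `alpha` falls linearly
#'   to 1 at `c = c_s`.
#' @param dH_dis_molar molar dissolution enthalpy (kJ/mol, per mole of
#'   dissolved peptide; negative = exothermic).
#' @param dilution_B exothermic half-sine amplitude (uJ/s).
#' @param dilution_omega half-sine angular frequency (1/s); the default makes
#'   the dilution peak span roughly the 30 s injection.
#' @param dilution_delta half-sine phase delay.
#' @param lorentzian_C endothermic Lorentzian amplitude (uJ/s), used for
#'   injections starting at or above `c_s` where two fast modes are resolved.
#' @param lorentzian_w Lorentzian width parameter (1/s^2).
#' @param lorentzian_delta Lorentzian centre (s).
#' @return An object of class `synthetic_truth_params`.
#' @export
truth_params <- function(c_s = 5, k0_inv = 30, alpha_low = 10,
                         dH_dis_molar = -1.4,
                         dilution_B = -2, dilution_omega = pi / 30,
                         dilution_delta = 0.2,
                         lorentzian_C = 1.5, lorentzian_w = 0.01,
                         lorentzian_delta = 15) {
  if (c_s <= 0) stop("'c_s' must be > 0 (mM)")
  if (k0_inv <= 0) stop("'k0_inv' must be > 0 (s)")
  if (alpha_low < 1) stop("'alpha_low' must be >= 1")
  structure(list(c_s = c_s, k0_inv = k0_inv, alpha_low = alpha_low,
                 dH_dis_molar = dH_dis_molar,
                 dilution_B = dilution_B, dilution_omega = dilution_omega,
                 dilution_delta = dilution_delta,
                 lorentzian_C = lorentzian_C, lorentzian_w = lorentzian_w,
                 lorentzian_delta = lorentzian_delta),
            class = "synthetic_truth_params")
}

#' Dissolution kinetics implied by the cell concentration
#'
#' Builds the [dissolution_kinetics()] truth for an injection into a cell at
#' concentration `c`: no dissolution at or above the solubility (`NULL`); below
#' it, the rate constant follows the reversible rate law
#' `k^-1 = k0_inv * c_s / (c_s - c)` and the lag exponent interpolates
#' linearly from `alpha_low` at `c = 0` to 1 at `c = c_s`.
#'
#' @param c cell concentration before the injection (mM).
#' @param k0_inv infinite-dilution inverse rate (s).
#' @param c_s monomer solubility (mM).
#' @param alpha_low lag exponent at `c = 0`.
#' @param A_scale amplitude (uJ/mM) of the dissolution heat.
#' @param f_agg aggregate fraction of the injected peptide.
#' @param delta_c0 concentration step (mM).
#' @param k_inj injection smoothing rate (1/s).
#' @return A [dissolution_kinetics()] object, or `NULL` for `c >= c_s`.
#' @export
kinetics_for_concentration <- function(c, k0_inv, c_s, alpha_low, A_scale,
                                       f_agg, delta_c0, k_inj = 1 / 15) {
  if (c < 0) stop("'c' must be >= 0 (mM)")
  if (c >= c_s) return(NULL)
  k_inv <- reversible_rate_inverse(c, rate_model_params(k0_inv, c_s))
  alpha <- max(1, alpha_low + (1 - alpha_low) * c / c_s)
  dissolution_kinetics(A = A_scale, k = 1 / k_inv, alpha = alpha,
                       k_inj = k_inj, f_agg = f_agg, delta_c0 = delta_c0,
                       c_mon0 = min(c, c_s))
}

#' Simulate a complete multi-injection ITC experiment
#'
#' Builds a uniformly sampled differential-power trace for the whole
#' schedule. Each injection window contains its fast dilution peak(s) and,
#' when the cell starts below the solubility, the slow dissolution component
#' with concentration-dependent rate and lag; injections that straddle the
#' solubility have their dissolution amplitude scaled by the undersaturated
#' fraction `clip((c_s - c_before) / dc0, 0, 1)`. A global polynomial drift
#' and i.i.d. Gaussian noise are added on top. The null injection (if
#' declared) appears as a small volume-scaled dilution blip at `t = 0` and is
#' excluded from the truth records.
#'
#' @param schedule an [injection_schedule()].
#' @param truth a [truth_params()] object.
#' @param noise a [noise_drift_spec()].
#' @param dt sampling interval (s); must resolve the injection
#'   (`dt <= t_inj / 10`).
#' @return A list with components `trace` (a [power_trace()]) and `truth`
#'   (data.frame of per-injection ground truth, one row per injection, with
#'   the kinetics and peak objects in list-columns and component enthalpies
#'   in uJ).
#' @export
simulate_experiment <- function(schedule, truth = truth_params(),
                                noise = noise_drift_spec(), dt = 1) {
  stopifnot(inherits(schedule, "injection_schedule"),
            inherits(truth, "synthetic_truth_params"),
            inherits(noise, "noise_drift_spec"))
  if (dt > schedule$t_inj / 10)
    stop(sprintf("sampling interval dt = %g s cannot resolve t_inj = %g s injections (need dt <= t_inj/10)",
                 dt, schedule$t_inj))
  dc0 <- step_concentration(schedule)
  f_agg <- aggregate_fraction(schedule$c_inj, truth$c_s)
  A_scale <- truth$dH_dis_molar * schedule$V_cell  # kJ/mol * uL -> uJ/mM
  onsets <- injection_onsets(schedule)
  total_t <- onsets[length(onsets)] + schedule$spacing
  times <- seq(0, total_t, by = dt)
  values <- numeric(length(times))

  conc <- cell_concentration_series(schedule)
  n <- schedule$n_injections
  half_sine <- dilution_peak("half_sine", B = truth$dilution_B,
                             omega = truth$dilution_omega,
                             delta = truth$dilution_delta)
  lorentz <- dilution_peak("lorentzian", C = truth$lorentzian_C,
                           w = truth$lorentzian_w,
                           delta = truth$lorentzian_delta)

  kin_list <- vector("list", n)
  peaks_list <- vector("list", n)
  H_dis <- H_dil_exo <- H_dil_endo <- numeric(n)
  for (i in seq_len(n)) {
    cb <- conc$c_before[i]
    kin <- kinetics_for_concentration(cb, truth$k0_inv, truth$c_s,
                                      truth$alpha_low, A_scale,
                                      f_agg, dc0)
    if (!is.null(kin)) {
      # partial undersaturation: only the fraction of the step below c_s dissolves
      scale <- min(1, max(0, (truth$c_s - cb) / dc0))
      if (scale < 1) kin$A <- kin$A * scale
    }
    peaks <- list(half_sine)
    if (cb >= truth$c_s) peaks <- c(peaks, list(lorentz))
    idx <- times >= onsets[i]
    tt <- times[idx] - onsets[i]
    values[idx] <- values[idx] + injection_power(tt, kin, peaks)
    kin_list[i] <- list(kin)   # keeps NULL entries (no dissolution above c_s)
    peaks_list[[i]] <- peaks
    H_dis[i] <- if (is.null(kin)) 0 else dissolution_enthalpy(kin)
    H_dil_exo[i] <- 2 * truth$dilution_B / truth$dilution_omega
    H_dil_endo[i] <- if (cb >= truth$c_s)
      truth$lorentzian_C * pi / sqrt(truth$lorentzian_w) else 0
  }

  if (!is.null(schedule$null_injection)) {
    # dilution-only blip, amplitude scaled by injected volume
    vol_scale <- schedule$null_injection[1] / schedule$V_inj
    null_peak <- half_sine
    null_peak$B <- null_peak$B * vol_scale
    idx <- times >= 0
    values[idx] <- values[idx] + dilution_power(times[idx], null_peak)
  }

  values <- values + drift_eval(times, noise$drift_coeffs)
  if (noise$noise_sd > 0) {
    set.seed(noise$seed)
    values <- values + stats::rnorm(length(values), sd = noise$noise_sd)
  }

  truth_df <- data.frame(injection = seq_len(n),
                         c_before = conc$c_before, c_after = conc$c_after,
                         onset = onsets,
                         enthalpy_dis = H_dis,
                         enthalpy_dil_exo = H_dil_exo,
                         enthalpy_dil_endo = H_dil_endo)
  truth_df$kinetics <- kin_list
  truth_df$peaks <- peaks_list

  trace <- power_trace(times, values, schedule = schedule,
                       annotations = list(onsets = onsets))
  list(trace = trace, truth = truth_df)
}
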