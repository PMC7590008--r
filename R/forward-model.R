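#' Dissolution kinetics parameters for one injection
#'
#' Bundle of the closed-form model parameters describing how one injection of
#' aggregate suspension dissolves in an undersaturated cell: the injected
#' concentration ramp, the sigmoidal monomer production with lag exponent
#' `alpha`, and the proportionality between monomer production rate and
#' measured differential power.
#'
#' @param A heat per unit concentration dissolved (uJ per mM); negative values
#'   describe exothermic dissolution, reproducing the observed minima in the
#'   differential power.
#' @param k dissolution rate constant (1/s).
#' @param alpha lag exponent (dimensionless, `>= 1`); `alpha > 1` delays the
#'   onset of dissolution after the injection.
#' @param k_inj smoothing rate of the injection ramp (1/s); default 1/15.
#' @param f_agg fraction of the injected peptide that is aggregated, in `[0, 1]`.
#' @param delta_c0 concentration step of the injection (mM).
#' @param c_mon0 free monomer concentration in the cell before the injection (mM).
#'
#' @return An object of class `dissolution_kinetics`.
#' @export
dissolution_kinetics <- function(A, k, alpha, k_inj = 1 / 15,
                                 f_agg, delta_c0, c_mon0 = 0) {
  stopifnot(is.numeric(A), is.numeric(k), is.numeric(alpha))
  if (k <= 0) stop("rate constant 'k' must be > 0 (1/s)")
  if (k_inj <= 0) stop("'k_inj' must be > 0 (1/s)")
  if (alpha < 1) stop("lag exponent 'alpha' must be >= 1")
  if (f_agg < 0 || f_agg > 1) stop("'f_agg' must lie in [0, 1]")
  if (delta_c0 <= 0) stop("'delta_c0' must be > 0 (mM)")
  if (c_mon0 < 0) stop("'c_mon0' must be >= 0 (mM)")
  structure(list(A = A, k = k, alpha = alpha, k_inj = k_inj,
                 f_agg = f_agg, delta_c0 = delta_c0, c_mon0 = c_mon0),
            class = "dissolution_kinetics")
}

#' Dilution peak shape
#'
#' Empirical shapes for the fast heat-of-dilution signal of one injection.
#' The common exothermic mode is half a period of a sine,
#' `B * sin(omega * t - delta)` on `delta/omega <= t <= (delta + pi)/omega`
#' and zero outside; the endothermic mode resolved at higher concentrations is
#' a Lorentzian `C / (1 + w * (t - delta)^2)`.
#'
#' @param shape `"half_sine"` or `"lorentzian"`.
#' @param B half-sine amplitude (uJ/s).
#' @param omega half-sine angular frequency (1/s); the peak lasts `pi/omega` s.
#' @param delta delay (s for `lorentzian`; the half-sine starts at
#'   `delta/omega` s, i.e. `delta` is a phase).
#' @param C Lorentzian amplitude (uJ/s).
#' @param w Lorentzian width parameter (1/s^2).
#' @return An object of class `dilution_peak`.
#' @export
dilution_peak <- function(shape = c("half_sine", "lorentzian"),
                          B = NULL, omega = NULL, delta = 0,
                          C = NULL, w = NULL) {
  shape <- match.arg(shape)
  if (shape == "half_sine") {
    if (is.null(B) || is.null(omega)) stop("half_sine needs 'B' and 'omega'")
    if (omega <= 0) stop("'omega' must be > 0")
    out <- list(shape = shape, B = B, omega = omega, delta = delta)
  } else {
    if (is.null(C) || is.null(w)) stop("lorentzian needs 'C' and 'w'")
    if (w <= 0) stop("'w' must be > 0")
    out <- list(shape = shape, C = C, w = w, delta = delta)
  }
  structure(out, class = "dilution_peak")
}

#' Ideal (piecewise-linear) injected concentration ramp
#'
#' The concentration added to the cell grows linearly during the injection and
#' is constant afterwards: `dc0 * t / t_inj` for `t < t_inj`, `dc0` for
#' `t >= t_inj`. Provided for reference; model fitting uses the smoothed ramp
#' [delta_c_smooth()] to avoid the discontinuous first derivative.
#'
#' @param t time since injection onset (s), vectorised, `>= 0`.
#' @param delta_c0 concentration step (mM).
#' @param t_inj injection duration (s).
#' @return Added concentration (mM).
#' @export
delta_c_ideal <- function(t, delta_c0, t_inj = 30) {
  if (any(t < 0)) stop("time 't' must be >= 0")
  if (t_inj <= 0) stop("'t_inj' must be > 0")
  ifelse(t < t_inj, delta_c0 * t / t_inj, delta_c0)
}

#' Smoothed (exponential) injected concentration ramp
#'
#' `dc(t) = dc0 * (1 - exp(-k_inj * t))`: monotone increasing, bounded by
#' `dc0`, with `k_inj = 1/15` 1/s giving a time dependence similar to the
#' 30 s linear ramp but with a continuous derivative.
#'
#' @inheritParams delta_c_ideal
#' @param k_inj smoothing rate (1/s).
#' @return Added concentration (mM).
#' @export
delta_c_smooth <- function(t, delta_c0, k_inj = 1 / 15) {
  if (any(t < 0)) stop("time 't' must be >= 0")
  if (k_inj <= 0) stop("'k_inj' must be > 0")
  delta_c0 * (1 - exp(-k_inj * t))
}

#' Free monomer concentration during one injection
#'
#' Sigmoidal test function for monomer production: the pre-injection monomer
#' level, plus the directly injected monomers `(1 - f_agg) * dc(t)`, plus the
#' monomers produced by aggregate dissolution
#' `f_agg * dc(t) * (1 - exp(-k t))^alpha`, where `dc(t)` is the smoothed
#' injection ramp. For `alpha > 1` the dissolution term has an effective lag.
#'
#' @param t time since injection onset (s), vectorised.
#' @param params a [dissolution_kinetics()] object.
#' @return Monomer concentration (mM).
#' @export
monomer_concentration <- function(t, params) {
  stopifnot(inherits(params, "dissolution_kinetics"))
  if (any(t < 0)) stop("time 't' must be >= 0")
  dc <- delta_c_smooth(t, params$delta_c0, params$k_inj)
  params$c_mon0 + (1 - params$f_agg) * dc +
    params$f_agg * dc * (1 - exp(-params$k * t))^params$alpha
}

#' Differential power of the slow dissolution process
#'
#' Time derivative of the dissolution term of [monomer_concentration()],
#' scaled by the proportionality constant `A`:
#' \deqn{\Delta P_{dis}(t) = A f_{agg} \Delta c_0 \left[
#'   k_{inj} e^{-k_{inj} t} (1 - e^{-kt})^\alpha +
#'   (1 - e^{-k_{inj} t})\, \alpha k e^{-kt} (1 - e^{-kt})^{\alpha - 1}\right]}
#' For `alpha > 1` the signal starts at exactly zero and passes through a
#' single interior extremum (a minimum for exothermic `A < 0`), i.e. the
#' dissolution is delayed relative to the injection.
#'
#' @inheritParams monomer_concentration
#' @return Differential power (uJ/s).
#' @export
dissolution_power <- function(t, params) {
  stopifnot(inherits(params, "dissolution_kinetics"))
  if (any(t < 0)) stop("time 't' must be >= 0")
  A <- params$A; k <- params$k; a <- params$alpha; ki <- params$k_inj
  s <- 1 - exp(-k * t)
  # s^(a-1) with 0^0 = 1 so that alpha = 1 reduces to the plain exponential
  s_am1 <- ifelse(s == 0 & a == 1, 1, s^(a - 1))
  A * params$f_agg * params$delta_c0 *
    (ki * exp(-ki * t) * s^a +
       (1 - exp(-ki * t)) * a * k * exp(-k * t) * s_am1)
}

#' Dissolution enthalpy of one injection (closed form)
#'
#' The time integral of [dissolution_power()] over the whole injection,
#' `dH = A * f_agg * dc0` (uJ). No quadrature is involved.
#'
#' @param params a [dissolution_kinetics()] object.
#' @return Enthalpy (uJ).
#' @export
dissolution_enthalpy <- function(params) {
  stopifnot(inherits(params, "dissolution_kinetics"))
  params$A * params$f_agg * params$delta_c0
}

#' Molar dissolution enthalpy
#'
#' Converts the amplitude `A` (uJ/mM) into a molar enthalpy (kJ/mol). Two
#' normalisations are available: per mole of peptide actually dissolved from
#' aggregates (`per = "dissolved"`, the default: `A / V_cell`) or per mole of
#' injected peptide (`per = "injected"`: `A * f_agg / V_cell`). With `A` in
#' uJ/mM and `V_cell` in uL the ratio is already in kJ/mol.
#'
#' @param A amplitude (uJ/mM), or a [dissolution_kinetics()] object.
#' @param V_cell cell volume (uL).
#' @param f_agg aggregate fraction (needed for `per = "injected"`).
#' @param per normalisation, `"dissolved"` or `"injected"`.
#' @return Molar enthalpy (kJ/mol).
#' @export
molar_enthalpy <- function(A, V_cell, f_agg = NULL,
                           per = c("dissolved", "injected")) {
  per <- match.arg(per)
  if (inherits(A, "dissolution_kinetics")) {
    f_agg <- A$f_agg
    A <- A$A
  }
  if (V_cell <= 0) stop("'V_cell' must be > 0 (uL)")
  if (per == "dissolved") A / V_cell
  else {
    if (is.null(f_agg)) stop("'f_agg' is required for per-injected normalisation")
    A * f_agg / V_cell
  }
}

#' Differential power of a fast dilution peak
#'
#' Evaluates a [dilution_peak()]: the half-sine is zero outside its
#' half-period support; the Lorentzian is defined everywhere.
#'
#' @param t time since injection onset (s), vectorised.
#' @param peak a [dilution_peak()] object.
#' @return Differential power (uJ/s).
#' @export
dilution_power <- function(t, peak) {
  stopifnot(inherits(peak, "dilution_peak"))
  if (any(t < 0)) stop("time 't' must be >= 0")
  if (peak$shape == "half_sine") {
    lo <- peak$delta / peak$omega
    hi <- (peak$delta + pi) / peak$omega
    ifelse(t >= lo & t <= hi, peak$B * sin(peak$omega * t - peak$delta), 0)
  } else {
    peak$C / (1 + peak$w * (t - peak$delta)^2)
  }
}

#' Total differential power of one injection
#'
#' Sum of the slow dissolution component (absent above the solubility) and any
#' number of fast dilution peaks.
#'
#' @param t time since injection onset (s), vectorised.
#' @param kinetics a [dissolution_kinetics()] object, or `NULL` when the cell
#'   is above the solubility and nothing dissolves.
#' @param peaks list of [dilution_peak()] objects (possibly empty).
#' @return Differential power (uJ/s).
#' @export
injection_power <- function(t, kinetics = NULL, peaks = list()) {
  out <- numeric(length(t))
  if (!is.null(kinetics)) out <- out + dissolution_power(t, kinetics)
  for (p in peaks) out <- out + dilution_power(t, p)
  out
}
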