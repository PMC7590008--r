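#' Configuration of the per-injection decomposition fit
#'
#' Collects the constants and knobs of the nonlinear least-squares
#' decomposition: the injection smoothing rate, the working estimate of the
#' solubility (which decides whether a dissolution component is included),
#' parameter bounds, multi-start grids, and the preprocessing settings.
#'
#' @param k_inj injection smoothing rate (1/s), held fixed during fitting.
#' @param c_s_estimate working monomer solubility (mM): injections starting
#'   below it are fitted with a dissolution component, injections at or above
#'   it with dilution peaks only (the endothermic Lorentzian is added there).
#' @param include_dissolution `"auto"` (by `c_s_estimate`), `"always"` or
#'   `"never"`.
#' @param alpha_bounds bounds for the lag exponent; default `c(1, 20)`.
#' @param k_inv_bounds bounds for the inverse rate `1/k` (s); `NULL` means
#'   `c(1, 10 * spacing)`, resolved at fit time.
#' @param alpha_starts multi-start values for `alpha`.
#' @param k_inv_starts multi-start values for `1/k` (s); `NULL` means
#'   `c(30, 0.1, 0.5) * spacing`-style grid resolved at fit time.
#' @param threshold derivative threshold (uJ/s per s) for peak detection.
#' @param smooth_window moving-average window (samples) for peak detection.
#' @param shape_constants `NULL` to calibrate the dilution shape constants
#'   (`omega`, `delta`, `w`, `delta_L`) on the data, or a named list fixing
#'   them.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(k_inj = 1 / 15, c_s_estimate = 5,
                       include_dissolution = c("auto", "always", "never"),
                       alpha_bounds = c(1, 20), k_inv_bounds = NULL,
                       alpha_starts = c(1.5, 3, 10), k_inv_starts = NULL,
                       threshold = 2e-3, smooth_window = 5L,
                       shape_constants = NULL) {
  include_dissolution <- match.arg(include_dissolution)
  if (k_inj <= 0) stop("'k_inj' must be > 0")
  if (alpha_bounds[1] < 1) stop("'alpha' is only defined for alpha >= 1")
  structure(list(k_inj = k_inj, c_s_estimate = c_s_estimate,
                 include_dissolution = include_dissolution,
                 alpha_bounds = alpha_bounds, k_inv_bounds = k_inv_bounds,
                 alpha_starts = alpha_starts, k_inv_starts = k_inv_starts,
                 threshold = threshold, smooth_window = as.integer(smooth_window),
                 shape_constants = shape_constants),
            class = "fit_config")
}

# Chord operator of the baseline correction: inside each detected peak
# interval subtract the straight line joining the vector's values at the
# interval ends. Applied to model predictions so that the fit sees its model
# through the same correction the data went through.
chord_correct <- function(v, bounds) {
  if (is.null(bounds) || nrow(bounds) == 0L) return(v)
  for (i in seq_len(nrow(bounds))) {
    s <- bounds$start[i]; e <- bounds$end[i]
    if (e > s) {
      line <- v[s] + (v[e] - v[s]) * (seq(s, e) - s) / (e - s)
      v[s:e] <- v[s:e] - line
    } else v[s] <- 0
  }
  v
}

# Unit-amplitude component shapes on the window time grid.
unit_dissolution <- function(tt, k_inv, alpha, k_inj, f_agg, delta_c0) {
  kin <- dissolution_kinetics(A = 1, k = 1 / k_inv, alpha = alpha,
                              k_inj = k_inj, f_agg = f_agg,
                              delta_c0 = delta_c0)
  dissolution_power(tt, kin)
}
unit_half_sine <- function(tt, omega, delta) {
  dilution_power(tt, dilution_peak("half_sine", B = 1, omega = omega,
                                   delta = delta))
}
unit_lorentzian <- function(tt, w, delta_L) {
  dilution_power(tt, dilution_peak("lorentzian", C = 1, w = w,
                                   delta = delta_L))
}

# Design matrix of the linear amplitudes (variable projection): columns are
# the unit dissolution shape (when included), the unit half-sine, the unit
# Lorentzian (when included) and an affine nuisance absorbing the local
# remainder of the global cubic baseline.
vp_design <- function(tt, nonlin, ctx) {
  cols <- list()
  if (ctx$include_dis)
    cols$A <- unit_dissolution(tt, nonlin[["k_inv"]], nonlin[["alpha"]],
                               ctx$k_inj, ctx$f_agg, ctx$delta_c0)
  omega <- if ("omega" %in% names(nonlin)) nonlin[["omega"]] else ctx$shape$omega
  delta <- if ("delta" %in% names(nonlin)) nonlin[["delta"]] else ctx$shape$delta
  cols$B <- unit_half_sine(tt, omega, delta)
  if (ctx$include_lor) {
    w <- if ("w" %in% names(nonlin)) nonlin[["w"]] else ctx$shape$w
    dL <- if ("delta_L" %in% names(nonlin)) nonlin[["delta_L"]] else ctx$shape$delta_L
    cols$C <- unit_lorentzian(tt, w, dL)
  }
  cols$a0 <- rep(1, length(tt))
  cols$a1 <- tt / max(tt[length(tt)], 1)
  do.call(cbind, cols)
}

# Profiled least squares for fixed nonlinear parameters: solve the linear
# amplitudes through the chord-corrected design, return rss and coefficients.
# Columns are rescaled to unit maximum for conditioning (a near-degenerate
# dissolution shape must not poison the other amplitudes).
vp_solve <- function(y, tt, nonlin, ctx) {
  X <- vp_design(tt, nonlin, ctx)
  Xc <- apply(X, 2, chord_correct, bounds = ctx$bounds)
  scale <- pmax(apply(abs(Xc), 2, max), 1e-300)
  Xs <- sweep(Xc, 2, scale, "/")
  qrX <- qr(Xs)
  beta <- qr.coef(qrX, y) / scale
  beta[is.na(beta)] <- 0
  fitted_c <- drop(Xc %*% beta)
  res <- y - fitted_c
  list(rss = sum(res^2), beta = beta, fitted = fitted_c, rank = qrX$rank,
       X = X)
}

# One multi-start variable-projection fit of a window. `free` names the
# nonlinear parameters (subset of k_inv, alpha, omega, delta, w, delta_L);
# `starts` is a list of named start vectors; `lower`/`upper` name-matched
# bounds. Nonlinear parameters are optimised on log scale where positive.
vp_fit <- function(y, tt, ctx, free, starts, lower, upper) {
  logpar <- setdiff(free, c("alpha", "delta"))   # positive-scale parameters
  to_opt <- function(p) {
    is_log <- names(p) %in% logpar
    p[is_log] <- log(p[is_log])
    p
  }
  from_opt <- function(q) {
    is_log <- names(q) %in% logpar
    q[is_log] <- exp(q[is_log])
    q
  }
  obj <- function(q) {
    p <- from_opt(q)
    vp_solve(y, tt, p, ctx)$rss
  }
  best <- NULL
  for (st in starts) {
    st <- st[free]
    q0 <- to_opt(st)
    lo <- to_opt(lower[free]); hi <- to_opt(upper[free])
    opt <- tryCatch(
      stats::optim(q0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$par_nat <- from_opt(opt$par)
    }
  }
  if (is.null(best)) return(NULL)
  sol <- vp_solve(y, tt, best$par_nat, ctx)
  # 52 = line-search failure, routinely hit at machine precision on
  # near-zero-residual (noiseless) objectives; the optimum is still valid
  list(nonlin = best$par_nat, beta = sol$beta, rss = sol$rss,
       fitted = sol$fitted, rank = sol$rank, X = sol$X,
       converged = best$convergence %in% c(0L, 52L))
}

#' Calibrate the dilution peak shape constants on one window
#'
#' Full fit of one injection window in which the dilution shape constants
#' (`omega` and `delta` of the half-sine and, when the window lies above the
#' working solubility, `w` and `delta_L` of the Lorentzian) are free
#' parameters alongside the kinetics. The constants are then frozen for the
#' rest of the series, mirroring instrument practice of using constant shape
#' parameters and varying only the amplitudes.
#'
#' @param window a baseline-corrected [power_trace()] window from
#'   [segment_injections()].
#' @param c_before cell concentration before this injection (mM).
#' @param schedule the [injection_schedule()].
#' @param config a [fit_config()].
#' @return Named list with `omega`, `delta` and (when calibrated) `w`,
#'   `delta_L`.
#' @export
calibrate_dilution_shape <- function(window, c_before, schedule,
                                     config = fit_config()) {
  stopifnot(inherits(window, "power_trace"), inherits(config, "fit_config"))
  y <- window$values
  if (max(abs(y)) < 10 * config$threshold || stats::sd(y) == 0)
    stop("window has no resolvable dilution peak; supply shape constants manually via fit_config(shape_constants = ...)")
  ctx <- window_context(window, c_before, schedule, config,
                        shape = list(omega = pi / schedule$t_inj, delta = 0.2,
                                     w = 0.01, delta_L = schedule$t_inj / 2))
  free <- c("omega", "delta")
  lower <- c(omega = pi / (20 * schedule$t_inj), delta = 0,
             w = 1e-5, delta_L = 0.5)
  upper <- c(omega = pi, delta = pi, w = 10, delta_L = 10 * schedule$t_inj)
  base <- c(omega = pi / schedule$t_inj, delta = 0.2,
            w = 0.01, delta_L = schedule$t_inj / 2)
  if (ctx$include_dis) {
    free <- c("k_inv", "alpha", free)
    lower <- c(k_inv = ctx$k_inv_bounds[1], alpha = config$alpha_bounds[1], lower)
    upper <- c(k_inv = ctx$k_inv_bounds[2], alpha = config$alpha_bounds[2], upper)
  }
  if (ctx$include_lor) free <- c(free, "w", "delta_L")
  starts <- list()
  for (a in config$alpha_starts)
    for (ki in ctx$k_inv_starts)
      starts[[length(starts) + 1L]] <- c(k_inv = ki, alpha = a, base)
  if (!ctx$include_dis) starts <- list(base)
  fit <- vp_fit(y, window$times, ctx, free, starts, lower, upper)
  if (is.null(fit)) stop("dilution shape calibration failed to converge")
  out <- list(omega = unname(fit$nonlin[["omega"]]),
              delta = unname(fit$nonlin[["delta"]]))
  if (ctx$include_lor) {
    out$w <- unname(fit$nonlin[["w"]])
    out$delta_L <- unname(fit$nonlin[["delta_L"]])
  }
  out
}

# Everything fit_injection needs about one window, resolved once.
window_context <- function(window, c_before, schedule, config, shape) {
  include_dis <- switch(config$include_dissolution,
                        auto = c_before < config$c_s_estimate,
                        always = TRUE, never = FALSE)
  k_inv_bounds <- config$k_inv_bounds
  if (is.null(k_inv_bounds)) k_inv_bounds <- c(1, 10 * schedule$spacing)
  k_inv_starts <- config$k_inv_starts
  if (is.null(k_inv_starts))
    k_inv_starts <- sort(unique(pmin(pmax(
      c(30, 0.1 * schedule$spacing, 0.5 * schedule$spacing),
      k_inv_bounds[1]), k_inv_bounds[2])))
  list(include_dis = include_dis,
       include_lor = c_before >= config$c_s_estimate,
       k_inj = config$k_inj,
       f_agg = aggregate_fraction(schedule$c_inj, config$c_s_estimate),
       delta_c0 = step_concentration(schedule),
       bounds = window$annotations$peak_bounds,
       k_inv_bounds = k_inv_bounds, k_inv_starts = k_inv_starts,
       shape = shape)
}

#' Fit one injection window as dilution plus dissolution
#'
#' Decomposes a baseline-corrected window into the slow dissolution component
#' and the fast dilution peak(s) by least squares. The dilution shape
#' constants are held at their calibrated values and only amplitudes vary;
#' the nonlinear parameters (`1/k` and `alpha`) are profiled by variable
#' projection (for fixed `1/k`, `alpha` all amplitudes are linear) with a
#' multi-start grid and best-RSS selection. An affine nuisance per window
#' absorbs what the global cubic baseline leaves behind locally; the model is
#' passed through the same peak-chord correction as the data.
#'
#' @param window a baseline-corrected [power_trace()] window.
#' @param c_before,c_after cell concentrations around this injection (mM).
#' @param schedule the [injection_schedule()].
#' @param config a [fit_config()].
#' @param shape named list of calibrated shape constants
#'   (`omega`, `delta`, and `w`, `delta_L` when needed).
#' @return An object of class `injection_fit`: estimates (`A`, `k_inv`,
#'   `alpha`, `B`, `C`), standard errors, component enthalpies (uJ and
#'   kJ/mol), `rss`, `converged`, and the window with fitted values.
#' @export
fit_injection <- function(window, c_before, c_after, schedule,
                          config = fit_config(), shape) {
  stopifnot(inherits(window, "power_trace"))
  ctx <- window_context(window, c_before, schedule, config, shape)
  y <- window$values
  tt <- window$times
  free <- character(0)
  lower <- upper <- numeric(0)
  starts <- list(numeric(0))
  if (ctx$include_dis) {
    free <- c("k_inv", "alpha")
    lower <- c(k_inv = ctx$k_inv_bounds[1], alpha = config$alpha_bounds[1])
    upper <- c(k_inv = ctx$k_inv_bounds[2], alpha = config$alpha_bounds[2])
    starts <- list()
    for (a in config$alpha_starts)
      for (ki in ctx$k_inv_starts)
        starts[[length(starts) + 1L]] <- c(k_inv = ki, alpha = a)
  }
  fit <- if (length(free)) {
    vp_fit(y, tt, ctx, free, starts, lower, upper)
  } else {
    sol <- vp_solve(y, tt, numeric(0), ctx)
    list(nonlin = numeric(0), beta = sol$beta, rss = sol$rss,
         fitted = sol$fitted, rank = sol$rank, X = sol$X, converged = TRUE)
  }
  idx <- window$annotations$injection
  if (is.null(idx)) idx <- NA_integer_
  if (is.null(fit) || !fit$converged) {
    return(structure(list(injection = idx, c_before = c_before,
                          c_after = c_after, converged = FALSE,
                          estimates = NULL, se = NULL, rss = NA_real_,
                          window = window),
                     class = "injection_fit"))
  }

  est <- c(fit$nonlin, fit$beta)
  res <- y - fit$fitted
  # standard errors over (nonlinear, linear) jointly
  all_par <- c(fit$nonlin, fit$beta)
  resid_fun <- function(p) {
    nl <- p[names(fit$nonlin)]
    X <- vp_design(tt, nl, ctx)
    Xc <- apply(X, 2, chord_correct, bounds = ctx$bounds)
    y - drop(Xc %*% p[colnames(fit$X)])
  }
  se <- tryCatch(ls_standard_errors(resid_fun, all_par, res),
                 error = function(e) rep(NA_real_, length(all_par)))
  names(se) <- names(all_par)

  enth <- integrate_component_enthalpies(est, ctx, schedule, tt)
  structure(list(injection = idx, c_before = c_before, c_after = c_after,
                 converged = TRUE, estimates = est, se = se,
                 rss = fit$rss, enthalpies = enth,
                 include_dis = ctx$include_dis,
                 include_lor = ctx$include_lor,
                 shape = ctx$shape,
                 fitted = fit$fitted, window = window),
            class = "injection_fit")
}

#' @export
print.injection_fit <- function(x, ...) {
  cat(sprintf("Injection %s fit (%s): c %.3g -> %.3g mM\n",
              x$injection, if (x$converged) "converged" else "NOT converged",
              x$c_before, x$c_after))
  if (x$converged) {
    if (x$include_dis)
      cat(sprintf("  dissolution: A = %.4g uJ/mM, 1/k = %.4g s, alpha = %.3g\n",
                  x$estimates[["A"]], x$estimates[["k_inv"]],
                  x$estimates[["alpha"]]))
    cat(sprintf("  enthalpies (uJ): dis %.4g, dil exo %.4g, dil endo %.4g; RSS %.4g\n",
                x$enthalpies["dis_uJ"], x$enthalpies["dil_exo_uJ"],
                x$enthalpies["dil_endo_uJ"], x$rss))
  }
  invisible(x)
}

#' Component enthalpies of a fitted injection
#'
#' The dissolution enthalpy uses the closed form `A * f_agg * dc0` (no
#' quadrature); the dilution enthalpies are trapezoidal quadratures of the
#' fitted shapes over the window. Molar values normalise by the moles of
#' dissolved peptide (`A / V_cell`) and, for reference, per mole injected
#' (`A * f_agg / V_cell`).
#'
#' @param est named estimate vector of an [fit_injection()] result (needs
#'   `A`, `k_inv`, `alpha`, `B`, optionally `C`).
#' @param ctx internal window context (aggregate fraction, step, shape).
#' @param schedule the [injection_schedule()].
#' @param tt window time grid (s).
#' @return Named numeric vector of enthalpies in uJ and kJ/mol.
#' @keywords internal
integrate_component_enthalpies <- function(est, ctx, schedule, tt) {
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  dis_uJ <- if (ctx$include_dis)
    est[["A"]] * ctx$f_agg * ctx$delta_c0 else 0
  hs <- est[["B"]] * unit_half_sine(tt, ctx$shape$omega, ctx$shape$delta)
  dil_exo_uJ <- trapz(tt, hs)
  dil_endo_uJ <- if (ctx$include_lor)
    trapz(tt, est[["C"]] * unit_lorentzian(tt, ctx$shape$w, ctx$shape$delta_L))
  else 0
  moles_dis_kJ <- if (ctx$include_dis)
    molar_enthalpy(est[["A"]], schedule$V_cell) else NA_real_
  moles_inj_kJ <- if (ctx$include_dis)
    molar_enthalpy(est[["A"]], schedule$V_cell, ctx$f_agg, per = "injected")
  else NA_real_
  c(dis_uJ = dis_uJ, dil_exo_uJ = dil_exo_uJ, dil_endo_uJ = dil_endo_uJ,
    dis_kJ_per_mol = moles_dis_kJ, dis_kJ_per_mol_injected = moles_inj_kJ)
}

#' Assemble per-injection fits into a results table
#'
#' Ordered table keyed by the post-injection concentration. Injections whose
#' fitted `1/k` exceeds a third of the injection spacing are flagged
#' unreliable: their dissolution is not complete before the next injection,
#' so the tail is truncated and the rate poorly determined.
#'
#' @param fits list of [fit_injection()] results.
#' @param spacing injection spacing (s) used for the reliability flag.
#' @return A data.frame with one row per injection.
#' @export
assemble_series <- function(fits, spacing) {
  if (length(fits) < 1L) stop("need at least one injection fit")
  rows <- lapply(fits, function(f) {
    has_dis <- f$converged && isTRUE(f$include_dis)
    k_inv <- if (has_dis) f$estimates[["k_inv"]] else NA_real_
    data.frame(
      injection = f$injection, c_before = f$c_before, c_after = f$c_after,
      enthalpy_dis_uJ = if (has_dis) f$enthalpies[["dis_uJ"]] else NA_real_,
      enthalpy_dis_kJ_per_mol = if (has_dis) f$enthalpies[["dis_kJ_per_mol"]] else NA_real_,
      enthalpy_dil_exo_uJ = if (f$converged) f$enthalpies[["dil_exo_uJ"]] else NA_real_,
      enthalpy_dil_endo_uJ = if (f$converged) f$enthalpies[["dil_endo_uJ"]] else NA_real_,
      k_inv = k_inv,
      alpha = if (has_dis) f$estimates[["alpha"]] else NA_real_,
      fit_rss = f$rss,
      converged = f$converged,
      unreliable = has_dis && !is.na(k_inv) && k_inv > spacing / 3)
  })
  out <- do.call(rbind, rows)
  out[order(out$c_after), , drop = FALSE]
}

#' Fit a whole dilution-quench titration series
#'
#' The main entry point: takes a raw differential-power trace and its
#' injection schedule, detects peak boundaries, corrects the baseline
#' (straight chords inside peaks, one global cubic outside), segments the
#' trace into per-injection windows, calibrates the dilution peak shape
#' constants on the first suitable window(s), fits every injection by
#' least squares and assembles the per-injection results table.
#'
#' @param trace a raw [power_trace()].
#' @param schedule an [injection_schedule()]; defaults to the one attached to
#'   the trace.
#' @param config a [fit_config()].
#' @return An object of class `dissolution_series_fit` with the results
#'   `table`, the per-injection `fits`, the `corrected` trace, the calibrated
#'   `shape` constants, the `schedule` and `config`. Supports `print()`,
#'   `summary()`, `coef()`, `plot()`, `predict()`, `fitted()` and
#'   `residuals()`.
#' @examples
#' sched <- injection_schedule(30, 10, 1460, spacing = 400, n_injections = 3)
#' sim <- simulate_experiment(sched, truth_params(),
#'                            noise_drift_spec(noise_sd = 0.05, seed = 7))
#' fit <- fit_dissolution_series(sim$trace)
#' coef(fit)
#' @export
fit_dissolution_series <- function(trace, schedule = NULL,
                                   config = fit_config()) {
  stopifnot(inherits(trace, "power_trace"))
  if (is.null(schedule)) schedule <- trace$schedule
  if (is.null(schedule)) stop("no injection schedule available")
  bounds <- detect_peak_bounds(trace, config$threshold, config$smooth_window,
                               onsets = injection_onsets(schedule))
  corrected <- correct_baseline(trace, bounds)
  windows <- segment_injections(corrected, schedule)
  conc <- cell_concentration_series(schedule)

  shape <- config$shape_constants
  if (is.null(shape)) {
    shape <- calibrate_dilution_shape(windows[[1L]], conc$c_before[1L],
                                      schedule, config)
    if (is.null(shape$w)) {
      above <- which(conc$c_before >= config$c_s_estimate)
      if (length(above)) {
        cal2 <- calibrate_dilution_shape(windows[[above[1L]]],
                                         conc$c_before[above[1L]],
                                         schedule, config)
        shape$w <- cal2$w; shape$delta_L <- cal2$delta_L
      }
    }
  }
  if (is.null(shape$w)) { shape$w <- 0.01; shape$delta_L <- schedule$t_inj / 2 }

  fits <- vector("list", schedule$n_injections)
  for (i in seq_len(schedule$n_injections)) {
    fits[[i]] <- fit_injection(windows[[i]], conc$c_before[i],
                               conc$c_after[i], schedule, config, shape)
  }
  table <- assemble_series(fits, schedule$spacing)
  structure(list(table = table, fits = fits, corrected = corrected,
                 shape = shape, schedule = schedule, config = config),
            class = "dissolution_series_fit")
}

#' @export
print.dissolution_series_fit <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Dilution-quench titration fit: %d injections (%d with dissolution, %d converged)\n",
              nrow(tab), sum(!is.na(tab$k_inv)), sum(tab$converged)))
  cat(sprintf("  concentrations %.3g -> %.3g mM; shape: omega = %.4g 1/s, delta = %.3g\n",
              min(tab$c_before), max(tab$c_after), x$shape$omega, x$shape$delta))
  ok <- !is.na(tab$k_inv) & !tab$unreliable
  if (any(ok))
    cat(sprintf("  reliable dissolution fits: 1/k in [%.3g, %.3g] s, molar dH in [%.3g, %.3g] kJ/mol\n",
                min(tab$k_inv[ok]), max(tab$k_inv[ok]),
                min(tab$enthalpy_dis_kJ_per_mol[ok]),
                max(tab$enthalpy_dis_kJ_per_mol[ok])))
  if (any(tab$unreliable))
    cat(sprintf("  %d injections flagged unreliable (1/k > spacing/3)\n",
                sum(tab$unreliable)))
  invisible(x)
}

#' @export
summary.dissolution_series_fit <- function(object, ...) {
  tab <- object$table
  ok <- !is.na(tab$k_inv) & !tab$unreliable & tab$converged
  out <- list(
    n_injections = nrow(tab),
    n_dissolution = sum(!is.na(tab$k_inv)),
    n_unreliable = sum(tab$unreliable),
    shape = object$shape,
    k_inv_low_c = if (any(ok)) tab$k_inv[ok][which.min(tab$c_before[ok])] else NA_real_,
    dH_dis_molar_low_c = if (any(ok))
      tab$enthalpy_dis_kJ_per_mol[ok][which.min(tab$c_before[ok])] else NA_real_,
    table = tab)
  class(out) <- "summary.dissolution_series_fit"
  out
}

#' @export
print.summary.dissolution_series_fit <- function(x, ...) {
  cat(sprintf("Titration series: %d injections, %d with a dissolution component, %d flagged unreliable\n",
              x$n_injections, x$n_dissolution, x$n_unreliable))
  cat(sprintf("  at the lowest concentration: 1/k = %.4g s, molar dH_dis = %.4g kJ/mol\n",
              x$k_inv_low_c, x$dH_dis_molar_low_c))
  print(utils::head(x$table[, c("injection", "c_after", "enthalpy_dis_kJ_per_mol",
                                "k_inv", "alpha", "unreliable")], 10))
  invisible(x)
}

#' @export
coef.dissolution_series_fit <- function(object, ...) {
  tab <- object$table
  m <- as.matrix(tab[, c("c_after", "enthalpy_dis_uJ", "enthalpy_dis_kJ_per_mol",
                         "k_inv", "alpha")])
  rownames(m) <- tab$injection
  m
}

#' @export
fitted.dissolution_series_fit <- function(object, ...) {
  lapply(object$fits, function(f) f$fitted)
}

#' @export
residuals.dissolution_series_fit <- function(object, ...) {
  lapply(object$fits, function(f)
    if (f$converged) f$window$values - f$fitted else f$window$values * NA_real_)
}

#' Model prediction for one fitted injection
#'
#' Evaluates the fitted decomposition of one injection window on an arbitrary
#' time grid (seconds since injection onset), without the chord correction or
#' the affine nuisance (i.e. the physical model components only), or the full
#' corrected-space prediction on the window grid.
#'
#' @param object a `dissolution_series_fit`.
#' @param injection injection index.
#' @param t time grid (s since onset); `NULL` uses the window grid.
#' @param components if `TRUE`, return a data.frame with per-component
#'   columns (`dissolution`, `dilution_exo`, `dilution_endo`) instead of the
#'   summed signal.
#' @param ... unused.
#' @return Numeric vector (or data.frame of components).
#' @export
predict.dissolution_series_fit <- function(object, injection = 1L, t = NULL,
                                           components = FALSE, ...) {
  f <- object$fits[[injection]]
  if (!f$converged) stop("injection ", injection, " did not converge")
  if (is.null(t)) t <- f$window$times
  est <- f$estimates
  dis <- if (f$include_dis)
    est[["A"]] * unit_dissolution(t, est[["k_inv"]], est[["alpha"]],
                                  object$config$k_inj,
                                  aggregate_fraction(object$schedule$c_inj,
                                                     object$config$c_s_estimate),
                                  step_concentration(object$schedule))
  else numeric(length(t))
  exo <- est[["B"]] * unit_half_sine(t, f$shape$omega, f$shape$delta)
  endo <- if (f$include_lor)
    est[["C"]] * unit_lorentzian(t, f$shape$w, f$shape$delta_L)
  else numeric(length(t))
  if (components)
    data.frame(t = t, dissolution = dis, dilution_exo = exo,
               dilution_endo = endo)
  else dis + exo + endo
}

#' @export
plot.dissolution_series_fit <- function(x, injections = NULL, ...) {
  tab <- x$table
  if (is.null(injections)) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    ok <- !is.na(tab$k_inv)
    graphics::plot(tab$c_after[ok], tab$enthalpy_dis_kJ_per_mol[ok],
                   pch = ifelse(tab$unreliable[ok], 1, 19),
                   xlab = "c after injection (mM)",
                   ylab = expression(Delta * H[dis] ~ (kJ / mol)), ...)
    graphics::abline(h = 0, lty = 3)
    graphics::plot(tab$c_after[ok], tab$k_inv[ok],
                   pch = ifelse(tab$unreliable[ok], 1, 19), log = "y",
                   xlab = "c after injection (mM)", ylab = expression(k^-1 ~ (s)))
  } else {
    op <- graphics::par(mfrow = c(length(injections), 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    for (i in injections) {
      f <- x$fits[[i]]
      graphics::plot(f$window$times, f$window$values, type = "l", col = "grey40",
                     xlab = "t since onset (s)",
                     ylab = expression(Delta * P ~ (mu * J / s)))
      if (f$converged)
        graphics::lines(f$window$times, f$fitted, col = "red3")
      graphics::legend("bottomright", bty = "n",
                       legend = sprintf("injection %d (c -> %.2f mM)",
                                        i, f$c_after))
    }
  }
  invisible(x)
}
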