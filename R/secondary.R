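#' Parameters of the reversible dissolution rate law
#'
#' @param k0_inv infinite-dilution inverse dissolution rate (s).
#' @param c_s monomer solubility (mM).
#' @return An object of class `rate_model_params`.
#' @export
rate_model_params <- function(k0_inv, c_s) {
  if (k0_inv <= 0) stop("'k0_inv' must be > 0 (s)")
  if (c_s <= 0) stop("'c_s' must be > 0 (mM)")
  structure(list(k0_inv = k0_inv, c_s = c_s), class = "rate_model_params")
}

#' Inverse dissolution rate versus concentration
#'
#' For a reversible process the net dissolution rate is the difference
#' between detachment and attachment rates, giving
#' `k^-1(c) = k0_inv * c_s / (c_s - c)`: it equals `k0_inv` at infinite
#' dilution and diverges as the cell approaches the solubility.
#'
#' @param c free monomer concentration (mM), `0 <= c < c_s`; vectorised.
#' @param params a [rate_model_params()] object.
#' @return Inverse rate `k^-1` (s).
#' @export
reversible_rate_inverse <- function(c, params) {
  stopifnot(inherits(params, "rate_model_params"))
  if (any(c < 0)) stop("'c' must be >= 0")
  if (any(c >= params$c_s))
    stop("rate law is only defined below the solubility (c < c_s)")
  params$k0_inv * params$c_s / (params$c_s - c)
}

#' Fit the reversible rate law to (c, k^-1) data
#'
#' Least-squares fit of `k^-1(c) = k0_inv * c_s / (c_s - c)` in `k^-1` space.
#' The model is linear in `1/k^-1 = (1 - c/c_s)/k0_inv`, which provides the
#' starting values (exact on noiseless data); a quasi-Newton refinement then
#' minimises the residual sum of squares of `k^-1` itself.
#'
#' @param c concentrations (mM).
#' @param k_inv observed inverse rates (s).
#' @return An object of class `rate_fit` with elements `k0_inv`, `c_s`,
#'   `fitted`, `residuals`, `rss`, `se` (standard errors from the
#'   least-squares covariance) and the data.
#' @export
fit_rate_model <- function(c, k_inv) {
  if (length(c) != length(k_inv)) stop("'c' and 'k_inv' lengths differ")
  if (length(unique(c)) < 3L)
    stop("need at least 3 points with distinct concentrations")
  if (any(k_inv <= 0)) stop("'k_inv' values must be > 0")
  # linearisation: 1/k_inv = a + b*c with a = 1/k0_inv, b = -1/(k0_inv*c_s)
  lf <- stats::lm(I(1 / k_inv) ~ c)
  a <- unname(stats::coef(lf)[1]); b <- unname(stats::coef(lf)[2])
  if (a <= 0 || b >= 0) {  # linearisation outside the physical region
    a <- 1 / max(k_inv[which.min(c)], 1e-6)
    b <- -a / (max(c) * 1.5)
  }
  start <- c(log_k0_inv = log(1 / a), log_c_s = log(-a / b))
  obj <- function(p) {
    k0 <- exp(p[1]); cs <- exp(p[2])
    if (cs <= max(c)) return(1e300)
    sum((k_inv - k0 * cs / (cs - c))^2)
  }
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  k0_inv <- unname(exp(opt$par[1])); c_s <- unname(exp(opt$par[2]))
  params <- rate_model_params(k0_inv, c_s)
  fitted <- reversible_rate_inverse(c, params)
  res <- k_inv - fitted
  se <- ls_standard_errors(function(p) {
    k_inv - exp(p[1]) * exp(p[2]) / (exp(p[2]) - c)
  }, opt$par, res)
  # delta method: se on log scale -> multiplicative scale
  se_nat <- c(k0_inv = unname(se[1]) * k0_inv, c_s = unname(se[2]) * c_s)
  structure(list(k0_inv = unname(k0_inv), c_s = unname(c_s),
                 fitted = fitted, residuals = res, rss = sum(res^2),
                 se = se_nat, data = data.frame(c = c, k_inv = k_inv),
                 convergence = opt$convergence),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("Reversible dissolution rate law  k^-1(c) = k0^-1 * c_s / (c_s - c)\n")
  cat(sprintf("  k0^-1 = %.4g s (se %.3g)\n", x$k0_inv, x$se["k0_inv"]))
  cat(sprintf("  c_s   = %.4g mM (se %.3g)\n", x$c_s, x$se["c_s"]))
  cat(sprintf("  RSS = %.4g s^2 over %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
coef.rate_fit <- function(object, ...) {
  c(k0_inv = object$k0_inv, c_s = object$c_s)
}

#' @export
predict.rate_fit <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$data$c else newdata$c
  reversible_rate_inverse(cc, rate_model_params(object$k0_inv, object$c_s))
}

#' Parameters for diffusion-limited dissolution of a spherical aggregate
#'
#' @param D monomer self-diffusion coefficient in the solvent (m^2/s).
#' @param v monomer molar volume (cm^3/mol).
#' @param R0 initial aggregate radius (nm).
#' @param c_s monomer solubility (mM).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(D, v, R0, c_s) {
  if (any(c(D, v, R0, c_s) <= 0)) stop("all diffusion parameters must be > 0")
  structure(list(D = D, v = v, R0 = R0, c_s = c_s), class = "diffusion_params")
}

#' Monomer molar volume from molecular weight and mass density
#'
#' `v = M / rho`, e.g. 829 g/mol at 1.5 g/cm^3 gives about 550 cm^3/mol.
#'
#' @param M molecular weight (g/mol).
#' @param rho mass density (g/cm^3).
#' @return Molar volume (cm^3/mol).
#' @export
molar_volume <- function(M, rho) {
  if (M <= 0 || rho <= 0) stop("'M' and 'rho' must be > 0")
  M / rho
}

#' Radius of a dissolving sphere under diffusion control
#'
#' At infinite dilution the radius of a diffusion-limited dissolving sphere
#' shrinks as `R(t) = sqrt(R0^2 - 2 D v c_s t)`; the product `v * c_s` is the
#' dimensionless equilibrium volume fraction. Inputs are converted to SI
#' internally (`v` cm^3/mol -> m^3/mol, `c_s` mM -> mol/m^3, `R0` nm -> m).
#'
#' @param t time (s), vectorised.
#' @param params a [diffusion_params()] object.
#' @param clamp if `TRUE`, return 0 beyond the dissolution time instead of
#'   raising a domain error.
#' @return Radius (nm).
#' @export
diffusion_limited_radius <- function(t, params, clamp = FALSE) {
  stopifnot(inherits(params, "diffusion_params"))
  if (any(t < 0)) stop("time 't' must be >= 0")
  R0_m <- params$R0 * 1e-9
  vc <- (params$v * 1e-6) * params$c_s        # (m^3/mol) * (mol/m^3), dimensionless
  rad2 <- R0_m^2 - 2 * params$D * vc * t
  if (any(rad2 < 0)) {
    if (!clamp)
      stop("time beyond the dissolution time: radius is zero from t = R0^2/(2 D v c_s); use clamp = TRUE for the clamped variant")
    rad2 <- pmax(rad2, 0)
  }
  sqrt(rad2) * 1e9
}

#' Diffusion-limited dissolution time of a spherical aggregate
#'
#' Time at which [diffusion_limited_radius()] reaches zero,
#' `t = R0^2 / (2 D v c_s)`, in seconds.
#'
#' @param params a [diffusion_params()] object.
#' @return Dissolution time (s).
#' @export
diffusion_limited_time <- function(params) {
  stopifnot(inherits(params, "diffusion_params"))
  R0_m <- params$R0 * 1e-9
  vc <- (params$v * 1e-6) * params$c_s
  R0_m^2 / (2 * params$D * vc)
}

#' Parameters of the partial-deprotonation pH model
#'
#' @param c_s monomer solubility (mM).
#' @param f fraction of peptides that deprotonate on joining an aggregate,
#'   in `(0, 1]`.
#' @param pH_solvent pH of the pure solvent, returned below the solubility.
#' @return An object of class `ph_model_params`.
#' @export
ph_model_params <- function(c_s, f, pH_solvent = 6.3) {
  if (c_s <= 0) stop("'c_s' must be > 0 (mM)")
  if (f <= 0 || f > 1) stop("deprotonation fraction 'f' must lie in (0, 1]")
  structure(list(c_s = c_s, f = f, pH_solvent = pH_solvent),
            class = "ph_model_params")
}

#' Solution pH versus peptide concentration
#'
#' Below the solubility the peptide behaves as a neutral salt and the pH is
#' that of the solvent. Above it, a fraction `f` of the aggregated peptides
#' (concentration `c - c_s`) each release one proton, so
#' `pH = -log10((c - c_s) * f)` with concentrations in mol/L.
#'
#' @param c total peptide concentration (mM), vectorised.
#' @param params a [ph_model_params()] object.
#' @return pH.
#' @export
ph_model <- function(c, params) {
  stopifnot(inherits(params, "ph_model_params"))
  if (any(c < 0)) stop("'c' must be >= 0 (mM)")
  out <- rep(params$pH_solvent, length(c))
  above <- c > params$c_s
  out[above] <- -log10((c[above] - params$c_s) * 1e-3 * params$f)
  out
}

#' Fit the deprotonation pH model to (c, pH) data
#'
#' Least-squares fit of `pH = -log10((c - c_s) * f)` (concentrations mol/L)
#' on the branch `c > c_s`. For a given `c_s` the optimal `log10(f)` is the
#' mean residual, so the fit profiles the 1-D likelihood over `c_s` and then
#' polishes both parameters jointly; `f` is constrained to `(0, 1]`.
#'
#' @param c concentrations (mM).
#' @param pH measured pH values.
#' @param pH_solvent solvent pH reported below the solubility.
#' @return An object of class `ph_fit` with elements `c_s`, `f`, `fitted`,
#'   `residuals`, `rss`, `n_used` (points on the `c > c_s` branch) and the data.
#' @export
fit_ph_deprotonation <- function(c, pH, pH_solvent = 6.3) {
  if (length(c) != length(pH)) stop("'c' and 'pH' lengths differ")
  if (sum(pH < pH_solvent - 0.5) < 3L)
    stop("need at least 3 points clearly below the solvent pH (candidates for c > c_s)")
  cs_max <- max(c) * (1 - 1e-9)
  # residuals over the whole table: solvent pH below c_s, Eq-model above;
  # log10(f) profiled out on the upper branch (f <= 1 enforced)
  full_rss <- function(cs) {
    use <- c > cs
    if (sum(use) < 3L) return(Inf)
    x <- -log10((c[use] - cs) * 1e-3)
    lf <- max(mean(pH[use] - x), 0)    # lf = -log10(f), f <= 1
    sum((pH[use] - (x + lf))^2) + sum((pH[!use] - pH_solvent)^2)
  }
  opt <- stats::optimize(full_rss, interval = c(0, cs_max * 0.999),
                         tol = 1e-10)
  cs0 <- opt$minimum
  use <- c > cs0
  x <- -log10((c[use] - cs0) * 1e-3)
  lf0 <- max(mean(pH[use] - x), 0)
  # joint polish on (c_s, -log10 f) at fixed branch membership
  obj <- function(p) {
    cs <- p[1]; lf <- p[2]
    if (cs <= 0 || cs >= min(c[use]) || lf < 0) return(1e300)
    sum((pH[use] + log10((c[use] - cs) * 1e-3) - lf)^2)
  }
  pol <- stats::optim(c(cs0, lf0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 2000))
  c_s <- pol$par[1]; f <- 10^(-max(pol$par[2], 0))
  params <- ph_model_params(c_s, f, pH_solvent)
  fitted <- ph_model(c, params)
  res <- pH - fitted
  structure(list(c_s = c_s, f = f, pH_solvent = pH_solvent,
                 fitted = fitted, residuals = res,
                 rss = sum(res[c > c_s]^2), n_used = sum(c > c_s),
                 data = data.frame(c = c, pH = pH)),
            class = "ph_fit")
}

#' @export
print.ph_fit <- function(x, ...) {
  cat("Partial-deprotonation pH model  pH = -log10((c - c_s) f)\n")
  cat(sprintf("  c_s = %.4g mM, f = %.3g (solvent pH %.3g below c_s)\n",
              x$c_s, x$f, x$pH_solvent))
  cat(sprintf("  RSS = %.4g over %d points above c_s\n", x$rss, x$n_used))
  invisible(x)
}

#' @export
coef.ph_fit <- function(object, ...) c(c_s = object$c_s, f = object$f)

#' @export
predict.ph_fit <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$data$c else newdata$c
  ph_model(cc, ph_model_params(object$c_s, object$f, object$pH_solvent))
}

# Standard errors from the least-squares covariance sigma^2 (J'J)^-1,
# with J the numerical Jacobian of the residual function at the optimum.
ls_standard_errors <- function(resid_fun, par, res) {
  n <- length(res); p <- length(par)
  if (n <= p) return(rep(NA_real_, p))
  J <- matrix(0, n, p)
  h <- pmax(abs(par), 1) * 1e-6
  for (j in seq_len(p)) {
    up <- par; up[j] <- up[j] + h[j]
    dn <- par; dn[j] <- dn[j] - h[j]
    J[, j] <- (resid_fun(up) - resid_fun(dn)) / (2 * h[j])
  }
  sigma2 <- sum(res^2) / (n - p)
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * sigma2, error = function(e) {
    # near-singular information: tiny ridge so an unidentifiable parameter
    # gets an honestly huge standard error instead of a failed covariance
    ridge <- max(diag(JtJ), 1e-300) * 1e-12
    solve(JtJ + diag(ridge, nrow(JtJ))) * sigma2
  })
  sqrt(pmax(diag(cov), 0))
}
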