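#' Default pipeline configuration
#'
#' Nested configuration for the simulate / fit / analyze pipeline, with
#' explicit units in every field name. Blocks: `schedule` (experiment
#' geometry), `generator` (synthetic truth, noise, drift, seed),
#' `preprocessing` (peak detection), `fitting` (decomposition constants and
#' bounds) and `analysis` (diffusion-reference and pH constants). Defaults
#' describe experiment A of the reference system: 27 x 10 uL injections of a
#' 30 mM peptide stock into a 1.46 mL cell of pure solvent, 30 s injections
#' spaced 1 h apart.
#'
#' @return A named list (class `pipeline_config`).
#' @export
default_config <- function() {
  structure(list(
    schedule = list(
      c_inj_mM = 30, V_inj_uL = 10, V_cell_uL = 1460,
      t_inj_s = 30, spacing_s = 3600, n_injections = 27L,
      c0_cell_mM = 0, null_injection = c(2, 4)),
    generator = list(
      c_s_mM = 5, k0_inv_s = 30, alpha_low = 10, dH_dis_kJ_per_mol = -1.4,
      dilution_B_uJ_per_s = -2, dilution_omega_per_s = pi / 30,
      dilution_delta = 0.2, lorentzian_C_uJ_per_s = 1.5,
      lorentzian_w_per_s2 = 0.01, lorentzian_delta_s = 15,
      noise_sd_uJ_per_s = 0.05, drift_coeffs = c(0.2, 0, 0, 0),
      seed = 1L, dt_s = 1),
    preprocessing = list(
      threshold_uJ_per_s2 = 2e-3, smooth_window_samples = 5L),
    fitting = list(
      k_inj_per_s = 1 / 15, c_s_estimate_mM = 5,
      include_dissolution = "auto",
      alpha_bounds = c(1, 20), k_inv_bounds_s = NULL,
      alpha_starts = c(1.5, 3, 10), k_inv_starts_s = NULL),
    analysis = list(
      D_m2_per_s = 2e-10, v_cm3_per_mol = 550, R0_nm = 100, c_s_mM = 5,
      pH_solvent = 6.3)),
    class = "pipeline_config")
}

# Recursively check a user config against the default schema: unknown keys
# are rejected with the full path, known keys override defaults.
merge_config <- function(user, defaults, path = character(0)) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(paste(c(path, unknown[1L]), collapse = "$"), collapse = ", "),
         "; known keys here: ", paste(names(defaults), collapse = ", "))
  out <- defaults
  for (k in names(user)) {
    out[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      merge_config(user[[k]], defaults[[k]], c(path, k))
    else user[[k]]
  }
  out
}

#' Read and validate a pipeline configuration
#'
#' Reads a JSON configuration file, checks every key against the schema of
#' [default_config()] (unknown keys are an error) and fills unspecified
#' fields with their defaults. `NULL` returns the defaults unchanged.
#'
#' @param path JSON file path, a named list, or `NULL`.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path = NULL) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) stop("malformed configuration JSON in ",
                                      path, ": ", conditionMessage(e)))
  } else path
  out <- merge_config(user, defaults)
  class(out) <- "pipeline_config"
  out
}

config_schedule <- function(config) {
  s <- config$schedule
  nj <- s$null_injection
  if (!is.null(nj) && (length(nj) == 0L || all(is.na(nj)))) nj <- NULL
  injection_schedule(c_inj = s$c_inj_mM, V_inj = s$V_inj_uL,
                     V_cell = s$V_cell_uL, t_inj = s$t_inj_s,
                     spacing = s$spacing_s, n_injections = s$n_injections,
                     c0_cell = s$c0_cell_mM, null_injection = nj)
}

config_truth <- function(config) {
  g <- config$generator
  truth_params(c_s = g$c_s_mM, k0_inv = g$k0_inv_s, alpha_low = g$alpha_low,
               dH_dis_molar = g$dH_dis_kJ_per_mol,
               dilution_B = g$dilution_B_uJ_per_s,
               dilution_omega = g$dilution_omega_per_s,
               dilution_delta = g$dilution_delta,
               lorentzian_C = g$lorentzian_C_uJ_per_s,
               lorentzian_w = g$lorentzian_w_per_s2,
               lorentzian_delta = g$lorentzian_delta_s)
}

config_fit <- function(config) {
  f <- config$fitting
  p <- config$preprocessing
  fit_config(k_inj = f$k_inj_per_s, c_s_estimate = f$c_s_estimate_mM,
             include_dissolution = f$include_dissolution,
             alpha_bounds = f$alpha_bounds, k_inv_bounds = f$k_inv_bounds_s,
             alpha_starts = f$alpha_starts, k_inv_starts = f$k_inv_starts_s,
             threshold = p$threshold_uJ_per_s2,
             smooth_window = p$smooth_window_samples)
}

run_log <- function(level, ...) {
  if (isTRUE(getOption("fibrildis.quiet"))) return(invisible(NULL))
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), sprintf(...)))
}

run_stamp <- function(config, seed) {
  list(package_version = pkg_version(),
       config_hash = fnv1a_hash(jsonlite::toJSON(unclass(config),
                                                 auto_unbox = TRUE)),
       seed = seed)
}

#' Simulate a synthetic experiment to disk
#'
#' Generates a complete synthetic titration experiment from the configuration
#' and writes `trace.csv` (+ `trace.csv.json` schedule sidecar) and
#' `truth.json` (per-injection ground truth) into `out_dir`.
#'
#' @param config a `pipeline_config`, a JSON path, or `NULL` for defaults.
#' @param out_dir output directory (created if missing).
#' @param seed overrides the generator seed when not `NULL`.
#' @return Invisibly, a list with `trace_path`, `truth_path` and the
#'   simulation result.
#' @export
run_simulate <- function(config = NULL, out_dir, seed = NULL) {
  config <- read_config(config)
  if (!is.null(seed)) config$generator$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- config_schedule(config)
  truth <- config_truth(config)
  g <- config$generator
  noise <- noise_drift_spec(noise_sd = g$noise_sd_uJ_per_s,
                            drift_coeffs = g$drift_coeffs, seed = g$seed)
  run_log("INFO", "simulate: %d injections, noise_sd = %g uJ/s, seed = %d",
          schedule$n_injections, noise$noise_sd, noise$seed)
  sim <- simulate_experiment(schedule, truth, noise, dt = g$dt_s)
  trace_path <- file.path(out_dir, "trace.csv")
  write_trace(sim$trace, trace_path)
  truth_records <- lapply(seq_len(nrow(sim$truth)), function(i) {
    r <- sim$truth[i, ]
    kin <- sim$truth$kinetics[[i]]
    list(injection = r$injection, c_before_mM = r$c_before,
         c_after_mM = r$c_after, onset_s = r$onset,
         enthalpy_dis_uJ = r$enthalpy_dis,
         enthalpy_dil_exo_uJ = r$enthalpy_dil_exo,
         enthalpy_dil_endo_uJ = r$enthalpy_dil_endo,
         kinetics = if (is.null(kin)) NULL else unclass(kin))
  })
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(stamp = run_stamp(config, g$seed),
                            injections = truth_records),
                       truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  run_log("INFO", "simulate: wrote %s and %s", trace_path, truth_path)
  invisible(list(trace_path = trace_path, truth_path = truth_path, sim = sim))
}

#' Fit a trace from disk and write the results table
#'
#' Runs preprocess, segmentation and per-injection decomposition on a trace
#' CSV (with its schedule sidecar) and writes `results.csv` (one row per
#' injection) plus `report.json` with the enthalpy-versus-concentration and
#' rate-versus-concentration summaries and the list of flagged injections.
#'
#' @param trace_path path to a CSV written by [write_trace()], or a
#'   [power_trace()] with an attached schedule.
#' @param config a `pipeline_config`, JSON path, or `NULL`.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with `results_path`, `report_path` and the
#'   `dissolution_series_fit`.
#' @export
run_fit <- function(trace_path, config = NULL, out_dir) {
  config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trace <- if (inherits(trace_path, "power_trace")) trace_path
           else read_trace(trace_path)
  if (is.null(trace$schedule))
    stop("trace has no injection schedule (missing sidecar?); cannot segment")
  run_log("INFO", "fit: %d samples, %d injections",
          length(trace$times), trace$schedule$n_injections)
  fit <- fit_dissolution_series(trace, config = config_fit(config))
  results_path <- file.path(out_dir, "results.csv")
  utils::write.csv(fit$table, results_path, row.names = FALSE)
  tab <- fit$table
  ok <- !is.na(tab$k_inv)
  report <- list(
    stamp = run_stamp(config, config$generator$seed),
    shape_constants = fit$shape,
    n_injections = nrow(tab),
    n_converged = sum(tab$converged),
    flagged_unreliable = tab$injection[tab$unreliable],
    enthalpy_vs_concentration = tab[ok, c("c_after", "enthalpy_dis_uJ",
                                          "enthalpy_dis_kJ_per_mol")],
    rate_vs_concentration = tab[ok, c("c_after", "k_inv", "alpha",
                                      "unreliable")])
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  run_log("INFO", "fit: wrote %s and %s (%d/%d converged)",
          results_path, report_path, sum(tab$converged), nrow(tab))
  invisible(list(results_path = results_path, report_path = report_path,
                 fit = fit))
}

#' Run a secondary analysis and write fitted parameters as JSON
#'
#' Dispatches on `what`: `"rate"` fits the reversible rate law to a
#' `(c_mM, k_inv_s)` table (or to the reliable rows of a `results.csv`),
#' `"ph"` fits the partial-deprotonation model to a `(c_mM, pH)` table, and
#' `"diffusion"` evaluates the diffusion-limited dissolution time from the
#' analysis constants (no table needed).
#'
#' @param input_path CSV path (ignored for `what = "diffusion"`).
#' @param config a `pipeline_config`, JSON path, or `NULL`.
#' @param what one of `"rate"`, `"ph"`, `"diffusion"`.
#' @param out_path output JSON path.
#' @return Invisibly, the parameter list written to `out_path`.
#' @export
run_analyze <- function(input_path = NULL, config = NULL,
                        what = c("rate", "ph", "diffusion"), out_path) {
  what <- match.arg(what)
  config <- read_config(config)
  an <- config$analysis
  out <- switch(what,
    rate = {
      df <- utils::read.csv(input_path)
      if (all(c("c_mM", "k_inv_s") %in% names(df))) {
        cc <- df$c_mM; ki <- df$k_inv_s
      } else if (all(c("c_after", "k_inv") %in% names(df))) {
        keep <- !is.na(df$k_inv) & !df$unreliable
        cc <- df$c_after[keep]; ki <- df$k_inv[keep]
      } else {
        stop("rate analysis expects columns (c_mM, k_inv_s) or a results.csv with (c_after, k_inv, unreliable)")
      }
      if (length(cc) == 0L) stop("rate analysis: no usable rows in ", input_path)
      fit <- fit_rate_model(cc, ki)
      list(model = "k_inv = k0_inv * c_s / (c_s - c)",
           k0_inv_s = fit$k0_inv, c_s_mM = fit$c_s,
           se_k0_inv_s = unname(fit$se["k0_inv"]),
           se_c_s_mM = unname(fit$se["c_s"]),
           rss = fit$rss, n = nrow(fit$data))
    },
    ph = {
      df <- utils::read.csv(input_path)
      if (!all(c("c_mM", "pH") %in% names(df)))
        stop("pH analysis expects columns (c_mM, pH)")
      if (nrow(df) == 0L) stop("pH analysis: empty table in ", input_path)
      fit <- fit_ph_deprotonation(df$c_mM, df$pH,
                                  pH_solvent = an$pH_solvent)
      list(model = "pH = -log10((c - c_s) * f), c > c_s",
           c_s_mM = fit$c_s, f = fit$f, pH_solvent = fit$pH_solvent,
           rss = fit$rss, n_above_cs = fit$n_used)
    },
    diffusion = {
      p <- diffusion_params(D = an$D_m2_per_s, v = an$v_cm3_per_mol,
                            R0 = an$R0_nm, c_s = an$c_s_mM)
      t_s <- diffusion_limited_time(p)
      list(model = "t = R0^2 / (2 D v c_s)",
           dissolution_time_s = t_s, dissolution_time_ms = 1e3 * t_s,
           D_m2_per_s = p$D, v_cm3_per_mol = p$v, R0_nm = p$R0,
           c_s_mM = p$c_s)
    })
  out <- c(list(stamp = run_stamp(config, config$generator$seed)), out)
  jsonlite::write_json(out, out_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  run_log("INFO", "analyze(%s): wrote %s", what, out_path)
  invisible(out)
}
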