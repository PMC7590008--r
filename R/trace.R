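#' Uniformly sampled differential-power trace
#'
#' Container for an ITC thermogram: strictly increasing, uniformly spaced
#' sample times (s) and differential power values (uJ/s), plus optional
#' annotations (injection schedule, peak bounds, injection windows) attached
#' by the generator and the preprocessing steps.
#'
#' @param times sample times (s), strictly increasing and uniform.
#' @param values differential power (uJ/s), same length as `times`.
#' @param schedule optional [injection_schedule()] the trace belongs to.
#' @param annotations optional named list of annotations.
#' @return An object of class `power_trace`.
#' @export
power_trace <- function(times, values, schedule = NULL, annotations = list()) {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length")
  if (length(times) >= 2L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("'times' must be strictly increasing")
    if (diff(range(dt)) > 1e-9 * max(abs(dt)))
      stop("'times' must be uniformly spaced (relative tolerance 1e-9)")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 schedule = schedule, annotations = annotations),
            class = "power_trace")
}

# Sampling interval (s) of a power_trace.
trace_dt <- function(trace) {
  stopifnot(inherits(trace, "power_trace"))
  if (length(trace$times) < 2L) stop("trace has fewer than 2 samples")
  trace$times[2L] - trace$times[1L]
}

#' @export
print.power_trace <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Power trace: %d samples, t = [%.4g, %.4g] s, dt = %.4g s\n",
              n, x$times[1L], x$times[n], if (n > 1) trace_dt(x) else NA_real_))
  cat(sprintf("  power range [%.4g, %.4g] uJ/s\n",
              min(x$values), max(x$values)))
  if (!is.null(x$schedule))
    cat(sprintf("  schedule attached: %d injections\n", x$schedule$n_injections))
  if (length(x$annotations))
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.power_trace <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l",
                 xlab = "time (s)", ylab = expression(Delta * P ~ (mu * J / s)),
                 ...)
  invisible(x)
}

#' Write a power trace to CSV with a JSON sidecar
#'
#' The trace samples go to `path` as a two-column CSV with header
#' `time_s,power_uJ_per_s`; the attached injection schedule (when present) is
#' written to `paste0(path, ".json")` so that a reader can re-segment the
#' trace without extra input.
#'
#' @param trace a [power_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "power_trace"))
  # %.17g guarantees exact binary round-trip of doubles
  lines <- c("time_s,power_uJ_per_s",
             sprintf("%.17g,%.17g", trace$times, trace$values))
  writeLines(lines, path)
  if (!is.null(trace$schedule)) {
    sc <- unclass(trace$schedule)
    jsonlite::write_json(sc, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a power trace written by [write_trace()]
#'
#' Reads the CSV samples and, when present, the JSON sidecar carrying the
#' injection schedule. A missing sidecar is not an error: the trace is
#' returned without a schedule and a warning is raised. A non-monotone or
#' non-uniform time column is a parse error naming the offending line.
#'
#' @param path CSV path written by [write_trace()].
#' @return A [power_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "power_uJ_per_s")
  if (!all(need %in% names(df)))
    stop("malformed trace CSV: expected columns ", paste(need, collapse = ", "))
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop(sprintf("malformed trace CSV: non-increasing time at line %d (data row %d)",
                 bad[1L] + 2L, bad[1L] + 1L))
  sidecar <- paste0(path, ".json")
  schedule <- NULL
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    schedule <- injection_schedule(
      c_inj = sc$c_inj, V_inj = sc$V_inj, V_cell = sc$V_cell,
      t_inj = sc$t_inj, spacing = sc$spacing, n_injections = sc$n_injections,
      c0_cell = sc$c0_cell,
      null_injection = if (is.null(sc$null_injection)) NULL else unlist(sc$null_injection))
  } else {
    warning("no schedule sidecar found next to ", path,
            "; trace returned without a schedule")
  }
  power_trace(df$time_s, df$power_uJ_per_s, schedule = schedule)
}
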