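# Moving-average smoothing with edge shrinkage (window must be odd).
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect peak boundaries by derivative thresholding
#'
#' Within each injection window, a peak starts where the absolute time
#' derivative of the (moving-average smoothed) differential power first
#' exceeds the threshold and ends where it does so for the last time. The
#' derivative is estimated by central differences. Windows in which the
#' derivative never crosses the threshold yield no peak.
#'
#' @param trace a [power_trace()].
#' @param threshold derivative threshold (uJ/s per s); default `2e-3`.
#' @param smooth_window moving-average window (samples) applied before
#'   differentiation; default 5.
#' @param onsets injection onset times (s). Defaults to the trace annotation
#'   (set by the generator) or, failing that, the attached schedule; if
#'   neither exists the whole trace is treated as a single window.
#' @return A data.frame with columns `window`, `start`, `end` (sample indices
#'   into the trace) and `start_s`, `end_s` (times); zero rows when no peak
#'   is found. Pairs are disjoint and ordered.
#' @export
detect_peak_bounds <- function(trace, threshold = 2e-3, smooth_window = 5L,
                               onsets = NULL) {
  stopifnot(inherits(trace, "power_trace"))
  if (threshold <= 0) stop("'threshold' must be > 0")
  if (is.null(onsets)) onsets <- trace$annotations$onsets
  if (is.null(onsets) && !is.null(trace$schedule))
    onsets <- injection_onsets(trace$schedule)
  if (is.null(onsets)) onsets <- trace$times[1L]

  sm <- moving_average(trace$values, smooth_window)
  dt <- trace_dt(trace)
  n <- length(sm)
  deriv <- numeric(n)
  deriv[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (2 * dt)
  deriv[1L] <- (sm[2L] - sm[1L]) / dt
  deriv[n] <- (sm[n] - sm[n - 1L]) / dt
  hot <- abs(deriv) > threshold

  edges <- c(onsets, trace$times[n] + dt)
  out <- data.frame(window = integer(0), start = integer(0), end = integer(0),
                    start_s = numeric(0), end_s = numeric(0))
  for (w in seq_along(onsets)) {
    in_win <- which(trace$times >= edges[w] & trace$times < edges[w + 1L])
    if (length(in_win) == 0L) next
    cross <- in_win[hot[in_win]]
    if (length(cross) == 0L) next
    s <- cross[1L]; e <- cross[length(cross)]
    out <- rbind(out, data.frame(window = w, start = s, end = e,
                                 start_s = trace$times[s],
                                 end_s = trace$times[e]))
  }
  out
}

#' Two-regime polynomial baseline correction
#'
#' Inside each detected peak interval the baseline is the first-degree
#' polynomial (straight line) joining the signal values at the peak start and
#' end; outside all peaks a single third-degree polynomial is fitted to every
#' non-peak sample and subtracted. This removes slow instrument drift without
#' disturbing the peak areas.
#'
#' @param trace a [power_trace()].
#' @param bounds peak bounds as returned by [detect_peak_bounds()]; computed
#'   from the trace when missing.
#' @param ... passed on to [detect_peak_bounds()] when `bounds` is `NULL`.
#' @return A corrected [power_trace()] carrying the bounds in
#'   `annotations$peak_bounds`.
#' @export
correct_baseline <- function(trace, bounds = NULL, ...) {
  stopifnot(inherits(trace, "power_trace"))
  if (is.null(bounds)) bounds <- detect_peak_bounds(trace, ...)
  n <- length(trace$values)
  in_peak <- rep(FALSE, n)
  if (nrow(bounds)) {
    if (any(bounds$start < 1L) || any(bounds$end > n))
      stop("peak bounds fall outside the trace")
    for (i in seq_len(nrow(bounds)))
      in_peak[bounds$start[i]:bounds$end[i]] <- TRUE
  }
  t <- trace$times
  # the lead-in before the first analysed injection holds the null-injection
  # blip; keep it out of the cubic fit's support so it cannot bend the
  # baseline (the correction is still applied there)
  support <- !in_peak
  if (!is.null(trace$schedule) && !is.null(trace$schedule$null_injection)) {
    first_onset <- injection_onsets(trace$schedule)[1L]
    blip_end <- min(3 * trace$schedule$t_inj, first_onset)
    if (sum(support & t >= blip_end) >= 4L)
      support <- support & t >= blip_end
  }
  if (sum(support) < 4L)
    stop("peaks cover (almost) the entire trace: no baseline support left")

  ts <- (t - mean(t)) / max(stats::sd(t), 1)   # scaled for conditioning
  fit <- stats::lm(y ~ ts + I(ts^2) + I(ts^3),
                   data = data.frame(y = trace$values, ts = ts),
                   subset = support)
  base <- numeric(n)
  base[!in_peak] <- stats::predict(fit, newdata = data.frame(ts = ts))[!in_peak]
  if (nrow(bounds)) {
    for (i in seq_len(nrow(bounds))) {
      s <- bounds$start[i]; e <- bounds$end[i]
      if (e > s) {
        base[s:e] <- trace$values[s] +
          (trace$values[e] - trace$values[s]) * (t[s:e] - t[s]) / (t[e] - t[s])
      } else {
        base[s] <- trace$values[s]
      }
    }
  }
  ann <- trace$annotations
  ann$peak_bounds <- bounds
  ann$baseline <- base
  power_trace(t, trace$values - base, schedule = trace$schedule,
              annotations = ann)
}

#' Split a trace into per-injection windows
#'
#' One window per analysed injection, starting at its onset and ending just
#' before the next onset (the last window runs to the end of the trace). The
#' null injection, which precedes the first onset, is excluded. Window times
#' are re-referenced to the injection onset (`t = 0` at onset); peak-bound
#' annotations are carried over with window-relative indices.
#'
#' @param trace a [power_trace()] (typically baseline-corrected).
#' @param schedule an [injection_schedule()]; defaults to the one attached to
#'   the trace.
#' @return A list of [power_trace()] windows, one per injection, each with
#'   `annotations$onset` (absolute onset time) and `annotations$injection`.
#' @export
segment_injections <- function(trace, schedule = NULL) {
  stopifnot(inherits(trace, "power_trace"))
  if (is.null(schedule)) schedule <- trace$schedule
  if (is.null(schedule))
    stop("no injection schedule available (pass one or attach it to the trace)")
  onsets <- injection_onsets(schedule)
  n_t <- length(trace$times)
  if (trace$times[n_t] < onsets[length(onsets)])
    stop(sprintf("trace ends at %.4g s but the schedule has %d injections, the last at %.4g s",
                 trace$times[n_t], schedule$n_injections, onsets[length(onsets)]))
  edges <- c(onsets, trace$times[n_t] + trace_dt(trace))
  bounds <- trace$annotations$peak_bounds
  out <- vector("list", schedule$n_injections)
  for (i in seq_len(schedule$n_injections)) {
    idx <- which(trace$times >= edges[i] & trace$times < edges[i + 1L])
    ann <- list(onset = onsets[i], injection = i)
    if (!is.null(bounds)) {
      b <- bounds[bounds$start >= idx[1L] & bounds$end <= idx[length(idx)], ,
                  drop = FALSE]
      if (nrow(b)) {
        b$start <- b$start - idx[1L] + 1L
        b$end <- b$end - idx[1L] + 1L
        b$start_s <- b$start_s - onsets[i]
        b$end_s <- b$end_s - onsets[i]
      }
      ann$peak_bounds <- b
    }
    out[[i]] <- power_trace(trace$times[idx] - onsets[i], trace$values[idx],
                            schedule = schedule, annotations = ann)
  }
  out
}

#' Write peak bounds as a BED-like text file
#'
#' Three tab-separated columns — window index, peak start time (s), peak end
#' time (s) — for quick inspection of the detected boundaries.
#'
#' @param bounds data.frame from [detect_peak_bounds()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_bounds <- function(bounds, path) {
  utils::write.table(bounds[, c("window", "start_s", "end_s")], path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
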