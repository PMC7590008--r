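#' Define the geometry and timing of a titration experiment
#'
#' An injection schedule captures everything the instrument controls: syringe
#' concentration, per-injection volume, cell volume, injection duration, the
#' waiting time between injections, the number of injections and the peptide
#' concentration already in the cell. An optional small null injection
#' (instrument practice before the first real injection) can be declared; it is
#' excluded from all analyses.
#'
#' @param c_inj syringe peptide concentration (mM).
#' @param V_inj injected volume per injection (uL).
#' @param V_cell cell volume (uL), constant throughout the experiment.
#' @param t_inj injection duration (s).
#' @param spacing waiting time between consecutive injection onsets (s).
#' @param n_injections number of analysed injections.
#' @param c0_cell peptide concentration in the cell before the first injection
#'   (mM); 0 for a pure-solvent cell.
#' @param null_injection `NULL`, or `c(volume_uL, duration_s)` describing a
#'   null injection performed at time 0 and excluded from analysis.
#'
#' @return An object of class `injection_schedule`.
#' @examples
#' sched <- injection_schedule(c_inj = 30, V_inj = 10, V_cell = 1460)
#' step_concentration(sched)
#' @export
injection_schedule <- function(c_inj, V_inj, V_cell,
                               t_inj = 30, spacing = 3600, n_injections = 27,
                               c0_cell = 0, null_injection = c(2, 4)) {
  stopifnot(is.numeric(c_inj), length(c_inj) == 1L,
            is.numeric(V_inj), length(V_inj) == 1L,
            is.numeric(V_cell), length(V_cell) == 1L)
  if (c_inj < 0) stop("syringe concentration 'c_inj' must be >= 0 (mM)")
  if (V_inj <= 0 || V_cell <= 0) stop("volumes 'V_inj' and 'V_cell' must be > 0 (uL)")
  if (V_inj >= V_cell) stop("'V_inj' must be smaller than the cell volume 'V_cell'")
  if (t_inj <= 0 || spacing <= 0) stop("'t_inj' and 'spacing' must be > 0 (s)")
  if (spacing <= t_inj) stop("'spacing' must exceed the injection duration 't_inj'")
  if (n_injections < 1) stop("'n_injections' must be >= 1")
  if (c0_cell < 0) stop("'c0_cell' must be >= 0 (mM)")
  if (!is.null(null_injection)) {
    if (length(null_injection) != 2L || any(null_injection <= 0))
      stop("'null_injection' must be NULL or c(volume_uL, duration_s), both > 0")
  }
  structure(list(c_inj = c_inj, V_inj = V_inj, V_cell = V_cell,
                 t_inj = t_inj, spacing = spacing,
                 n_injections = as.integer(n_injections),
                 c0_cell = c0_cell, null_injection = null_injection),
            class = "injection_schedule")
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat("Injection schedule:\n")
  cat(sprintf("  %d x %.3g uL injections of %.3g mM into %.4g uL cell (c0 = %.3g mM)\n",
              x$n_injections, x$V_inj, x$c_inj, x$V_cell, x$c0_cell))
  cat(sprintf("  injection time %.3g s, spacing %.4g s, step dc0 = %.4g mM\n",
              x$t_inj, x$spacing, step_concentration(x)))
  if (!is.null(x$null_injection))
    cat(sprintf("  null injection: %.3g uL over %.3g s (excluded from analysis)\n",
                x$null_injection[1], x$null_injection[2]))
  invisible(x)
}

#' Concentration step per injection
#'
#' The increase of the total peptide concentration in the cell caused by one
#' injection, `dc0 = c_inj * V_inj / V_cell`, under the additive bookkeeping
#' used throughout (the cell volume is treated as constant).
#'
#' @param schedule an [injection_schedule()].
#' @return Concentration step (mM).
#' @export
step_concentration <- function(schedule) {
  stopifnot(inherits(schedule, "injection_schedule"))
  schedule$c_inj * schedule$V_inj / schedule$V_cell
}

#' Fraction of injected peptide residing in aggregates
#'
#' In the syringe the free monomer concentration equals the solubility `c_s`,
#' so of the injected peptide a fraction `f_agg = 1 - c_s / c_inj` arrives as
#' aggregates.
#'
#' @param c_inj syringe concentration (mM).
#' @param c_s monomer solubility (mM), `0 <= c_s <= c_inj`.
#' @return Aggregate fraction in `[0, 1]`.
#' @export
aggregate_fraction <- function(c_inj, c_s) {
  if (c_inj <= 0) stop("'c_inj' must be > 0")
  if (c_s < 0 || c_s > c_inj)
    stop("solubility 'c_s' must satisfy 0 <= c_s <= c_inj")
  1 - c_s / c_inj
}

#' Cell concentration before and after each injection
#'
#' Additive bookkeeping: after injection `n` the total cell concentration is
#' `c0_cell + n * dc0`. An optional displacement correction additionally
#' dilutes the existing cell contents by `V_inj / V_cell` at every injection
#' (overflow-cell geometry); it is off by default because the plain additive
#' model reproduces the instrument's printed concentration readouts.
#'
#' @param schedule an [injection_schedule()].
#' @param displacement if `TRUE`, apply the overflow-displacement correction.
#' @return A data.frame with columns `injection`, `c_before`, `c_after` (mM).
#' @export
cell_concentration_series <- function(schedule, displacement = FALSE) {
  stopifnot(inherits(schedule, "injection_schedule"))
  n <- schedule$n_injections
  dc0 <- step_concentration(schedule)
  if (!displacement) {
    c_after <- schedule$c0_cell + seq_len(n) * dc0
    c_before <- c(schedule$c0_cell, c_after[-n])
  } else {
    keep <- 1 - schedule$V_inj / schedule$V_cell
    c_before <- c_after <- numeric(n)
    cc <- schedule$c0_cell
    for (i in seq_len(n)) {
      c_before[i] <- cc
      cc <- cc * keep + dc0
      c_after[i] <- cc
    }
  }
  data.frame(injection = seq_len(n), c_before = c_before, c_after = c_after)
}

#' First injection at which the cell reaches a concentration
#'
#' Smallest injection index `n` whose post-injection concentration satisfies
#' `c_after(n) >= c_s`. Returns 0 when the cell already starts at or above
#' `c_s`, and `NA_integer_` when the schedule never reaches it.
#'
#' @param schedule an [injection_schedule()].
#' @param c_s target concentration (mM), typically the monomer solubility.
#' @return Integer injection index, 0, or `NA_integer_`.
#' @export
first_injection_reaching <- function(schedule, c_s) {
  stopifnot(inherits(schedule, "injection_schedule"), is.numeric(c_s))
  if (schedule$c0_cell >= c_s) return(0L)
  ser <- cell_concentration_series(schedule)
  hit <- which(ser$c_after >= c_s)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

# Onset time (s) of each analysed injection on the simulated timeline.
# The null injection (if any) sits at t = 0 and injection i starts at
# i * spacing, so every analysed window has the full spacing available.
injection_onsets <- function(schedule) {
  first <- if (is.null(schedule$null_injection)) 0 else schedule$spacing
  first + (seq_len(schedule$n_injections) - 1L) * schedule$spacing
}
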