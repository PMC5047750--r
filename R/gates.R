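#' Classify gate logic from deletion-strain expression means
#'
#' Reads the population logic off the deletion panel: with
#' `f2 = msn2d_mean / wt_mean` (expression with Msn4 only) and
#' `f4 = msn4d_mean / wt_mean` (Msn2 only), the promoter is an `OR`
#' gate if either factor alone sustains at least `high_cut` of the WT
#' response, an `AND` gate if neither deletion reaches `low_cut`,
#' `MSN2_REQUIRED` if losing Msn2 abolishes expression while losing
#' Msn4 is tolerated (`f2 < low_cut`, `f4 >= high_cut`), symmetrically
#' `MSN4_REQUIRED`, and `NONE` otherwise (including a non-induced WT).
#' The call is invariant to rescaling all three means by a common
#' positive factor.
#'
#' @param wt_mean,msn2d_mean,msn4d_mean Mean expression of the
#'   wild-type and deletion strains, a.u. (non-negative).
#' @param low_cut,high_cut Fraction-of-WT cutoffs.
#' @return Object of class `gate_call` with the label, the input means
#'   and the WT fractions.
#' @examples
#' classify_gate(1.0, 0.9, 0.95)$label   # OR
#' classify_gate(1.0, 0.05, 0.08)$label  # AND
#' classify_gate(1.0, 0.05, 0.8)$label   # MSN2_REQUIRED
#' @export
classify_gate <- function(wt_mean, msn2d_mean, msn4d_mean,
                          low_cut = 0.25, high_cut = 0.5) {
  if (any(c(wt_mean, msn2d_mean, msn4d_mean) < 0))
    stop("expression means must be non-negative")
  if (low_cut > high_cut) stop("'low_cut' must be <= 'high_cut'")
  if (wt_mean <= 0) {
    label <- "NONE"; f2 <- f4 <- NA_real_
  } else {
    f2 <- msn2d_mean / wt_mean
    f4 <- msn4d_mean / wt_mean
    label <- if (min(f2, f4) >= high_cut) "OR"
    else if (max(f2, f4) < low_cut) "AND"
    else if (f2 < low_cut && f4 >= high_cut) "MSN2_REQUIRED"
    else if (f4 < low_cut && f2 >= high_cut) "MSN4_REQUIRED"
    else "NONE"
  }
  structure(list(label = label, wt_mean = wt_mean,
                 msn2d_mean = msn2d_mean, msn4d_mean = msn4d_mean,
                 frac_msn2d = f2, frac_msn4d = f4,
                 low_cut = low_cut, high_cut = high_cut),
            class = "gate_call")
}

#' @export
print.gate_call <- function(x, ...) {
  cat(sprintf("<gate_call> %s (msn2d/WT = %.3g, msn4d/WT = %.3g; cuts %g/%g)\n",
              x$label, x$frac_msn2d, x$frac_msn4d, x$low_cut, x$high_cut))
  invisible(x)
}

mean_endpoint <- function(experiment) {
  # measurement noise can push an uninduced population mean slightly
  # below zero; the classifier sees expression, so floor at 0
  max(0, mean(experiment$reporter[, ncol(experiment$reporter)]))
}

#' Gate calls across input durations
#'
#' Applies [classify_gate()] to matched WT/msn2d/msn4d experiments at
#' each input duration, exposing how the population logic of a promoter
#' moves from Msn4-dependent (AND) toward Msn4-independent as the input
#' is prolonged. Note the distinction kept here: at long durations the
#' slow promoter still requires Msn2, so the call is `MSN2_REQUIRED`
#' rather than a symmetric `OR`.
#'
#' @param experiments_by_duration Named list (names = durations in
#'   minutes); each element a list with components `WT`, `msn2d`,
#'   `msn4d` (each a `cell_experiment`), optionally `msn2d_msn4d`.
#' @param low_cut,high_cut Cutoffs passed to [classify_gate()].
#' @return Data frame with one row per duration: `duration_min`,
#'   `label`, `wt_mean`, `msn2d_mean`, `msn4d_mean`, `frac_msn2d`,
#'   `frac_msn4d`.
#' @export
gate_vs_duration <- function(experiments_by_duration, low_cut = 0.25,
                             high_cut = 0.5) {
  rows <- lapply(names(experiments_by_duration), function(d) {
    ex <- experiments_by_duration[[d]]
    for (g in c("WT", "msn2d", "msn4d"))
      if (is.null(ex[[g]]))
        stop("missing genotype '", g, "' for duration ", d)
    gc <- classify_gate(mean_endpoint(ex$WT), mean_endpoint(ex$msn2d),
                        mean_endpoint(ex$msn4d), low_cut, high_cut)
    data.frame(duration_min = as.numeric(d), label = gc$label,
               wt_mean = gc$wt_mean, msn2d_mean = gc$msn2d_mean,
               msn4d_mean = gc$msn4d_mean, frac_msn2d = gc$frac_msn2d,
               frac_msn4d = gc$frac_msn4d, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

half_rise_time <- function(trace, time_min) {
  r0 <- trace[1L]
  rise <- trace[length(trace)] - r0
  if (rise <= 0) return(NA_real_)
  first_crossing(time_min, trace, r0 + rise / 2)
}

#' Ratio of slow-to-fast promoter activation timescales
#'
#' Per experiment, the activation timescale is the median over induced
#' cells of the delay from stimulus onset to the reporter's
#' half-of-final-rise time, minus the maturation delay. Returns the
#' slow/fast ratio of these timescales. Both experiments must share the
#' stimulus program.
#'
#' @param fast_experiment,slow_experiment `cell_experiment`s (WT,
#'   matching stimulus) for the fast and slow promoter classes.
#' @param min_rise Minimal endpoint rise (a.u.) for a cell to count as
#'   induced; cells below it are excluded from the median.
#' @return List with `ratio`, `timescale_fast_min`,
#'   `timescale_slow_min`, and the per-class induced-cell counts.
#' @export
estimate_kinetic_ratio <- function(fast_experiment, slow_experiment,
                                   min_rise = 1) {
  one <- function(ex) {
    stopifnot(inherits(ex, "cell_experiment"))
    tm <- ex$time_min
    onset <- ex$meta$stim$onset_min
    mat <- ex$meta$prom$maturation_delay_min
    th <- apply(ex$reporter, 1L, function(tr) {
      if (tr[length(tr)] - tr[1L] < min_rise) return(NA_real_)
      half_rise_time(tr, tm)
    })
    th <- th[!is.na(th)]
    if (!length(th))
      stop("non-induced population: no cell rises by 'min_rise'")
    list(timescale = stats::median(th) - onset - mat, n = length(th))
  }
  sf <- format(fast_experiment$meta$stim)
  ss <- format(slow_experiment$meta$stim)
  if (!identical(sf, ss))
    stop("experiments must share the stimulus program (", sf, " vs ", ss, ")")
  f <- one(fast_experiment); s <- one(slow_experiment)
  list(ratio = s$timescale / f$timescale,
       timescale_fast_min = f$timescale,
       timescale_slow_min = s$timescale,
       n_induced_fast = f$n, n_induced_slow = s$n)
}
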