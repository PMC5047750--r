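#' Define a stimulus program
#'
#' A stimulus program describes the input that drives Msn2/Msn4 nuclear
#' translocation: a square inhibitor pulse, an adapting ("KCl-like")
#' response to a sustained stressor, or a sustained ("ethanol-like")
#' response. The program also fixes the sampling grid of the experiment:
#' a closed, uniform grid `seq(0, total_min, by = sample_interval_min)`,
#' 2-min cadence over 3 h by default.
#'
#' @param kind One of `"pulse"`, `"adaptive_transient"`, `"sustained"`.
#'   `pulse` holds the input at `dose` for `duration_min` minutes from
#'   `onset_min`; `sustained` holds it indefinitely; `adaptive_transient`
#'   applies a sustained stressor to which the TF response adapts with
#'   timescale `tau_adapt_min`, yielding a transient translocation pulse
#'   (roughly 30 min wide at the default 15-min adaptation timescale).
#' @param dose Dimensionless input strength in `[0, 1]`, scaling the
#'   cell-specific translocation amplitude.
#' @param onset_min Stimulus onset, minutes (>= 0).
#' @param duration_min Pulse duration, minutes; required positive for
#'   `kind = "pulse"` and ignored otherwise.
#' @param total_min Length of the sampled experiment, minutes.
#' @param sample_interval_min Sampling cadence, minutes.
#' @param tau_adapt_min Adaptation timescale for `adaptive_transient`,
#'   minutes.
#' @return An object of class `stimulus_program`.
#' @examples
#' stim <- stimulus_program("pulse", dose = 1, duration_min = 30)
#' stim_times(stim)[1:5]
#' @export
stimulus_program <- function(kind = c("pulse", "adaptive_transient", "sustained"),
                             dose = 1,
                             onset_min = 0,
                             duration_min = 30,
                             total_min = 180,
                             sample_interval_min = 2,
                             tau_adapt_min = 15) {
  kind <- match.arg(kind)
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) ||
      dose < 0 || dose > 1)
    stop("'dose' must be a single number in [0, 1]")
  if (onset_min < 0) stop("'onset_min' must be >= 0")
  if (total_min <= 0 || sample_interval_min <= 0)
    stop("'total_min' and 'sample_interval_min' must be positive")
  if (kind == "pulse") {
    if (!is.numeric(duration_min) || duration_min <= 0)
      stop("'duration_min' must be > 0 for a pulse stimulus")
    if (total_min < onset_min + duration_min)
      stop("'total_min' must cover onset_min + duration_min for a pulse")
  }
  if (kind == "adaptive_transient" && tau_adapt_min <= 0)
    stop("'tau_adapt_min' must be positive")
  structure(
    list(kind = kind, dose = dose, onset_min = onset_min,
         duration_min = if (kind == "pulse") duration_min else NA_real_,
         total_min = total_min,
         sample_interval_min = sample_interval_min,
         tau_adapt_min = tau_adapt_min),
    class = "stimulus_program")
}

#' Sampling grid of a stimulus program
#'
#' @param stim A [stimulus_program()].
#' @return Numeric vector of sample times in minutes (closed interval).
#' @export
stim_times <- function(stim) {
  stopifnot(inherits(stim, "stimulus_program"))
  seq(0, stim$total_min, by = stim$sample_interval_min)
}

#' Evaluate the normalized input drive of a stimulus
#'
#' Returns u(t) in `[0, 1]`: the fraction of the cell-specific maximal
#' translocation amplitude that the input commands at each time. For
#' `adaptive_transient` the drive decays exponentially from `dose` with
#' the adaptation timescale despite the stressor staying on.
#'
#' @param stim A [stimulus_program()].
#' @param t Numeric vector of times, minutes.
#' @param lag_min Extra onset lag in minutes (used for the delayed Msn4
#'   response); default 0.
#' @return Numeric vector, same length as `t`.
#' @export
stimulus_drive <- function(stim, t, lag_min = 0) {
  stopifnot(inherits(stim, "stimulus_program"))
  s <- t - stim$onset_min - lag_min
  u <- numeric(length(t))
  on <- s >= 0
  if (stim$kind == "pulse") {
    u[on & s < stim$duration_min] <- stim$dose
  } else if (stim$kind == "sustained") {
    u[on] <- stim$dose
  } else {
    u[on] <- stim$dose * exp(-s[on] / stim$tau_adapt_min)
  }
  u
}

#' @export
print.stimulus_program <- function(x, ...) {
  dur <- if (x$kind == "pulse") sprintf(", %g min", x$duration_min) else ""
  cat(sprintf("<stimulus_program> %s (dose %g%s), onset %g min, %g min sampled every %g min\n",
              x$kind, x$dose, dur, x$onset_min, x$total_min,
              x$sample_interval_min))
  invisible(x)
}

#' @export
format.stimulus_program <- function(x, ...) {
  if (x$kind == "pulse")
    sprintf("pulse%gmin_d%g", x$duration_min, x$dose)
  else sprintf("%s_d%g", x$kind, x$dose)
}
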