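#' Cross-channel scaling factor from paired calibration ensembles
#'
#' Computes the factor that puts channel-A fluorescence on the
#' channel-B scale, as done for the RFP-to-YFP calibration: the same
#' trace shape is recorded through both channels in two strains, the
#' single-cell traces are averaged per ensemble, and the factor is the
#' ratio of the maximal intensities of the two averaged traces.
#' Multiplying channel-A values by the factor yields "normalized a.u.".
#'
#' @param ensemble_A,ensemble_B `cells x time` matrices sampled on the
#'   same grid.
#' @return An object of class `channel_scaling` with fields `factor` and
#'   `source`.
#' @examples
#' A <- matrix(rep(c(0, 50, 100, 50), each = 3), nrow = 3)
#' compute_scaling_factor(A, A * 1.52)$factor
#' @export
compute_scaling_factor <- function(ensemble_A, ensemble_B) {
  ensemble_A <- as.matrix(ensemble_A); ensemble_B <- as.matrix(ensemble_B)
  if (ncol(ensemble_A) != ncol(ensemble_B))
    stop("ensembles must share the sampling grid")
  mA <- max(colMeans(ensemble_A)); mB <- max(colMeans(ensemble_B))
  if (!is.finite(mA) || !is.finite(mB) || mA <= 0 || mB <= 0)
    stop("averaged traces must have positive maxima")
  structure(list(factor = mB / mA,
                 source = sprintf("ratio of averaged-trace maxima (n=%d vs n=%d cells)",
                                  nrow(ensemble_A), nrow(ensemble_B))),
            class = "channel_scaling")
}

#' @export
print.channel_scaling <- function(x, ...) {
  cat(sprintf("<channel_scaling> factor %.4g (%s)\n", x$factor, x$source))
  invisible(x)
}

#' Apply (or invert) a channel scaling
#' @param scaling A `channel_scaling`.
#' @param values Numeric values on the channel-A scale.
#' @param inverse If `TRUE`, map normalized values back to channel A.
#' @return Scaled values.
#' @export
apply_scaling <- function(scaling, values, inverse = FALSE) {
  stopifnot(inherits(scaling, "channel_scaling"))
  if (inverse) values / scaling$factor else values * scaling$factor
}

window_index <- function(time_min, window_min) {
  if (length(window_min) != 2L || window_min[2L] < window_min[1L])
    stop("'window_min' must be c(lo, hi) with hi >= lo")
  idx <- which(time_min >= window_min[1L] & time_min <= window_min[2L])
  if (!length(idx)) stop("window does not overlap the sampling grid")
  idx
}

#' Peak level of a trace within a time window
#'
#' The maximal sample value within the closed window, the statistic used
#' for "peak nuclear translocation" (maximal value in the first 30 min
#' by default).
#'
#' @param trace Numeric vector of samples.
#' @param time_min Sample times, minutes.
#' @param window_min Closed window `c(lo, hi)`, minutes.
#' @return Maximum in-window sample.
#' @export
peak_level <- function(trace, time_min, window_min = c(0, 30)) {
  max(trace[window_index(time_min, window_min)])
}

#' Area under the curve as a plain sample sum
#'
#' The AUC convention for 2-min sampled traces: the sum of the in-window
#' samples, with no trapezoid weighting.
#'
#' @inheritParams peak_level
#' @return Sum of in-window samples (a.u. x samples).
#' @export
auc <- function(trace, time_min, window_min = range(time_min)) {
  sum(trace[window_index(time_min, window_min)])
}

first_crossing <- function(time_min, trace, level, from = -Inf,
                           downward = FALSE) {
  y <- if (downward) level - trace else trace - level
  ok <- time_min >= from
  for (i in which(ok)) {
    if (y[i] >= 0) {
      if (i == 1L || !ok[i - 1L] || y[i - 1L] >= 0) return(time_min[i])
      # linear interpolation between the bracketing samples
      w <- -y[i - 1L] / (y[i] - y[i - 1L])
      return(time_min[i - 1L] + w * (time_min[i] - time_min[i - 1L]))
    }
  }
  NA_real_
}

#' Half-maximum import and export times of a translocation trace
#'
#' Import time: the first time (linearly interpolated between samples)
#' after stimulus onset at which the trace reaches half of its
#' in-window maximum. Export time: the first time after stimulus offset
#' at which it falls back below half-maximum; `NA` (flagged) when the
#' input has no offset (sustained stimulation).
#'
#' @param trace Numeric vector of samples.
#' @param time_min Sample times, minutes.
#' @param onset_min Stimulus onset, minutes.
#' @param offset_min Stimulus offset, minutes, or `NA` for sustained
#'   inputs.
#' @return List with `t_half_import_min` and `t_half_export_min`
#'   (absolute times, minutes).
#' @export
half_max_times <- function(trace, time_min, onset_min = 0,
                           offset_min = NA) {
  if (max(trace) <= 0) stop("trace has no positive maximum")
  half <- max(trace[time_min >= onset_min]) / 2
  imp <- first_crossing(time_min, trace, half, from = onset_min)
  exp_t <- if (is.na(offset_min)) NA_real_
           else first_crossing(time_min, trace, half, from = offset_min,
                               downward = TRUE)
  list(t_half_import_min = imp, t_half_export_min = exp_t)
}

#' Last-sample expression endpoint (and maximum) of a reporter trace
#'
#' The endpoint statistic is the last sample of the single-cell time
#' trace; the maximum over the trace is the "maximal level of gene
#' expression" variant. For a stable reporter at plateau they coincide
#' up to measurement noise.
#'
#' @param trace Numeric reporter samples.
#' @param stat `"endpoint"` (last sample) or `"max"`.
#' @return Scalar expression value.
#' @export
expression_endpoint <- function(trace, stat = c("endpoint", "max")) {
  if (!length(trace)) stop("empty reporter trace")
  stat <- match.arg(stat)
  if (stat == "endpoint") trace[length(trace)] else max(trace)
}

#' Ensemble mean/SD statistics of a set of traces
#'
#' Per-timepoint mean and sample standard deviation (n-1 denominator) of
#' an ensemble, plus the coefficient of variation at the peak time of
#' the mean trace (SD at that time divided by the mean at that time).
#' With `scale_mode = "percent_of_mean_peak"` both mean and SD are
#' expressed as percent of the mean-trace peak ("% max of mean"); the CV
#' is invariant to this rescaling.
#'
#' @param traces `cells x time` matrix (>= 2 cells).
#' @param time_min Sample times, minutes.
#' @param scale_mode `"normalized_au"` or `"percent_of_mean_peak"`.
#' @return List of class `ensemble_stats`: `mean_trace`, `sd_trace`,
#'   `cv_at_peak`, `sd_at_peak`, `peak_time_of_mean`, `scale_mode`.
#' @export
ensemble_stats <- function(traces, time_min,
                           scale_mode = c("normalized_au",
                                          "percent_of_mean_peak")) {
  scale_mode <- match.arg(scale_mode)
  traces <- as.matrix(traces)
  if (nrow(traces) < 2L) stop("need at least 2 traces")
  if (ncol(traces) != length(time_min))
    stop("trace length must match 'time_min'")
  m <- colMeans(traces)
  s <- apply(traces, 2L, stats::sd)
  ip <- which.max(m)
  cv <- s[ip] / m[ip]
  sd_at_peak <- s[ip]
  if (scale_mode == "percent_of_mean_peak") {
    pk <- m[ip]
    m <- 100 * m / pk
    s <- 100 * s / pk
  }
  structure(list(mean_trace = m, sd_trace = s, cv_at_peak = cv,
                 sd_at_peak = sd_at_peak,
                 peak_time_of_mean = time_min[ip],
                 scale_mode = scale_mode),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("<ensemble_stats> peak of mean at %g min; CV at peak %.3f; SD at peak %.3f (%s)\n",
              x$peak_time_of_mean, x$cv_at_peak, x$sd_at_peak, x$scale_mode))
  invisible(x)
}

#' Per-cell trace features of an experiment
#'
#' Extracts, for every cell, the scalar summaries used throughout the
#' analysis: peak TF levels and AUCs in a window after stimulus onset,
#' half-max import/export times per TF, and reporter endpoint/maximum.
#' Deleted (all-zero) TF channels yield zero peaks/AUCs and `NA`
#' half-max times.
#'
#' @param experiment A `cell_experiment` (from [generate_experiment()]
#'   or [read_traces()]).
#' @param window_min Onset-aligned peak/AUC window, minutes after onset
#'   (default `c(0, 30)`).
#' @return Data frame (one row per cell) with columns `cell_id`,
#'   `genotype`, `promoter`, `stimulus`, `peak_msn2`, `peak_msn4`,
#'   `auc_msn2`, `auc_msn4`, `t_half_import_msn2`, `t_half_export_msn2`,
#'   `t_half_import_msn4`, `t_half_export_msn4`, `expr_endpoint`,
#'   `expr_max`.
#' @export
compute_features <- function(experiment, window_min = c(0, 30)) {
  stopifnot(inherits(experiment, "cell_experiment"))
  tm <- experiment$time_min
  stim <- experiment$meta$stim
  onset <- stim$onset_min
  offset <- if (!is.null(stim$kind) && stim$kind == "pulse")
    stim$onset_min + stim$duration_min else NA_real_
  win <- onset + window_min

  per_tf <- function(X) {
    n <- nrow(X)
    pk <- apply(X, 1L, peak_level, time_min = tm, window_min = win)
    au <- apply(X, 1L, auc, time_min = tm, window_min = win)
    ti <- te <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (max(X[i, ]) > 0) {
        hm <- half_max_times(X[i, ], tm, onset_min = onset,
                             offset_min = offset)
        ti[i] <- hm$t_half_import_min; te[i] <- hm$t_half_export_min
      }
    }
    list(peak = pk, auc = au, t_imp = ti, t_exp = te)
  }
  f2 <- per_tf(experiment$msn2)
  f4 <- per_tf(experiment$msn4)
  data.frame(cell_id = experiment$cell_id,
             genotype = experiment$genotype,
             promoter = experiment$meta$promoter,
             stimulus = format(stim),
             peak_msn2 = f2$peak, peak_msn4 = f4$peak,
             auc_msn2 = f2$auc, auc_msn4 = f4$auc,
             t_half_import_msn2 = f2$t_imp, t_half_export_msn2 = f2$t_exp,
             t_half_import_msn4 = f4$t_imp, t_half_export_msn4 = f4$t_exp,
             expr_endpoint = apply(experiment$reporter, 1L,
                                   expression_endpoint),
             expr_max = apply(experiment$reporter, 1L, expression_endpoint,
                              stat = "max"),
             stringsAsFactors = FALSE)
}
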