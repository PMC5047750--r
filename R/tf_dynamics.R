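# First-order relaxation of a nuclear-localization trace toward a
# piecewise-constant target amplitude * drive(t), with separate import and
# export timescales. Exact exponential update per fine step; vectorized
# over cells.
relax_traces <- function(amp, drive_fine, dt, tau_import, tau_export) {
  n <- length(amp)
  K <- length(drive_fine)
  x <- matrix(0, n, K)
  e_imp <- exp(-dt / tau_import)
  e_exp <- exp(-dt / tau_export)
  xk <- numeric(n)
  for (k in seq_len(K - 1L)) {
    target <- amp * drive_fine[k]
    ek <- ifelse(target >= xk, e_imp, e_exp)
    xk <- target + (xk - target) * ek
    x[, k + 1L] <- xk
  }
  x
}

# Log-normal draws parameterized by mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Sample single-cell TF translocation traces
#'
#' Draws `n_cells` cells and simulates nuclear Msn2 and Msn4 time traces
#' on the stimulus sampling grid. Each cell's maximal amplitude is
#' log-normal (mean and CV from `tf`, scaled by the stimulus dose); the
#' trace rises first-order after stimulus onset (Msn4 with an extra
#' `lag_msn4_min` lag), tracks the input drive, and decays after offset.
#' Deleted genotypes have the corresponding channel identically zero.
#' Per-cell translational capacity is 1 except under sustained
#' (ethanol-like) stimulation, where it is Beta-distributed with most
#' mass near zero.
#'
#' @param tf A [tf_params()].
#' @param stim A [stimulus_program()].
#' @param genotype One of `genotypes()`.
#' @param n_cells Number of cells (>= 1).
#' @param seed Optional integer seed; if supplied, `set.seed(seed)` is
#'   called so the draw is reproducible.
#' @param noise If `TRUE` (default), additive Gaussian measurement noise
#'   (`meas_noise_sd`) is applied to the sampled traces of present
#'   channels; latent noiseless traces are returned otherwise.
#' @param dt Internal integration step, minutes.
#' @return A list of class `tf_sample` with elements `time_min`, `msn2`
#'   and `msn4` (`n_cells x length(time_min)` matrices, normalized
#'   a.u.), `capacity` (length `n_cells`), `amp_msn2`, `amp_msn4`, and
#'   the generating `genotype`/`stim`/`tf`.
#' @examples
#' s <- sample_tf_traces(tf_params(), stimulus_program("pulse"), "WT",
#'                       n_cells = 5, seed = 1)
#' dim(s$msn2)
#' @export
sample_tf_traces <- function(tf, stim, genotype = "WT", n_cells,
                             seed = NULL, noise = TRUE, dt = 0.1) {
  stopifnot(inherits(tf, "tf_params"), inherits(stim, "stimulus_program"))
  if (!genotype %in% genotypes())
    stop("unknown genotype: ", genotype)
  if (!is.numeric(n_cells) || n_cells < 1)
    stop("'n_cells' must be >= 1")
  n_cells <- as.integer(n_cells)
  if (!is.null(seed)) set.seed(seed)

  times <- stim_times(stim)
  t_fine <- seq(0, stim$total_min, by = dt)
  idx <- match(round(times / dt), round(t_fine / dt))
  if (anyNA(idx)) stop("'dt' must divide the sample interval")

  # draws always happen for both channels so RNG streams are aligned
  # across genotypes (deletion = zeroing, not skipping)
  amp2 <- stim$dose * rlnorm_mean_cv(n_cells, tf$mean_amp_msn2, tf$cv_amp_msn2)
  amp4 <- stim$dose * rlnorm_mean_cv(
    n_cells, tf$mean_amp_msn2 / tf$amp_ratio_msn2_over_msn4, tf$cv_amp_msn4)
  capacity <- if (stim$kind == "sustained")
    stats::rbeta(n_cells, tf$capacity_beta_shape1, tf$capacity_beta_shape2)
  else rep(1, n_cells)

  if (stim$dose == 0) {
    msn2 <- msn4 <- matrix(0, n_cells, length(times))
  } else {
    u2 <- stimulus_drive(stim, t_fine)
    u4 <- stimulus_drive(stim, t_fine, lag_min = tf$lag_msn4_min)
    msn2 <- relax_traces(amp2, u2, dt, tf$tau_import_min, tf$tau_export_min)[, idx, drop = FALSE]
    msn4 <- relax_traces(amp4, u4, dt, tf$tau_import_min, tf$tau_export_min)[, idx, drop = FALSE]
  }

  del2 <- genotype %in% c("msn2d", "msn2d_msn4d")
  del4 <- genotype %in% c("msn4d", "msn2d_msn4d")
  if (noise && stim$dose > 0) {
    msn2 <- msn2 + matrix(stats::rnorm(length(msn2), 0, tf$meas_noise_sd),
                          nrow = n_cells)
    msn4 <- msn4 + matrix(stats::rnorm(length(msn4), 0, tf$meas_noise_sd),
                          nrow = n_cells)
  }
  if (del2) msn2[] <- 0
  if (del4) msn4[] <- 0

  structure(list(time_min = times, msn2 = msn2, msn4 = msn4,
                 capacity = capacity, amp_msn2 = amp2, amp_msn4 = amp4,
                 genotype = genotype, stim = stim, tf = tf),
            class = "tf_sample")
}

#' @export
print.tf_sample <- function(x, ...) {
  cat(sprintf("<tf_sample> %d cells, genotype %s, %s\n",
              nrow(x$msn2), x$genotype, format(x$stim)))
  invisible(x)
}
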