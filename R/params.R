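#' Transcription-factor translocation parameters
#'
#' Parameters of the single-cell nuclear translocation model shared by
#' Msn2 and Msn4. Each cell draws a translocation amplitude from a
#' log-normal distribution; the nuclear level relaxes first-order toward
#' `amplitude * drive(t)` with import timescale `tau_import_min` while
#' rising and `tau_export_min` while falling. Msn4 follows the same input
#' with a short lag and a roughly 3-fold lower, more heterogeneous
#' amplitude. Levels are expressed in "normalized a.u.", i.e. after
#' cross-channel scaling so the two TFs are directly comparable.
#'
#' @param mean_amp_msn2 Population mean of the maximal Msn2 nuclear level
#'   at dose 1, normalized a.u.
#' @param amp_ratio_msn2_over_msn4 Fold difference between mean Msn2 and
#'   mean Msn4 amplitudes (default 3).
#' @param cv_amp_msn2,cv_amp_msn4 Coefficients of variation of the
#'   cell-specific amplitudes (Msn4 is the noisier channel).
#' @param lag_msn4_min Onset lag of Msn4 translocation behind Msn2,
#'   minutes.
#' @param tau_import_min,tau_export_min Nuclear import / export
#'   relaxation timescales, minutes.
#' @param meas_noise_sd Additive Gaussian measurement noise applied to
#'   every sampled channel, normalized a.u.
#' @param capacity_beta_shape1,capacity_beta_shape2 Shape parameters of
#'   the Beta distribution of per-cell translational capacity under
#'   sustained (ethanol-like) stress; most mass near zero reflects the
#'   translational arrest that leaves the majority of cells unable to
#'   express the reporter. Capacity is 1 for all other stimuli.
#' @return An object of class `tf_params`.
#' @export
tf_params <- function(mean_amp_msn2 = 40,
                      amp_ratio_msn2_over_msn4 = 3,
                      cv_amp_msn2 = 0.2,
                      cv_amp_msn4 = 0.5,
                      lag_msn4_min = 2.5,
                      tau_import_min = 1.5,
                      tau_export_min = 3,
                      meas_noise_sd = 0.5,
                      capacity_beta_shape1 = 0.3,
                      capacity_beta_shape2 = 1.2) {
  vals <- c(mean_amp_msn2 = mean_amp_msn2,
            amp_ratio_msn2_over_msn4 = amp_ratio_msn2_over_msn4,
            cv_amp_msn2 = cv_amp_msn2, cv_amp_msn4 = cv_amp_msn4,
            lag_msn4_min = lag_msn4_min,
            tau_import_min = tau_import_min,
            tau_export_min = tau_export_min,
            meas_noise_sd = meas_noise_sd,
            capacity_beta_shape1 = capacity_beta_shape1,
            capacity_beta_shape2 = capacity_beta_shape2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all tf_params fields must be positive and finite")
  structure(as.list(vals), class = "tf_params")
}

#' @export
print.tf_params <- function(x, ...) {
  cat("<tf_params>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Promoter activation parameters
#'
#' Parameters of the promoter model: chromatin opening proceeds through
#' `n_steps` sequential remodeling steps, each at rate
#' `n_steps * k_open_per_min * a_w(t) * H(t)`, where `a_w` is the
#' shared-site occupancy drive weighted by the class-specific activator
#' potencies and `H` is the opening gate. For the fast class `H = 1`
#' whenever combined TF level exceeds `basal_au`; for the slow class
#' `H = 1` only while the Msn2 level is at or above the switch threshold
#' `theta_msn2` (Msn2 as a low-threshold switch). The open state
#' transcribes at `beta_max * (x2 + x4) / (K_occ + x2 + x4)` and
#' attenuates irreversibly at rate `k_close_per_min`, giving each
#' promoter a finite expression window scaled to its kinetic class.
#'
#' Defaults encode a 5-fold difference in activation timescale between
#' the fast and slow classes (`k_open`, `k_close` and `beta_max` all
#' scale 5:1), a slow-class switch threshold of 10 normalized a.u. (25%
#' of the mean maximal Msn2 level at the default [tf_params()]), and
#' slow-class weights in which Msn4 is the potent opening activator
#' (w_msn4 = 3 compensating its 3-fold lower level) while Msn2
#' contributes weakly but occupies shared sites (w_msn2 = 0.3), which
#' produces the Msn2:Msn4 ratio suppression.
#'
#' @param kinetics_class `"fast"` or `"slow"`.
#' @param k_open_per_min Overall chromatin opening rate, 1/min (inverse
#'   of the mean opening time at saturating drive).
#' @param k_close_per_min Irreversible attenuation rate of the open
#'   state, 1/min.
#' @param theta_msn2 Slow-class Msn2 switch threshold, normalized a.u.
#'   (`NA` for the fast class).
#' @param beta_max Maximal transcription rate of the open state,
#'   expression a.u./min.
#' @param K_occ Half-saturation constant of shared-site occupancy,
#'   normalized a.u.
#' @param w_msn2,w_msn4 Dimensionless activator weights in the opening
#'   drive.
#' @param rate_w_msn2,rate_w_msn4 Activator weights in the open-state
#'   transcription rate,
#'   `beta_max * (rw2*x2 + rw4*x4) / (K_occ + x2 + x4)`; equal for the
#'   fast class, mildly Msn4-tilted for the slow class.
#' @param maturation_delay_min Fluorophore maturation, modeled as a pure
#'   delay of the observed reporter, minutes.
#' @param n_steps Number of sequential opening steps (sets the sharpness
#'   of the activation delay; relative dispersion `1/sqrt(n_steps)`).
#' @param basal_au Basal occupancy level (normalized a.u.) above which
#'   the fast-class gate is on.
#' @return An object of class `promoter_params`.
#' @examples
#' promoter_params("fast")
#' promoter_params("slow")
#' @export
promoter_params <- function(kinetics_class = c("fast", "slow"),
                            k_open_per_min = NULL,
                            k_close_per_min = NULL,
                            theta_msn2 = NULL,
                            beta_max = NULL,
                            K_occ = 5,
                            w_msn2 = NULL,
                            w_msn4 = NULL,
                            rate_w_msn2 = 1,
                            rate_w_msn4 = NULL,
                            maturation_delay_min = 10,
                            n_steps = 8,
                            basal_au = 1) {
  kinetics_class <- match.arg(kinetics_class)
  fast <- kinetics_class == "fast"
  if (is.null(k_open_per_min)) k_open_per_min <- if (fast) 0.45 else 0.09
  if (is.null(k_close_per_min)) k_close_per_min <- if (fast) 0.25 else 0.05
  if (is.null(beta_max)) beta_max <- if (fast) 5 else 1
  if (is.null(w_msn2)) w_msn2 <- if (fast) 1 else 0.35
  if (is.null(w_msn4)) w_msn4 <- if (fast) 1 else 3
  if (is.null(theta_msn2)) theta_msn2 <- if (fast) NA_real_ else 10
  if (is.null(rate_w_msn4)) rate_w_msn4 <- if (fast) 1 else 2
  rates <- c(k_open_per_min = k_open_per_min,
             k_close_per_min = k_close_per_min, beta_max = beta_max,
             K_occ = K_occ, w_msn2 = w_msn2, w_msn4 = w_msn4,
             rate_w_msn2 = rate_w_msn2, rate_w_msn4 = rate_w_msn4,
             basal_au = basal_au)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("promoter rates, weights and scales must be positive and finite")
  if (maturation_delay_min < 0) stop("'maturation_delay_min' must be >= 0")
  if (n_steps < 1 || n_steps != round(n_steps))
    stop("'n_steps' must be a positive integer")
  if (!fast && (!is.finite(theta_msn2) || theta_msn2 <= 0))
    stop("slow-class promoters need a positive 'theta_msn2'")
  structure(
    list(kinetics_class = kinetics_class,
         k_open_per_min = k_open_per_min,
         k_close_per_min = k_close_per_min,
         theta_msn2 = theta_msn2,
         beta_max = beta_max, K_occ = K_occ,
         w_msn2 = w_msn2, w_msn4 = w_msn4,
         rate_w_msn2 = rate_w_msn2, rate_w_msn4 = rate_w_msn4,
         maturation_delay_min = maturation_delay_min,
         n_steps = as.integer(n_steps), basal_au = basal_au),
    class = "promoter_params")
}

#' @export
print.promoter_params <- function(x, ...) {
  cat(sprintf("<promoter_params> %s kinetics class\n", x$kinetics_class))
  for (nm in setdiff(names(x), "kinetics_class"))
    cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Genotypes understood by the generator
#' @return Character vector of valid genotype codes.
#' @export
genotypes <- function() c("WT", "msn2d", "msn4d", "msn2d_msn4d")
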