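#' Fit the regulator mode of a binned expression relationship
#'
#' Distinguishes the two regulatory archetypes seen at single-cell
#' resolution: a "switch" (expression steps from a basal to an induced
#' level once the TF exceeds a threshold, as Msn2 does on slow
#' promoters) and a "rheostat" (expression scales linearly with TF
#' activity, as Msn4 does), with a flat no-dependence model as the null.
#' Three candidates are fit to the per-bin mean expression values,
#' weighted by the number of cells per bin:
#'
#' * flat: `E = b`
#' * switch (step): `E = b + h * 1(x >= theta)` with the threshold
#'   `theta` scanned over the interior bin boundaries
#' * rheostat (linear): `E = b + m * x` at the bin centers
#'
#' The candidate with the smallest small-sample information criterion
#' (AICc at the effective sample size `sum(n_per_bin)`) is selected;
#' exact ties favour the simpler model in the order flat, switch,
#' rheostat. The threshold is reported both in normalized a.u. and as a
#' percentage of the maximal mean TF level of the ensemble (the largest
#' per-bin mean TF).
#'
#' @param binned A `binned_relationship` (from [bin_by_tf()]) with at
#'   least 4 populated bins.
#' @return An object of class `regulator_mode_fit` with fields `mode`
#'   (`"switch"`, `"rheostat"` or `"flat"`), `theta_hat`,
#'   `theta_hat_pct_max`, `step_height`, `slope`, `intercept`,
#'   `sse_step`, `sse_linear`, `sse_flat`, `criterion` (named vector),
#'   plus the data used. Supports `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals` and `plot`.
#' @examples
#' b <- structure(list(tf = "msn2", bin_edges = seq(0, 50, 10),
#'                     bin_centers = c(5, 15, 25, 35, 45),
#'                     bin_means = c(0, 0, 1, 1, 1),
#'                     bin_mean_tf = c(5, 15, 25, 35, 45),
#'                     responder_fraction = rep(NA, 5),
#'                     n_per_bin = rep(10L, 5), n_retained = 50L,
#'                     n_excluded = 0L), class = "binned_relationship")
#' fit_regulator_mode(b)
#' @export
fit_regulator_mode <- function(binned) {
  stopifnot(inherits(binned, "binned_relationship"))
  ok <- !is.na(binned$bin_means)
  if (sum(ok) < 4L) stop("need at least 4 populated bins")
  x <- binned$bin_centers[ok]
  y <- binned$bin_means[ok]
  w <- binned$n_per_bin[ok]
  if (all(w == 0)) w <- rep(1, length(y))
  N <- sum(w)

  wrss <- function(fitted) sum(w * (y - fitted)^2)

  # flat
  b_flat <- sum(w * y) / N
  sse_flat <- wrss(b_flat)

  # linear (weighted least squares on bin centers)
  lin <- stats::lm.wfit(cbind(1, x), y, w)
  sse_lin <- wrss(cbind(1, x) %*% lin$coefficients)

  # step: scan interior bin boundaries
  cand <- binned$bin_edges[-c(1L, length(binned$bin_edges))]
  cand <- cand[vapply(cand, function(th) any(x < th) && any(x >= th),
                      logical(1))]
  if (!length(cand)) stop("no interior boundary splits the populated bins")
  best <- NULL
  for (th in cand) {
    lo <- x < th
    b0 <- sum(w[lo] * y[lo]) / sum(w[lo])
    b1 <- sum(w[!lo] * y[!lo]) / sum(w[!lo])
    s <- wrss(ifelse(lo, b0, b1))
    if (is.null(best) || s < best$sse - 1e-12) {
      best <- list(theta = th, base = b0, height = b1 - b0, sse = s)
    }
  }

  aicc <- function(rss, p) {
    rss <- max(rss, 1e-300)
    n <- max(N, p + 2)
    n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  }
  crit <- c(flat = aicc(sse_flat, 1),
            switch = aicc(best$sse, 3),
            rheostat = aicc(sse_lin, 2))
  # exact ties favour the simpler model: flat, then switch, then rheostat
  pref <- c("flat", "switch", "rheostat")
  mode <- pref[which.min(crit[pref] - c(2e-9, 1e-9, 0))]

  max_tf <- max(binned$bin_mean_tf[ok])
  structure(
    list(mode = mode,
         theta_hat = best$theta,
         theta_hat_pct_max = 100 * best$theta / max_tf,
         max_mean_tf_level = max_tf,
         step_height = best$height, step_base = best$base,
         slope = unname(lin$coefficients[2L]),
         intercept = unname(lin$coefficients[1L]),
         flat_level = b_flat,
         sse_step = best$sse, sse_linear = sse_lin, sse_flat = sse_flat,
         criterion = crit,
         binned = binned, x = x, y = y, w = w),
    class = "regulator_mode_fit")
}

mode_fit_predict <- function(object, x, mode = object$mode) {
  switch(mode,
         flat = rep(object$flat_level, length(x)),
         switch = object$step_base +
           object$step_height * (x >= object$theta_hat),
         rheostat = object$intercept + object$slope * x)
}

#' @export
print.regulator_mode_fit <- function(x, ...) {
  cat(sprintf("<regulator_mode_fit> mode: %s\n", x$mode))
  if (x$mode == "switch")
    cat(sprintf("  threshold %.3g a.u. (%.1f%% of max mean TF level %.3g); step height %.3g\n",
                x$theta_hat, x$theta_hat_pct_max, x$max_mean_tf_level,
                x$step_height))
  if (x$mode == "rheostat")
    cat(sprintf("  slope %.4g a.u. expression per a.u. TF (intercept %.3g)\n",
                x$slope, x$intercept))
  cat(sprintf("  AICc: flat %.2f | switch %.2f | rheostat %.2f\n",
              x$criterion["flat"], x$criterion["switch"],
              x$criterion["rheostat"]))
  invisible(x)
}

#' @export
summary.regulator_mode_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  weighted SSE: flat %.4g | step %.4g | linear %.4g (n = %d cells in %d bins)\n",
              object$sse_flat, object$sse_step, object$sse_linear,
              sum(object$w), length(object$y)))
  invisible(object)
}

#' @export
coef.regulator_mode_fit <- function(object, ...) {
  switch(object$mode,
         flat = c(level = object$flat_level),
         switch = c(base = object$step_base, height = object$step_height,
                    theta = object$theta_hat),
         rheostat = c(intercept = object$intercept, slope = object$slope))
}

#' @export
predict.regulator_mode_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
  else if (is.data.frame(newdata)) newdata[[1L]] else as.numeric(newdata)
  mode_fit_predict(object, x)
}

#' @export
fitted.regulator_mode_fit <- function(object, ...) {
  mode_fit_predict(object, object$x)
}

#' @export
residuals.regulator_mode_fit <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
plot.regulator_mode_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16, cex = 0.4 + sqrt(x$w / max(x$w)),
                 xlab = sprintf("peak %s (normalized a.u.)", x$binned$tf),
                 ylab = "mean expression (a.u.)",
                 main = sprintf("regulator mode: %s", x$mode), ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, mode_fit_predict(x, xs), col = "firebrick")
  if (x$mode == "switch")
    graphics::abline(v = x$theta_hat, lty = 3, col = "grey40")
  invisible(x)
}
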