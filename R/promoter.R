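# Linear interpolation of grid traces onto the solver's half-step grid.
interp_half_grid <- function(X, times, t_half) {
  h <- times[2L] - times[1L]
  j <- pmin(floor((t_half - times[1L]) / h) + 1L, length(times) - 1L)
  w <- (t_half - times[j]) / h
  Xh <- matrix(0, nrow(X), length(t_half))
  for (k in seq_along(t_half))
    Xh[, k] <- X[, j[k]] * (1 - w[k]) + X[, j[k] + 1L] * w[k]
  Xh
}

#' Simulate reporter expression from TF traces
#'
#' Integrates, per cell, the promoter activation model driven by given
#' nuclear Msn2/Msn4 traces (linearly interpolated between samples).
#' Chromatin opens through `n_steps` sequential steps at per-step rate
#' `n_steps * k_open * a_w(t) * H(t)` with weighted shared-site
#' occupancy `a_w = (w2*x2 + w4*x4) / (K_occ + x2 + x4)`; the gate
#' `H(t)` is 1 for the fast class whenever combined TF level exceeds
#' `basal_au` and, for the slow class, only while `x2 >= theta_msn2`.
#' The open state transcribes at
#' `beta_max * (rw2*x2 + rw4*x4) / (K_occ + x2 + x4)`, scaled by the cell's
#' translational capacity, and attenuates irreversibly at
#' `k_close_per_min`. The stable reporter accumulates without
#' degradation and is observed after a pure maturation delay. The
#' integration (classical fixed-step Runge-Kutta) is deterministic given
#' its inputs.
#'
#' @param msn2,msn4 Numeric vectors (one cell) or `n x length(time_min)`
#'   matrices of nuclear TF levels, normalized a.u.
#' @param capacity Per-cell translational capacity in `[0, 1]`; recycled
#'   to the number of cells.
#' @param prom A [promoter_params()].
#' @param time_min Uniform sampling grid of the traces, minutes.
#' @param dt Integration step, minutes.
#' @return Reporter trace(s) on `time_min`, same shape as `msn2`.
#' @examples
#' tm <- seq(0, 180, by = 2)
#' x2 <- ifelse(tm <= 30, 40, 0)
#' x4 <- ifelse(tm <= 30, 13, 0)
#' r <- simulate_promoter(x2, x4, 1, promoter_params("slow"), tm)
#' r[length(r)]
#' @export
simulate_promoter <- function(msn2, msn4, capacity = 1, prom, time_min,
                              dt = 0.2) {
  stopifnot(inherits(prom, "promoter_params"))
  vec_in <- is.null(dim(msn2))
  if (vec_in) {
    msn2 <- matrix(msn2, nrow = 1)
    msn4 <- matrix(msn4, nrow = 1)
  }
  n <- nrow(msn2)
  Tn <- length(time_min)
  if (ncol(msn2) != Tn || !identical(dim(msn2), dim(msn4)))
    stop("trace lengths must match the time grid")
  if (Tn < 2L) stop("need at least two time points")
  capacity <- rep_len(capacity, n)

  total <- time_min[Tn] - time_min[1L]
  K <- ceiling(total / dt)
  dt <- total / K                       # exact cover of the grid span
  t_half <- time_min[1L] + (0:(2L * K)) * (dt / 2)

  x2 <- pmax(interp_half_grid(msn2, time_min, t_half), 0)
  x4 <- pmax(interp_half_grid(msn4, time_min, t_half), 0)
  tot <- x2 + x4
  den <- prom$K_occ + tot
  gate <- if (prom$kinetics_class == "fast") tot >= prom$basal_au
          else x2 >= prom$theta_msn2
  rmat <- prom$n_steps * prom$k_open_per_min *
    ((prom$w_msn2 * x2 + prom$w_msn4 * x4) / den) * gate
  armat <- (prom$rate_w_msn2 * x2 + prom$rate_w_msn4 * x4) / den

  m <- prom$n_steps
  kc <- prom$k_close_per_min
  brate <- prom$beta_max * capacity

  C <- matrix(0, n, m); C[, 1L] <- 1
  P <- numeric(n); R <- numeric(n)
  Rfull <- matrix(0, n, K + 1L)

  deriv <- function(C, P, r, ar) {
    dC <- -r * C
    if (m > 1L) dC[, 2:m] <- dC[, 2:m] + r * C[, 1:(m - 1L)]
    list(dC = dC, dP = r * C[, m] - kc * P, dR = brate * ar * P)
  }

  for (k in seq_len(K)) {
    i1 <- 2L * k - 1L; i2 <- 2L * k; i3 <- 2L * k + 1L
    r1 <- rmat[, i1]; r2 <- rmat[, i2]; r3 <- rmat[, i3]
    a1 <- armat[, i1]; a2 <- armat[, i2]; a3 <- armat[, i3]
    f1 <- deriv(C, P, r1, a1)
    f2 <- deriv(C + dt / 2 * f1$dC, P + dt / 2 * f1$dP, r2, a2)
    f3 <- deriv(C + dt / 2 * f2$dC, P + dt / 2 * f2$dP, r2, a2)
    f4 <- deriv(C + dt * f3$dC, P + dt * f3$dP, r3, a3)
    C <- C + dt / 6 * (f1$dC + 2 * f2$dC + 2 * f3$dC + f4$dC)
    P <- P + dt / 6 * (f1$dP + 2 * f2$dP + 2 * f3$dP + f4$dP)
    R <- R + dt / 6 * (f1$dR + 2 * f2$dR + 2 * f3$dR + f4$dR)
    Rfull[, k + 1L] <- R
  }

  # observed reporter: maturation as a pure delay
  t_full <- time_min[1L] + (0:K) * dt
  t_obs <- time_min - prom$maturation_delay_min
  out <- matrix(0, n, Tn)
  for (j in seq_len(Tn)) {
    tj <- t_obs[j]
    if (tj <= t_full[1L]) next
    jj <- min(floor((tj - t_full[1L]) / dt) + 1L, K)
    w <- (tj - t_full[jj]) / dt
    out[, j] <- Rfull[, jj] * (1 - w) + Rfull[, jj + 1L] * w
  }
  if (vec_in) drop(out) else out
}
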