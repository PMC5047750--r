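# Shared fixture builders. Everything is generated in code at test time.

default_tf <- tf_params()

pulse_exp <- function(promoter, duration, genotype, n = 200, seed = 11,
                      dose = 1) {
  generate_experiment(default_tf, promoter_params(promoter),
                      stimulus_program("pulse", dose = dose,
                                       duration_min = duration),
                      genotype, n, seed = seed)
}

mean_ep <- function(ex) max(0, mean(ex$reporter[, ncol(ex$reporter)]))

# square (instant on/off) TF traces on the standard grid, for
# deterministic promoter-model checks
square_trace <- function(level, duration, times = seq(0, 180, by = 2)) {
  ifelse(times <= duration, level, 0)
}

std_times <- seq(0, 180, by = 2)

# Independent fine-step explicit-Euler integrator of the promoter model,
# written from the model statement (not from the package internals):
# sequential m-step opening at rate m*k_open*a_w*H, irreversible shutoff
# k_close, transcription beta*capacity*a_r*P, maturation as pure delay.
euler_promoter <- function(msn2, msn4, capacity, prom, times,
                           dt = 0.005) {
  interp <- function(v, t) stats::approx(times, v, t, rule = 2)$y
  tt <- seq(times[1], times[length(times)], by = dt)
  x2 <- pmax(interp(msn2, tt), 0)
  x4 <- pmax(interp(msn4, tt), 0)
  den <- prom$K_occ + x2 + x4
  gate <- if (prom$kinetics_class == "fast")
    (x2 + x4) >= prom$basal_au else x2 >= prom$theta_msn2
  r <- prom$n_steps * prom$k_open_per_min *
    (prom$w_msn2 * x2 + prom$w_msn4 * x4) / den * gate
  ar <- (prom$rate_w_msn2 * x2 + prom$rate_w_msn4 * x4) / den
  m <- prom$n_steps
  cvec <- c(1, rep(0, m - 1)); P <- 0; R <- numeric(length(tt)); Rk <- 0
  for (k in seq_along(tt)[-length(tt)]) {
    rk <- r[k]
    dc <- -rk * cvec
    if (m > 1) dc[2:m] <- dc[2:m] + rk * cvec[1:(m - 1)]
    dP <- rk * cvec[m] - prom$k_close_per_min * P
    dR <- prom$beta_max * capacity * ar[k] * P
    cvec <- cvec + dt * dc; P <- P + dt * dP; Rk <- Rk + dt * dR
    R[k + 1] <- Rk
  }
  interp_R <- function(t) stats::approx(tt, R, t, rule = 2)$y
  obs <- times - prom$maturation_delay_min
  ifelse(obs <= 0, 0, interp_R(pmax(obs, 0)))
}
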