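test_that("gate classification follows the deletion-fraction rules", {
  expect_equal(classify_gate(1.0, 0.9, 0.95)$label, "OR")
  expect_equal(classify_gate(1.0, 0.05, 0.08)$label, "AND")
  expect_equal(classify_gate(1.0, 0.05, 0.8)$label, "MSN2_REQUIRED")
  expect_equal(classify_gate(1.0, 0.8, 0.05)$label, "MSN4_REQUIRED")
  expect_equal(classify_gate(1.0, 0.05, 0.4)$label, "NONE")
  expect_equal(classify_gate(0, 0, 0)$label, "NONE")
  expect_error(classify_gate(1, -0.1, 0.5), "non-negative")

  # scale invariance
  set.seed(12)
  for (i in 1:25) {
    w <- runif(1, 0.5, 2); a <- runif(1); b <- runif(1); c <- runif(1, 1, 9)
    expect_identical(classify_gate(w, a, b)$label,
                     classify_gate(c * w, c * a, c * b)$label)
  }
})

make_binned <- function(centers, means, n = rep(10L, length(centers))) {
  wd <- diff(centers)[1]
  edges <- c(centers - wd / 2, centers[length(centers)] + wd / 2)
  structure(list(tf = "msn2", bin_edges = edges, bin_centers = centers,
                 bin_means = means, bin_mean_tf = centers,
                 responder_fraction = rep(NA_real_, length(centers)),
                 n_per_bin = n, n_retained = sum(n), n_excluded = 0L),
            class = "binned_relationship")
}

test_that("regulator-mode fitting recovers exact archetypes", {
  # exact step: threshold at the 15 -> 25 boundary, reported 20
  fs <- fit_regulator_mode(make_binned(c(5, 15, 25, 35, 45),
                                       c(0, 0, 1, 1, 1)))
  expect_equal(fs$mode, "switch")
  expect_equal(fs$theta_hat, 20)
  expect_equal(fs$step_height, 1)
  expect_equal(fs$theta_hat_pct_max, 100 * 20 / 45)

  # exact line: slope recovered to machine precision
  fl <- fit_regulator_mode(make_binned(c(5, 15, 25, 35, 45),
                                       2 + 0.3 * c(5, 15, 25, 35, 45)))
  expect_equal(fl$mode, "rheostat")
  expect_equal(fl$slope, 0.3, tolerance = 1e-12)
  expect_equal(fl$intercept, 2, tolerance = 1e-10)

  # constant data: the simplest model wins the tie
  ff <- fit_regulator_mode(make_binned(c(5, 15, 25, 35, 45), rep(3, 5)))
  expect_equal(ff$mode, "flat")

  expect_error(fit_regulator_mode(make_binned(c(5, 15, 25),
                                              c(0, 1, 1))), "4 populated")
  # predict/coef/residuals are coherent
  expect_equal(unname(coef(fs)["theta"]), 20)
  expect_equal(predict(fs, c(10, 30)), c(0, 1))
  expect_equal(sum(residuals(fs)^2), 0)
})

test_that("kinetic-ratio estimation is exact on constructed reporters", {
  fake_exp <- function(tau, n = 3) {
    tm <- std_times
    rep_tr <- matrix(rep(10 * (1 - exp(-tm / tau)), each = n), nrow = n)
    structure(list(time_min = tm, msn2 = rep_tr, msn4 = rep_tr,
                   reporter = rep_tr,
                   capacity = rep(1, n),
                   cell_id = sprintf("c%d", 1:n),
                   genotype = rep("WT", n),
                   meta = list(label = "fake", genotype = "WT",
                               promoter = "fast",
                               stim = stimulus_program("pulse",
                                                       duration_min = 60),
                               prom = promoter_params(
                                 "fast", maturation_delay_min = 0))),
              class = "cell_experiment")
  }
  same <- estimate_kinetic_ratio(fake_exp(6), fake_exp(6))
  expect_equal(same$ratio, 1)
  # slow reporter an exact 5x time dilation of the fast one
  dil <- estimate_kinetic_ratio(fake_exp(4), fake_exp(20))
  expect_equal(dil$ratio, 5, tolerance = 0.05)

  flat <- fake_exp(6)
  flat$reporter[] <- 0
  expect_error(estimate_kinetic_ratio(fake_exp(6), flat), "non-induced")
  mism <- fake_exp(6)
  mism$meta$stim <- stimulus_program("pulse", duration_min = 30)
  expect_error(estimate_kinetic_ratio(mism, fake_exp(6)), "stimulus")
})

test_that("gate calls shift with duration on the slow promoter", {
  mk <- function(prom, dur, g) pulse_exp(prom, dur, g, n = 120, seed = 55)
  slow <- list(
    "30" = list(WT = mk("slow", 30, "WT"), msn2d = mk("slow", 30, "msn2d"),
                msn4d = mk("slow", 30, "msn4d")),
    "60" = list(WT = mk("slow", 60, "WT"), msn2d = mk("slow", 60, "msn2d"),
                msn4d = mk("slow", 60, "msn4d")))
  tab <- gate_vs_duration(slow)
  expect_equal(tab$label, c("AND", "MSN2_REQUIRED"))

  # missing genotype is an explicit error
  broken <- slow; broken[["30"]]$msn2d <- NULL
  expect_error(gate_vs_duration(broken), "msn2d")

  # double deletion never induces: mean below the responder threshold
  dd30 <- mk("slow", 30, "msn2d_msn4d"); dd60 <- mk("slow", 60, "msn2d_msn4d")
  ctrl <- pulse_exp("slow", 30, "WT", n = 120, seed = 56, dose = 0)
  thr <- derive_responder_threshold(ctrl)$threshold
  expect_lt(mean_ep(dd30), thr)
  expect_lt(mean_ep(dd60), thr)
})

test_that("msn4d slow-promoter output grows with pulse duration", {
  eps <- sapply(c(15, 30, 45, 60), function(d)
    mean_ep(pulse_exp("slow", d, "msn4d", n = 150, seed = 61)))
  expect_true(all(diff(eps) >= 0))
})
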