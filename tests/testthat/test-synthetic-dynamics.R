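test_that("zero dose and deletions zero the right channels", {
  stim0 <- stimulus_program("pulse", dose = 0, duration_min = 30)
  s0 <- sample_tf_traces(default_tf, stim0, "WT", 20, seed = 1)
  expect_true(all(s0$msn2 == 0))
  expect_true(all(s0$msn4 == 0))

  stim <- stimulus_program("pulse", dose = 1, duration_min = 30)
  wt <- sample_tf_traces(default_tf, stim, "WT", 25, seed = 3)
  d4 <- sample_tf_traces(default_tf, stim, "msn4d", 25, seed = 3)
  expect_true(all(d4$msn4 == 0))
  # msn2 untouched by the deletion: identical under the shared seed
  expect_identical(wt$msn2, d4$msn2)

  dd <- sample_tf_traces(default_tf, stim, "msn2d_msn4d", 10, seed = 3)
  expect_true(all(dd$msn2 == 0) && all(dd$msn4 == 0))

  expect_error(sample_tf_traces(default_tf, stim, "msn3d", 10), "genotype")
  expect_error(sample_tf_traces(default_tf, stim, "WT", 0), "n_cells")
})

test_that("trace grid arithmetic and determinism hold", {
  stim <- stimulus_program("pulse")
  s <- sample_tf_traces(default_tf, stim, "WT", 300, seed = 5)
  expect_equal(dim(s$msn2), c(300, 91))
  expect_equal(dim(s$msn4), c(300, 91))
  expect_length(s$capacity, 300)

  s2 <- sample_tf_traces(default_tf, stim, "WT", 300, seed = 5)
  expect_identical(s, s2)

  ex <- generate_experiment(default_tf, promoter_params("fast"), stim,
                            "WT", 15, seed = 9)
  ex2 <- generate_experiment(default_tf, promoter_params("fast"), stim,
                             "WT", 15, seed = 9)
  expect_identical(ex$reporter, ex2$reporter)
})

test_that("TF traces rise after onset and decay after offset", {
  stim <- stimulus_program("pulse", dose = 1, onset_min = 10,
                           duration_min = 30)
  s <- sample_tf_traces(default_tf, stim, "WT", 50, seed = 7,
                        noise = FALSE)
  tm <- s$time_min
  m2 <- colMeans(s$msn2)
  expect_true(all(m2[tm <= 10] == 0))
  # rising through the pulse, near amplitude at its end
  expect_gt(m2[tm == 20], 0.9 * m2[tm == 40])
  # decayed by ~5 export timescales after offset
  expect_lt(m2[tm == 60], 0.05 * max(m2))
  # reporter-free check of capacity: pulse leaves it at 1
  expect_true(all(s$capacity == 1))
})

test_that("Msn4 is ~3-fold lower, lagged 2-3 min, noisier in CV but not SD", {
  stim <- stimulus_program("pulse", dose = 1, duration_min = 30)
  s <- sample_tf_traces(default_tf, stim, "WT", 800, seed = 21)
  tm <- s$time_min
  pk2 <- apply(s$msn2, 1, peak_level, time_min = tm, window_min = c(0, 30))
  pk4 <- apply(s$msn4, 1, peak_level, time_min = tm, window_min = c(0, 30))
  expect_gt(mean(pk2) / mean(pk4), 2.5)
  expect_lt(mean(pk2) / mean(pk4), 3.5)

  h2 <- half_max_times(colMeans(s$msn2), tm, onset_min = 0, offset_min = 30)
  h4 <- half_max_times(colMeans(s$msn4), tm, onset_min = 0, offset_min = 30)
  lag <- h4$t_half_import_min - h2$t_half_import_min
  expect_gte(lag, 2)
  expect_lte(lag, 3)

  e2 <- ensemble_stats(s$msn2, tm)
  e4 <- ensemble_stats(s$msn4, tm)
  expect_gt(e4$cv_at_peak, e2$cv_at_peak)
  expect_lt(e4$sd_at_peak, e2$sd_at_peak)
})

test_that("sustained (ethanol-like) stimulation reduces capacity heterogeneously", {
  s <- sample_tf_traces(default_tf, stimulus_program("sustained"), "WT",
                        400, seed = 13)
  expect_true(all(s$capacity >= 0 & s$capacity <= 1))
  # translational arrest: the majority of cells are strongly limited
  expect_gt(mean(s$capacity < 0.5), 0.5)
  expect_lt(mean(s$capacity), 0.35)
  # sustained drive holds nuclear localization at plateau
  m2 <- colMeans(s$msn2)
  expect_gt(m2[length(m2)], 0.9 * max(m2))
})

test_that("adaptive-transient input produces a ~30-min TF pulse despite sustained stress", {
  s <- sample_tf_traces(default_tf, stimulus_program("adaptive_transient"),
                        "WT", 100, seed = 17, noise = FALSE)
  m2 <- colMeans(s$msn2)
  tm <- s$time_min
  ipk <- which.max(m2)
  expect_lt(tm[ipk], 15)                      # early peak
  above <- tm[m2 > 0.25 * max(m2)]
  width <- max(above) - min(above)
  expect_gt(width, 15)
  expect_lt(width, 45)                        # transient, roughly half-hour
  expect_lt(m2[length(m2)], 0.05 * max(m2))   # fully adapted by 3 h
})

test_that("zeroing a channel equals simulating the deletion genotype", {
  stim <- stimulus_program("pulse", dose = 1, duration_min = 30)
  prom <- promoter_params("slow")
  wt <- generate_experiment(default_tf, prom, stim, "WT", 20, seed = 31)
  d2 <- generate_experiment(default_tf, prom, stim, "msn2d", 20, seed = 31)
  # shared seed: the surviving channel is trace-identical
  expect_identical(wt$msn4, d2$msn4)
  expect_true(all(d2$msn2 == 0))
  # and the deletion reporter equals the promoter driven by the zeroed
  # latent channel
  lat <- sample_tf_traces(default_tf, stim, "msn2d", 20, seed = 31,
                          noise = FALSE)
  rep_manual <- simulate_promoter(lat$msn2, lat$msn4, lat$capacity, prom,
                                  lat$time_min)
  set.seed(31)
  invisible(sample_tf_traces(default_tf, stim, "msn2d", 20, noise = FALSE))
  sdn <- default_tf$meas_noise_sd
  invisible(matrix(rnorm(length(rep_manual), 0, sdn), 20))  # msn2 noise
  invisible(matrix(rnorm(length(rep_manual), 0, sdn), 20))  # msn4 noise
  noise_rep <- matrix(rnorm(length(rep_manual), 0, sdn), 20)
  expect_equal(d2$reporter, rep_manual + noise_rep, tolerance = 1e-12)
})
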